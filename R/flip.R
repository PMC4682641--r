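#' Fluorescence loss in photobleaching (FLIP) analysis
#'
#' Tracks the fluorescence of non-bleached loci while another locus in the
#' same nucleus is bleached. Each locus trace is divided by its own
#' pre-bleach mean, so every curve starts at 1; control loci from unbleached
#' cells quantify acquisition photobleaching. Reports the per-locus relative
#' time series, the final relative fluorescence per label, and a one-sided
#' Welch test of whether flip loci end lower than controls (exchange between
#' domains through the shared pool).
#'
#' @param stack Time-series [image_stack()] of the bleached nucleus.
#' @param rois List of `roi` objects with labels `frap` (the bleached locus)
#'   and `flip` (non-bleached loci in the same nucleus).
#' @param control_stacks Optional list of time-series stacks from unbleached
#'   cells.
#' @param control_rois List (parallel to `control_stacks`) of `roi` lists or
#'   single `roi`s labelled `control`.
#' @param n_final Number of final frames summarized as "final relative
#'   fluorescence".
#' @return A list of class `flip_result` with `curves` (tibble: `locus`,
#'   `label`, `time`, `relative`), `final` (per-locus final relative
#'   fluorescence), and `test` (one-sided Welch flip < control, or `NULL`
#'   without controls).
#' @export
flip_analysis <- function(stack, rois, control_stacks = list(),
                          control_rois = list(), n_final = 15) {
  labels <- vapply(rois, function(r) r$label, character(1))
  if (!"frap" %in% labels) abort("Provide the bleached locus as a 'frap' ROI.")
  if (!"flip" %in% labels) abort("Provide at least one non-bleached 'flip' ROI.")

  frap_trace <- extract_trace(stack, rois[[which(labels == "frap")[1]]])
  frap_trace <- detect_bleach_frame(subtract_background(frap_trace))
  idx <- bleach_index(frap_trace)

  rel_curve <- function(st, roi, bleach_idx) {
    tr <- extract_trace(st, roi)
    pre <- mean(tr$intensity[tr$frame < bleach_idx])
    if (pre <= 0) abort(sprintf("Locus '%s' has non-positive pre-bleach signal.", roi$label))
    tibble(
      label = roi$label,
      time = (tr$frame - bleach_idx) * attr(tr, "frame_interval"),
      relative = tr$intensity / pre
    )
  }

  curves <- purrr::imap_dfr(rois, function(roi, i) {
    dplyr::mutate(rel_curve(stack, roi, idx), locus = paste0(roi$label, "_", i))
  })
  if (length(control_stacks) > 0) {
    if (length(control_rois) != length(control_stacks)) {
      abort("`control_rois` must parallel `control_stacks`.")
    }
    ctrl <- purrr::imap_dfr(control_stacks, function(st, i) {
      rr <- control_rois[[i]]
      if (inherits(rr, "roi")) rr <- list(rr)
      purrr::imap_dfr(rr, function(roi, j) {
        dplyr::mutate(rel_curve(st, roi, idx),
                      locus = paste0("control_", i, "_", j), label = "control")
      })
    })
    curves <- dplyr::bind_rows(curves, ctrl)
  } else {
    warn("No control loci supplied: acquisition bleaching is unquantified and no significance test is run.")
  }

  final <- curves |>
    dplyr::group_by(.data$locus, .data$label) |>
    dplyr::summarise(
      final_relative = mean(utils::tail(.data$relative, n_final)),
      .groups = "drop"
    )

  test <- NULL
  flip_final <- final$final_relative[final$label == "flip"]
  ctrl_final <- final$final_relative[final$label == "control"]
  if (length(flip_final) >= 2 && length(ctrl_final) >= 2) {
    test <- welch_t_test(flip_final, ctrl_final, alternative = "less")
  }
  structure(
    list(curves = dplyr::relocate(curves, "locus"), final = final, test = test),
    class = "flip_result"
  )
}

#' Summarise FLIP final fluorescence across replicate experiments
#'
#' Convenience aggregation when each replicate produced one `flip_result`:
#' pools the per-locus final relative fluorescence and tests flip < control
#' across replicates.
#'
#' @param results List of `flip_result` objects.
#' @return List with `final` (pooled tibble) and `test` (one-sided Welch).
#' @export
pool_flip_results <- function(results) {
  final <- purrr::map_dfr(seq_along(results), function(i) {
    dplyr::mutate(results[[i]]$final, replicate = i)
  })
  flip_final <- final$final_relative[final$label == "flip"]
  ctrl_final <- final$final_relative[final$label == "control"]
  test <- if (length(flip_final) >= 2 && length(ctrl_final) >= 2) {
    welch_t_test(flip_final, ctrl_final, alternative = "less")
  }
  list(final = final, test = test)
}

#' @export
print.flip_result <- function(x, ...) {
  cat("<flip_result>\n")
  print(x$final)
  if (!is.null(x$test)) {
    cat(sprintf("flip < control: t = %.3f, p = %.4g\n", x$test$t, x$test$p))
  }
  invisible(x)
}

#' Plot FLIP curves
#'
#' Average relative fluorescence of the bleached (frap), non-bleached (flip),
#' and control loci over time.
#' @param object A `flip_result`.
#' @param ... Unused.
#' @export
autoplot.flip_result <- function(object, ...) {
  avg <- object$curves |>
    dplyr::group_by(.data$label, .data$time) |>
    dplyr::summarise(relative = mean(.data$relative), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time, y = .data$relative,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      frap = "#b2182b", flip = "#2166ac", control = "#1a9850"
    )) +
    ggplot2::labs(x = "Time after bleach (s)", y = "Relative fluorescence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
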