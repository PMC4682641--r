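#' FRAP trace container
#'
#' A tidy per-frame record of one bleach experiment: frame index (1-based),
#' acquisition time, and mean ROI intensity, with the processing state
#' (background subtraction, bleach frame, normalization) carried in
#' attributes. Times are re-aligned so the first post-bleach frame sits at
#' t = 0 once the bleach frame is known.
#'
#' @param frame Integer frame indices.
#' @param time Acquisition times, s.
#' @param intensity Mean ROI intensity per frame.
#' @param frame_interval Frame interval, s.
#' @return A tibble of class `frap_trace`.
#' @export
frap_trace <- function(frame, time, intensity, frame_interval = NULL) {
  if (is.unsorted(time, strictly = TRUE)) abort("Times must be strictly increasing.")
  out <- tibble(frame = as.integer(frame), time = time, intensity = intensity)
  structure(out,
    class = c("frap_trace", class(out)),
    frame_interval = frame_interval %||% stats::median(diff(time)),
    background_subtracted = FALSE,
    bleach_index = NA_integer_,
    normalized = FALSE
  )
}

trace_attr <- function(trace) {
  list(
    frame_interval = attr(trace, "frame_interval"),
    background_subtracted = attr(trace, "background_subtracted"),
    bleach_index = attr(trace, "bleach_index"),
    normalized = attr(trace, "normalized")
  )
}

restore_trace <- function(data, template, ...) {
  dots <- list(...)
  a <- utils::modifyList(trace_attr(template), dots)
  structure(as_tibble(data),
    class = c("frap_trace", class(tibble())),
    frame_interval = a$frame_interval,
    background_subtracted = a$background_subtracted,
    bleach_index = a$bleach_index,
    normalized = a$normalized
  )
}

#' Extract a mean-intensity trace from a time series
#'
#' Computes the per-frame mean of the pixels inside the ROI (circle
#' membership: pixel centre within the radius), mirroring the manual
#' ROI-mean measurement done on the microscope data.
#'
#' @param stack An [image_stack()] with role `timeseries`.
#' @param roi An `roi` (see [roi_circle()]).
#' @return A [frap_trace()] with raw intensities.
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$role != "timeseries") {
    abort("`extract_trace()` expects a time-series stack.")
  }
  d <- dim(stack$data)
  mask <- roi_mask(roi, d[2:3])
  vals <- vapply(seq_len(d[1]), function(i) mean(stack$data[i, , ][mask]),
                 numeric(1))
  frap_trace(
    frame = seq_len(d[1]),
    time = (seq_len(d[1]) - 1) * stack$frame_interval,
    intensity = vals,
    frame_interval = stack$frame_interval
  )
}

#' Subtract the background from a trace
#'
#' Background is the per-trace minimum intensity, so the corrected minimum is
#' exactly zero and the result is invariant to any constant offset. An
#' explicit background value (e.g. from a background ROI) may be supplied
#' instead.
#'
#' @param trace A [frap_trace()].
#' @param background Optional fixed background; default is `min(intensity)`.
#' @return The corrected trace.
#' @export
subtract_background <- function(trace, background = NULL) {
  bg <- background %||% min(trace$intensity)
  out <- trace
  out$intensity <- trace$intensity - bg
  restore_trace(out, trace, background_subtracted = TRUE)
}

#' Locate the bleach frame
#'
#' The bleach pulse is triggered manually during acquisition, so the bleach
#' frame is inferred: it is the frame immediately after the largest
#' single-step intensity drop (earliest such frame on ties). The drop must
#' exceed `threshold` times the standard deviation of the other
#' frame-to-frame steps, otherwise no bleach is detected.
#'
#' @param trace A [frap_trace()] (>= 3 frames).
#' @param threshold Multiple of the step standard deviation the drop must
#'   exceed.
#' @return The trace with `bleach_index` set and times re-aligned so the
#'   first post-bleach frame is t = 0. Retrieve the index with
#'   [bleach_index()].
#' @export
detect_bleach_frame <- function(trace, threshold = 3) {
  y <- trace$intensity
  if (length(y) < 3) abort("Need at least 3 frames to locate a bleach.")
  drops <- -diff(y) # positive = intensity fell
  k <- which.max(drops)
  max_drop <- drops[k]
  others <- drops[-k]
  noise <- if (length(others) >= 2) sd(others) else 0
  if (max_drop <= 0 || max_drop <= threshold * noise) {
    abort("No bleach detected: no intensity drop exceeds the noise threshold.")
  }
  idx <- k + 1L # first post-bleach frame
  out <- trace
  out$time <- (out$frame - idx) * attr(trace, "frame_interval")
  restore_trace(out, trace, bleach_index = idx)
}

#' @rdname detect_bleach_frame
#' @export
bleach_index <- function(trace) attr(trace, "bleach_index")

#' Normalize a trace to its recovery plateau
#'
#' Divides the background-subtracted intensities by the mean of the last 15
#' acquired frames, so the normalized plateau mean is exactly 1. Traces with
#' fewer than 15 post-bleach frames use all their post-bleach frames (with a
#' warning).
#'
#' @param trace A background-subtracted [frap_trace()] with a known bleach
#'   frame.
#' @param n_plateau Number of final frames defining the plateau.
#' @return The trace with a `normalized` column added.
#' @export
normalize_trace <- function(trace, n_plateau = 15) {
  if (!attr(trace, "background_subtracted")) {
    abort("Subtract the background before normalizing (see `subtract_background()`).")
  }
  idx <- bleach_index(trace)
  if (is.na(idx)) abort("Bleach frame unknown: run `detect_bleach_frame()` first.")
  if (isTRUE(attr(trace, "normalized"))) return(trace)
  n_post <- sum(trace$frame >= idx)
  if (n_post < n_plateau) {
    warn(sprintf(
      "Only %d post-bleach frames available; plateau uses all of them.", n_post
    ))
    n_plateau <- n_post
  }
  plateau <- mean(utils::tail(trace$intensity, n_plateau))
  if (plateau <= 0) abort("Degenerate trace: recovery plateau mean is <= 0.")
  out <- trace
  out$normalized <- out$intensity / plateau
  restore_trace(out, trace, normalized = TRUE)
}

#' Average normalized traces aligned at the bleach
#'
#' Aligns each trace at its bleach frame and takes the pointwise unweighted
#' mean of the normalized intensities over the traces available at each
#' aligned frame.
#'
#' @param traces List of normalized [frap_trace()] objects sharing a frame
#'   interval.
#' @return Tibble with columns `time`, `mean_normalized`, `n`, `sd`.
#' @export
average_traces <- function(traces) {
  if (length(traces) == 0) abort("No traces to average.")
  ok <- vapply(traces, function(tr) isTRUE(attr(tr, "normalized")), logical(1))
  if (!all(ok)) abort("All traces must be normalized before averaging.")
  fi <- vapply(traces, function(tr) attr(tr, "frame_interval"), numeric(1))
  if (diff(range(fi)) > 1e-9) abort("Traces have mixed frame intervals.")
  long <- purrr::map_dfr(seq_along(traces), function(i) {
    tr <- traces[[i]]
    tibble(
      trace = i,
      aligned = tr$frame - bleach_index(tr),
      normalized = tr$normalized
    )
  })
  long |>
    dplyr::group_by(.data$aligned) |>
    dplyr::summarise(
      time = .data$aligned[1] * fi[1],
      mean_normalized = mean(.data$normalized),
      n = dplyr::n(),
      sd = sd(.data$normalized),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$aligned) |>
    dplyr::select("time", "mean_normalized", "n", "sd")
}

#' Post-bleach portion of a trace or averaged curve
#'
#' @param x A normalized `frap_trace` or the output of [average_traces()].
#' @return Tibble with columns `time` (starting at 0) and `value`.
#' @export
recovery_points <- function(x) {
  if (inherits(x, "frap_trace")) {
    idx <- bleach_index(x)
    if (is.na(idx)) abort("Bleach frame unknown.")
    col <- if ("normalized" %in% names(x)) x$normalized else x$intensity
    keep <- x$frame >= idx
    tibble(time = x$time[keep], value = col[keep])
  } else {
    keep <- x$time >= 0
    tibble(time = x$time[keep], value = x$mean_normalized[keep])
  }
}

#' Convert traces to the canonical trace table
#'
#' @param traces Named list of `frap_trace` objects.
#' @return Tibble in [write_traces()] column order.
#' @export
trace_table <- function(traces) {
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- sprintf("exp%03d", seq_along(traces))
  }
  purrr::map_dfr(names(traces), function(id) {
    tr <- traces[[id]]
    tibble(
      experiment_id = id,
      frame = tr$frame,
      time_s = tr$time,
      raw = tr$intensity,
      normalized = if ("normalized" %in% names(tr)) tr$normalized else NA_real_,
      bleach = tr$frame == bleach_index(tr)
    )
  })
}
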