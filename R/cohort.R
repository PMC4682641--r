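#' Five-number box summary
#'
#' Summary used for the half-time boxplots: the box bounds the interquartile
#' range divided by the median, whiskers extend to the most extreme data
#' point within 1.5 x IQR beyond the box, and points beyond are outliers.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector (n >= 1).
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, plus a list-column `outliers`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("Cannot summarise an empty group.")
  qs <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble(
    n = length(values),
    median = qs[2], q1 = qs[1], q3 = qs[3], iqr = iqr,
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    n_outliers = sum(!inside),
    outliers = list(sort(values[!inside]))
  )
}

#' Welch's two-sample t-test
#'
#' Student's t-test with two-tailed distribution, two samples, unequal
#' variance: the Welch statistic with Welch-Satterthwaite degrees of
#' freedom, implemented from the closed form. Degenerate inputs (both
#' variances zero) return p = 1 for equal means and p = 0 (with a warning)
#' otherwise.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param alternative `"two.sided"`, `"less"` (mean of `a` below `b`), or
#'   `"greater"`.
#' @return A list with `t`, `df`, `p`, and the group means.
#' @export
welch_t_test <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) abort("Need n >= 2 in each group.")
  ma <- mean(a)
  mb <- mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = ma, mean_b = mb))
    }
    warn("Both groups have zero variance with different means; p = 0.")
    return(list(t = sign(ma - mb) * Inf, df = length(a) + length(b) - 2, p = 0,
                mean_a = ma, mean_b = mb))
  }
  se2a <- va / length(a)
  se2b <- vb / length(b)
  t_stat <- (ma - mb) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t_stat), df),
    less = pt(t_stat, df),
    greater = pt(t_stat, df, lower.tail = FALSE)
  )
  list(t = t_stat, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Build a cohort record table
#'
#' Canonical per-experiment record: one row per FRAP experiment with its
#' condition, cell-cycle phase label (phases are input labels from
#' synchronization/morphology, never inferred here), time since release from
#' arrest, fitted half-time, and mobile fraction.
#'
#' @param experiment_id,condition,phase,time_min,t_half_ms,f_m Column
#'   vectors; `phase` must be one of G1, S, G2, unassigned.
#' @return A tibble of class `experiment_records`.
#' @export
experiment_records <- function(experiment_id, condition = "wt",
                               phase = "unassigned", time_min = NA_real_,
                               t_half_ms, f_m = NA_real_) {
  phase <- as.character(phase)
  bad <- setdiff(unique(phase), c("G1", "S", "G2", "unassigned"))
  if (length(bad) > 0) {
    abort(paste("Unknown phase label(s):", paste(bad, collapse = ", ")))
  }
  if (any(t_half_ms <= 0, na.rm = TRUE)) abort("`t_half_ms` must be > 0.")
  out <- tibble(
    experiment_id = as.character(experiment_id),
    condition = as.character(condition),
    phase = phase,
    time_min = time_min,
    t_half_ms = t_half_ms,
    f_m = f_m
  )
  class(out) <- c("experiment_records", class(out))
  out
}

#' @rdname experiment_records
#' @param path CSV with columns `experiment_id, condition, phase, time_min,
#'   t_half_ms, f_m`.
#' @export
read_experiment_records <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  do.call(experiment_records, as.list(raw))
}

#' Cell-cycle phase profile of half-recovery times
#'
#' Summarises half-times per phase (box summaries), runs the pairwise Welch
#' tests G1-S, S-G2, G1-G2 on the phases with n >= 2, and returns the
#' time-resolved scatter of half-time against time since release for
#' plotting. p-values are reported raw (no multiple-testing correction)
#' unless `p_adjust = "holm"`.
#'
#' @param records An [experiment_records()] tibble (or compatible data
#'   frame).
#' @param value Column to profile (default `t_half_ms`).
#' @param p_adjust `"none"` (default, flagged in the output) or `"holm"`.
#' @return A list of class `phase_profile`: `summaries` (per-phase box
#'   summaries), `tests` (pairwise Welch results), `scatter`
#'   (time-resolved records), `p_adjust`.
#' @export
phase_profile <- function(records, value = "t_half_ms",
                          p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  records <- as_tibble(records)
  if (!"phase" %in% names(records)) abort("Records need a `phase` column.")
  vals <- split(records[[value]], records$phase)

  summaries <- purrr::imap_dfr(vals, function(v, ph) {
    dplyr::mutate(summarize_group(v), phase = ph, .before = 1)
  })

  pairs <- list(c("G1", "S"), c("S", "G2"), c("G1", "G2"))
  tests <- purrr::map_dfr(pairs, function(pr) {
    va <- vals[[pr[1]]]
    vb <- vals[[pr[2]]]
    if (is.null(va) || is.null(vb)) return(NULL)
    if (length(va) < 2 || length(vb) < 2) {
      warn(sprintf("Phase pair %s-%s skipped (n < 2).", pr[1], pr[2]))
      return(NULL)
    }
    w <- welch_t_test(va, vb)
    tibble(
      group_a = pr[1], group_b = pr[2],
      n_a = length(va), n_b = length(vb),
      mean_a = w$mean_a, mean_b = w$mean_b,
      t = w$t, df = w$df, p = w$p
    )
  })
  if (nrow(tests) > 0 && p_adjust == "holm") {
    tests$p_adjusted <- stats::p.adjust(tests$p, method = "holm")
  }
  structure(
    list(
      summaries = summaries, tests = tests,
      scatter = dplyr::select(records, dplyr::any_of(c(
        "experiment_id", "condition", "phase", "time_min", value
      ))),
      p_adjust = p_adjust
    ),
    class = "phase_profile"
  )
}

#' @export
print.phase_profile <- function(x, ...) {
  cat("<phase_profile>\n")
  print(dplyr::select(x$summaries, -"outliers"))
  if (nrow(x$tests) > 0) {
    cat(sprintf("Pairwise Welch tests (p adjustment: %s):\n", x$p_adjust))
    print(x$tests)
  }
  invisible(x)
}

#' Boxplot of half-times per phase
#'
#' @param object A `phase_profile`.
#' @param ... Unused.
#' @export
autoplot.phase_profile <- function(object, ...) {
  value <- setdiff(names(object$scatter),
                   c("experiment_id", "condition", "phase", "time_min"))[1]
  dat <- dplyr::mutate(object$scatter,
    phase = factor(.data$phase, levels = c("G1", "S", "G2", "unassigned"))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8, coef = 1.5,
                          fill = "grey90") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
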