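#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> %s on %d points\n", x$model, x$n_points
  ))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  t_half = %.1f ms, R^2 = %.4f, RSS = %.4g\n",
              1000 * x$t_half, x$r_squared, x$rss))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a recovery fit
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @export
tidy.recovery_fit <- function(x, ...) {
  units <- c(a = "", b = "1/s", c = "", d = "1/s")
  tibble(
    term = names(x$params),
    estimate = unname(x$params),
    unit = unname(units[names(x$params)])
  )
}

#' @rdname tidy.recovery_fit
#' @return For `glance()`: a one-row model summary.
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble(
    model = x$model,
    t_half_ms = 1000 * x$t_half,
    r_squared = x$r_squared,
    rss = x$rss,
    aic = x$aic,
    n = x$n_points,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname tidy.recovery_fit
#' @export
augment.recovery_fit <- function(x, ...) {
  x$data
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf(
    "<model_selection> chose %s (F = %.3f, p = %.4g)\n",
    x$model, x$f_statistic, x$p_value
  ))
  print(x$choice)
  invisible(x)
}

#' @export
tidy.model_selection <- function(x, ...) tidy(x$choice)

#' @export
glance.model_selection <- function(x, ...) {
  dplyr::bind_cols(glance(x$choice),
                   tibble(f_statistic = x$f_statistic, p_value = x$p_value))
}

#' Predicted recovery at arbitrary times
#'
#' @param object A `recovery_fit`.
#' @param times Times, s.
#' @param ... Unused.
#' @export
predict.recovery_fit <- function(object, times = object$data$time, ...) {
  p <- object$params
  y <- p[["a"]] * (1 - exp(-p[["b"]] * times))
  if (object$model == "two_component") {
    y <- y + p[["c"]] * (1 - exp(-p[["d"]] * times))
  }
  y
}

#' Plot a recovery fit
#'
#' Data points with the fitted curve and the half-recovery time marked, in
#' the style of published mean-recovery-curve figures.
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_fit <- function(object, ...) {
  grid <- tibble(
    time = seq(0, max(object$data$time), length.out = 300)
  )
  grid$value <- predict(object, grid$time)
  asym <- sum(object$params[names(object$params) %in% c("a", "c")])
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.8, colour = "grey20") +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = asym, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = "Time after bleach (s)", y = "Normalized intensity",
      subtitle = sprintf("%s fit: t1/2 = %.0f ms, R² = %.4f",
                         gsub("_", "-", object$model),
                         1000 * object$t_half, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP trace
#'
#' @param object A `frap_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_trace <- function(object, ...) {
  ycol <- if ("normalized" %in% names(object)) "normalized" else "intensity"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Time (s)", y = ycol) +
    ggplot2::theme_minimal()
  idx <- bleach_index(object)
  if (!is.na(idx)) {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                                 colour = "#b2182b")
  }
  p
}
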