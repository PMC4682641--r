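#' Geometry for a line-scan experiment
#'
#' Places the probed binding region at the nucleus centre, on the scanned
#' line (the x axis through the centre), with the remaining foci away from
#' the line.
#'
#' @param nucleus_radius Nucleus radius, um.
#' @param probe_radius Radius of the probed on-line region, um.
#' @export
linescan_geometry <- function(nucleus_radius = 1.2, probe_radius = 0.2) {
  nucleus_geometry(
    nucleus_radius = nucleus_radius,
    foci = tibble(
      focus = 1:3,
      x = c(0, -0.55, 0.55) * nucleus_radius,
      y = c(0, 0.55, 0.55) * nucleus_radius,
      z = 0,
      radius = c(probe_radius, 0.15, 0.15)
    )
  )
}

#' Imaging configuration for high-speed line scans
#'
#' Nominal 2 ms sampling along a single line.
#' @param n_frames Number of line acquisitions.
#' @param bleach_frame First post-bleach sample index.
#' @param ... Passed to [imaging_config()].
#' @export
linescan_imaging <- function(n_frames = 700, bleach_frame = 101, ...) {
  imaging_config(
    frame_interval = 0.002, n_frames = n_frames,
    bleach_duration = 0.002, bleach_frame = bleach_frame,
    bleach_radius = 0.2, ...
  )
}

#' Simulate a line-scan FRAP experiment
#'
#' Renders fluorescence intensities along a line through the nucleus at
#' ~2 ms resolution for a bleached nucleus and an unbleached control nucleus
#' generated from the same configuration with a distinct seed. The bleach
#' region is the interval of line positions within the bleach radius of the
#' probed region's centre.
#'
#' @param config A [kinetic_config()].
#' @param geometry A [linescan_geometry()] (the line is the x axis, y = z = 0).
#' @param imaging A [linescan_imaging()].
#' @param seed Integer seed (control nucleus uses `seed + 1`).
#' @param bleach Apply the bleach pulse to the frap nucleus.
#' @return A list of class `linescan_series`: `scans` (tibble: `series`,
#'   `position`, `time`, `intensity`), `positions` (um), `bleach_positions`
#'   (0-based indices of the bleached interval), `bleach_frame`.
#' @export
simulate_linescan <- function(config, geometry = linescan_geometry(),
                              imaging = linescan_imaging(), seed = NULL,
                              bleach = TRUE) {
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- image_grid(geometry, imaging)
  if (is.null(grid)) abort("Pixel grid smaller than the nucleus.")
  ax <- grid$axis
  on_line <- abs(ax) <= geometry$nucleus_radius
  if (!any(on_line)) abort("The scanned line does not intersect the nucleus.")
  times <- frame_times(imaging)
  duration <- max(times) + imaging$frame_interval
  bleach_time <- times[imaging$bleach_frame] - imaging$bleach_duration

  render_one <- function(sd, do_bleach) {
    traj <- simulate_molecules(config, geometry, duration, seed = sd)
    if (do_bleach) {
      traj <- apply_bleach(traj, geometry, imaging, bleach_time, focus = 1)
    }
    k_foci <- nrow(geometry$foci)
    occ <- occupancy_counts(traj, times, fluorescent_only = TRUE)
    fc <- as.matrix(occ[, paste0("CHROM_", seq_len(k_foci))])
    pool <- occ$FREE + occ$RNA
    # 1D rendering: each focus is a normalized Gaussian along x, attenuated
    # by its off-line distance; the pool is uniform along the chord
    prof <- matrix(0, length(ax), length(times))
    n_line <- sum(on_line)
    for (j in seq_len(k_foci)) {
      s <- geometry$foci$radius[j]
      off <- exp(-(geometry$foci$y[j]^2 + geometry$foci$z[j]^2) / (2 * s^2))
      if (off < 1e-6) next
      kern <- exp(-(ax - geometry$foci$x[j])^2 / (2 * s^2))
      kern <- kern / sum(kern)
      prof <- prof + imaging$gain * off * kern %o% fc[, j]
    }
    prof[on_line, ] <- prof[on_line, ] +
      imaging$gain * rep(1 / n_line, n_line) %o% pool
    if (imaging$noise_model == "poisson") {
      prof[] <- rpois(length(prof), prof)
    }
    prof
  }

  base_seed <- seed %||% sample.int(.Machine$integer.max / 2, 1)
  frap <- render_one(base_seed, do_bleach = bleach)
  ctrl <- render_one(base_seed + 1L, do_bleach = FALSE)

  centre_idx <- which.min(abs(ax - geometry$foci$x[1]))
  in_bleach <- which(abs(ax - geometry$foci$x[1]) <= imaging$bleach_radius)

  long <- function(mat, id) {
    tibble(
      series = id,
      position = rep(seq_along(ax) - 1L, times = length(times)),
      time = rep(times, each = length(ax)),
      intensity = as.vector(mat)
    )
  }
  structure(
    list(
      scans = dplyr::bind_rows(long(frap, "frap"), long(ctrl, "ctrl")),
      positions = ax,
      bleach_positions = in_bleach - 1L,
      bleach_frame = imaging$bleach_frame,
      frame_interval = imaging$frame_interval
    ),
    class = "linescan_series"
  )
}

#' Control-normalized relative intensity of the bleached region
#'
#' Region mean (over the bleach interval) of the frap series divided by the
#' time-matched region mean of the control series, scaled so the pre-bleach
#' mean equals 1. Shared multiplicative illumination drift cancels exactly in
#' the ratio.
#'
#' @param series A `linescan_series`, or a tibble like its `scans` element.
#' @param bleach_positions 0-based position indices of the bleached region
#'   (taken from the series when available).
#' @param bleach_frame First post-bleach sample (1-based; taken from the
#'   series when available).
#' @return Tibble with columns `time`, `relative`, and attribute
#'   `bleach_frame`.
#' @export
relative_intensity <- function(series, bleach_positions = NULL,
                               bleach_frame = NULL) {
  if (inherits(series, "linescan_series")) {
    bleach_positions <- bleach_positions %||% series$bleach_positions
    bleach_frame <- bleach_frame %||% series$bleach_frame
    scans <- series$scans
  } else {
    scans <- as_tibble(series)
  }
  if (is.null(bleach_positions)) abort("Supply the bleached position interval.")
  region <- scans |>
    dplyr::filter(.data$position %in% bleach_positions) |>
    dplyr::group_by(.data$series, .data$time) |>
    dplyr::summarise(value = mean(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "series", values_from = "value")
  if (!all(c("frap", "ctrl") %in% names(region))) {
    abort("Need both a 'frap' and a 'ctrl' series.")
  }
  if (any(region$ctrl <= 0)) abort("Control region mean must stay > 0.")
  rel <- region$frap / region$ctrl
  tt <- region$time
  ord <- order(tt)
  rel <- rel[ord]
  tt <- tt[ord]
  bleach_frame <- bleach_frame %||% (which.min(diff(rel)) + 1L)
  pre <- mean(rel[seq_len(bleach_frame - 1)])
  out <- tibble(time = tt, relative = rel / pre)
  attr(out, "bleach_frame") <- bleach_frame
  out
}

#' Gliding (centred moving) average
#'
#' Centred moving mean with truncated (shrinking) windows at the edges, so
#' the output has the same length as the input and no values are fabricated
#' at the boundaries. For even windows the extra point is taken on the left.
#'
#' @param x Numeric vector.
#' @param window Window length (>= 1, <= length of `x`).
#' @return Smoothed numeric vector.
#' @export
gliding_average <- function(x, window = 40) {
  n <- length(x)
  if (window < 1) abort("`window` must be >= 1.")
  if (window > n) abort("`window` exceeds the series length.")
  left <- ceiling((window - 1) / 2)
  right <- floor((window - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Half-recovery time from a line-scan relative curve
#'
#' Fits `y(t) = y0 + a (1 - exp(-b t))` to the post-bleach segment of the
#' relative curve and reports `1000 ln 2 / b`. The offset `y0` absorbs the
#' signal that survives the bleach plus the freely diffusing pool, which
#' re-equilibrates within one 2 ms sample; `y0` and `a` are profiled in
#' closed form, so only `b` is searched. The curve is fitted unsmoothed: a
#' centred gliding average preserves an exponential's rate in the interior
#' but distorts the samples nearest the bleach, exactly where a fast
#' recovery carries its information ([gliding_average()] remains the display
#' convention).
#'
#' @param rel Output of [relative_intensity()] (columns `time`, `relative`).
#' @param window Plateau window (samples) used to check that the region
#'   recovers at all.
#' @param bleach_frame First post-bleach sample; taken from the curve's
#'   attribute when absent.
#' @return Half-recovery time in ms.
#' @export
linescan_halftime <- function(rel, window = 40, bleach_frame = NULL) {
  bleach_frame <- bleach_frame %||% attr(rel, "bleach_frame")
  if (is.null(bleach_frame)) abort("Bleach sample unknown.")
  post <- seq(bleach_frame, nrow(rel))
  tt <- rel$time[post] - rel$time[bleach_frame]
  vv <- rel$relative[post]
  head_mean <- mean(utils::head(vv, max(5, window %/% 4)))
  tail_mean <- mean(utils::tail(vv, max(5, window %/% 2)))
  if (!is.finite(tail_mean) || tail_mean - head_mean < 0.02) {
    abort("No recovery: the bleached region does not regain fluorescence.")
  }
  fit <- fit_offset_exponential(tt, vv)
  if (fit$a < 0.02) abort("No recovery: the bleached region does not regain fluorescence.")
  1000 * log(2) / fit$b
}

# y(t) = y0 + a (1 - exp(-b t)); y0 and a profiled, b searched on a log grid
# with golden-section refinement
fit_offset_exponential <- function(times, values, b_range = c(1e-2, 1e3),
                                   n_scan = 300) {
  profile_b <- function(b) {
    m <- 1 - exp(-b * times)
    mm <- mean(m)
    vm <- mean(values)
    sxx <- sum((m - mm)^2)
    if (sxx < 1e-12) return(list(a = 0, y0 = vm, sse = sum((values - vm)^2)))
    a <- sum((m - mm) * (values - vm)) / sxx
    y0 <- vm - a * mm
    list(a = a, y0 = y0, sse = sum((values - y0 - a * m)^2))
  }
  grid_b <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = n_scan))
  sse <- vapply(grid_b, function(b) profile_b(b)$sse, numeric(1))
  k <- which.min(sse)
  opt <- optimize(function(lg) profile_b(exp(lg))$sse,
    lower = log(grid_b[max(1, k - 1)]),
    upper = log(grid_b[min(n_scan, k + 1)]), tol = 1e-12
  )
  b <- exp(opt$minimum)
  c(profile_b(b), list(b = b))
}

#' Plot a line-scan series as a kymograph
#'
#' @param object A `linescan_series`.
#' @param ... Unused.
#' @export
autoplot.linescan_series <- function(object, ...) {
  ggplot2::ggplot(object$scans,
                  ggplot2::aes(x = .data$time, y = .data$position,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~ .data$series) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time (s)", y = "Position (px)") +
    ggplot2::theme_minimal()
}
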