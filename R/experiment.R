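#' Simulate one complete FRAP experiment
#'
#' Runs the full generative chain: stochastic molecule trajectories at steady
#' state, a diffraction-limited bleach pulse on the chosen focus ending
#' exactly at the acquisition time of `imaging$bleach_frame`, and rendering
#' into a pre-acquisition z-stack, the single-plane time series, and a
#' post-acquisition z-stack, together with the ground truth the analysis
#' should recover.
#'
#' @param config A [kinetic_config()].
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()].
#' @param seed Integer seed (drives trajectories, bleach, drift, and noise).
#' @param bleach_focus Index of the bleached focus, or `NULL` for an
#'   unbleached control cell.
#' @return A list of class `frap_experiment`: `pre`, `timeseries`, `post`,
#'   `counts`, `trajectory`, `truth` (a [ground_truth()]), and the ROIs for
#'   the bleached locus and nucleus in pixel coordinates.
#' @export
simulate_frap_experiment <- function(config,
                                     geometry = nucleus_geometry(),
                                     imaging = imaging_config(),
                                     seed = NULL,
                                     bleach_focus = 1) {
  if (!is.null(seed)) withr::local_seed(seed)
  times <- frame_times(imaging)
  duration <- max(times) + imaging$frame_interval
  bleach_time <- times[imaging$bleach_frame] - imaging$bleach_duration

  traj <- simulate_molecules(config, geometry, duration)
  if (!is.null(bleach_focus)) {
    traj <- apply_bleach(traj, geometry, imaging, bleach_time, focus = bleach_focus)
  }
  rendered <- render_timeseries(traj, geometry, imaging)

  bs <- bleach_spec(
    focus = bleach_focus %||% 1L,
    pool_fraction = pool_bleach_fraction(geometry, imaging$bleach_radius)
  )
  structure(
    c(rendered, list(
      trajectory = traj,
      truth = ground_truth(config, geometry, bs),
      locus_roi = focus_roi(geometry, imaging, bleach_focus %||% 1L),
      nucleus_roi = nucleus_roi(geometry, imaging)
    )),
    class = "frap_experiment"
  )
}

#' Pixel-space ROIs for simulated geometry
#'
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()].
#' @param focus Focus index.
#' @param radius_um ROI radius in um (default: 2x the focus radius, capturing
#'   the rendered spot).
#' @param label ROI label.
#' @export
focus_roi <- function(geometry, imaging, focus = 1, radius_um = NULL,
                      label = "frap") {
  radius_um <- radius_um %||% (2 * geometry$foci$radius[focus])
  centre <- um_to_pixel(geometry, imaging,
                        geometry$foci$x[focus], geometry$foci$y[focus])
  roi_circle(centre, radius_um / imaging$pixel_size, label = label)
}

#' @rdname focus_roi
#' @export
nucleus_roi <- function(geometry, imaging) {
  centre <- um_to_pixel(geometry, imaging, 0, 0)
  roi_circle(centre, geometry$nucleus_radius / imaging$pixel_size * 1.02,
             label = "nucleus")
}

#' Analyze one FRAP experiment end to end
#'
#' The fixed pipeline: extract the locus trace, subtract the background,
#' locate the bleach frame, normalize to the recovery plateau, fit the
#' requested recovery model(s), and (when pre/post stacks are available)
#' compute the whole-nucleus-corrected mobile fraction.
#'
#' @param experiment A `frap_experiment` (or a list with `timeseries`,
#'   optionally `pre`/`post`, `locus_roi`, `nucleus_roi`).
#' @param model Passed to [fit_recovery()].
#' @return A list of class `frap_analysis` with `trace`, `fit` (or
#'   `selection`), and `mobile_fraction` (or `NULL`).
#' @export
analyze_frap <- function(experiment, model = "one") {
  trace <- extract_trace(experiment$timeseries, experiment$locus_roi) |>
    subtract_background() |>
    detect_bleach_frame()
  norm <- normalize_trace(trace)
  fit <- fit_recovery(norm, model = model)
  mf <- NULL
  if (!is.null(experiment$pre) && !is.null(experiment$post)) {
    mf <- corrected_mobile_fraction(
      trace, experiment$pre, experiment$post,
      nucleus_roi = experiment$nucleus_roi,
      locus_roi = experiment$locus_roi
    )
  }
  structure(
    list(trace = norm, fit = fit, mobile_fraction = mf),
    class = "frap_analysis"
  )
}

#' Simulate and analyze a cohort of FRAP experiments
#'
#' Simulates `n` independent experiments, normalizes each trace, averages
#' the aligned traces, and fits the mean recovery curve; per-experiment fits
#' are returned as records for cohort statistics.
#'
#' @inheritParams simulate_frap_experiment
#' @param n Number of experiments.
#' @param model Model for the averaged-curve fit.
#' @return A list of class `frap_cohort`: `mean_curve`, `mean_fit`,
#'   `records` ([experiment_records()]), and `traces`.
#' @export
simulate_frap_cohort <- function(config, geometry = nucleus_geometry(),
                                 imaging = imaging_config(), n = 31,
                                 seed = NULL, model = "one") {
  if (!is.null(seed)) withr::local_seed(seed)
  seeds <- sample.int(2^30, n)
  runs <- purrr::map(seeds, function(sd) {
    exp_i <- simulate_frap_experiment(config, geometry, imaging, seed = sd)
    trace <- extract_trace(exp_i$timeseries, exp_i$locus_roi) |>
      subtract_background() |>
      detect_bleach_frame() |>
      normalize_trace()
    fit_i <- fit_recovery(trace, model = "one")
    list(trace = trace, t_half_ms = halftime_from_curve(fit_i))
  })
  traces <- purrr::map(runs, "trace")
  mean_curve <- average_traces(traces)
  mean_fit <- fit_recovery(mean_curve, model = model)
  records <- experiment_records(
    experiment_id = sprintf("sim%03d", seq_len(n)),
    t_half_ms = purrr::map_dbl(runs, "t_half_ms")
  )
  structure(
    list(
      mean_curve = mean_curve, mean_fit = mean_fit,
      records = records, traces = traces,
      truth = ground_truth(config, geometry, bleach_spec(
        pool_fraction = pool_bleach_fraction(geometry, imaging$bleach_radius)
      ))
    ),
    class = "frap_cohort"
  )
}
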