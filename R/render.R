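#' Render a trajectory into image stacks
#'
#' Produces the three acquisitions of a bleach experiment: a whole-nucleus
#' z-stack before the time series, the single-plane time series itself, and a
#' z-stack after it. Each focus is rendered as a Gaussian spot whose planar
#' amplitude is attenuated by `exp(-dz^2 / (2 sigma_axial^2))` under an
#' Ornstein-Uhlenbeck axial drift started in focus (z = 0); the diffusing
#' pool (FREE + RNA) is rendered as uniform background inside the nucleus
#' mask. Per-frame acquisition photobleaching is applied multiplicatively and
#' Poisson noise last. The z-stacks split each focus across planes with
#' normalized plane weights, so the stack sum is invariant to axial drift by
#' construction.
#'
#' @param traj A (typically bleached) `molecule_trajectory`.
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()].
#' @param seed Optional integer seed for drift and noise.
#' @return A list of class `rendered_experiment` with elements `pre`,
#'   `timeseries`, `post` (each an [image_stack()]) plus the noise-free
#'   per-frame fluorescent counts used (`counts`, a tibble).
#' @export
render_timeseries <- function(traj, geometry, imaging, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  times <- frame_times(imaging)
  if (max(times) > attr(traj, "duration") + 1e-9) {
    abort("Trajectory does not cover the imaging window.")
  }
  grid <- image_grid(geometry, imaging)
  if (is.null(grid)) abort("Pixel grid smaller than the nucleus.")
  k_foci <- nrow(geometry$foci)

  occ <- occupancy_counts(traj, times, fluorescent_only = TRUE)
  focus_counts <- as.matrix(occ[, paste0("CHROM_", seq_len(k_foci))])
  pool_counts <- occ$FREE + occ$RNA

  # OU axial drift per focus, started at z = 0
  z <- matrix(0, length(times), k_foci)
  if (imaging$z_drift_sigma > 0) {
    a <- exp(-imaging$frame_interval / imaging$z_drift_tau)
    s_step <- imaging$z_drift_sigma * sqrt(1 - a^2)
    for (i in seq_along(times)[-1]) {
      z[i, ] <- a * z[i - 1, ] + s_step * rnorm(k_foci)
    }
  }
  atten <- exp(-z^2 / (2 * imaging$psf_axial_sigma^2))

  acq <- (1 - imaging$acquisition_bleach_rate)^(seq_along(times) - 1)
  frames <- lapply(seq_along(times), function(i) {
    render_plane(grid, geometry, imaging,
      focus_amp = imaging$gain * focus_counts[i, ] * atten[i, ] * acq[i],
      pool_amp = imaging$gain * pool_counts[i] * acq[i]
    )
  })
  frames <- maybe_poisson(frames, imaging)
  ts <- image_stack(
    simplify2array_frames(frames),
    frame_interval = imaging$frame_interval,
    pixel_size = imaging$pixel_size, role = "timeseries"
  )

  pre <- render_zstack(traj, geometry, imaging, grid, at_time = 0)
  post <- render_zstack(traj, geometry, imaging, grid,
    at_time = max(times),
    acq_factor = acq[length(acq)]
  )
  structure(
    list(
      pre = pre, timeseries = ts, post = post,
      counts = dplyr::bind_cols(occ,
        tibble(attenuation_1 = atten[, 1], acquisition_factor = acq)
      )
    ),
    class = "rendered_experiment"
  )
}

image_grid <- function(geometry, imaging) {
  half <- geometry$nucleus_radius * 1.15
  n_px <- ceiling(2 * half / imaging$pixel_size)
  ax <- (seq_len(n_px) - (n_px + 1) / 2) * imaging$pixel_size
  if (max(ax) < geometry$nucleus_radius) return(NULL)
  mask <- outer(ax^2, ax^2, `+`) <= geometry$nucleus_radius^2 # rows = y, cols = x
  list(axis = ax, n_px = n_px, mask = mask, n_mask = sum(mask))
}

# one plane: Gaussian focus kernels (normalized to unit sum) + uniform pool
render_plane <- function(grid, geometry, imaging, focus_amp, pool_amp) {
  img <- matrix(0, grid$n_px, grid$n_px)
  if (pool_amp > 0) img[grid$mask] <- pool_amp / grid$n_mask
  for (j in seq_len(nrow(geometry$foci))) {
    if (focus_amp[j] <= 0) next
    s <- geometry$foci$radius[j]
    ky <- exp(-(grid$axis - geometry$foci$y[j])^2 / (2 * s^2))
    kx <- exp(-(grid$axis - geometry$foci$x[j])^2 / (2 * s^2))
    kern <- ky %o% kx
    img <- img + focus_amp[j] * kern / sum(kern)
  }
  img
}

render_zstack <- function(traj, geometry, imaging, grid, at_time,
                          acq_factor = 1) {
  k_foci <- nrow(geometry$foci)
  occ <- occupancy_counts(traj, at_time, fluorescent_only = TRUE)
  focus_counts <- as.numeric(occ[1, paste0("CHROM_", seq_len(k_foci))])
  pool_count <- occ$FREE[1] + occ$RNA[1]
  np <- imaging$zstack$n_planes
  zp <- (seq_len(np) - (np + 1) / 2) * imaging$zstack$spacing
  # normalized plane weights: the stack sum of each focus equals its count
  wgt <- vapply(geometry$foci$z, function(zf) {
    a <- exp(-(zp - zf)^2 / (2 * imaging$psf_axial_sigma^2))
    a / sum(a)
  }, numeric(np))
  planes <- lapply(seq_len(np), function(p) {
    render_plane(grid, geometry, imaging,
      focus_amp = imaging$gain * focus_counts * wgt[p, ] * acq_factor,
      pool_amp = imaging$gain * pool_count / np * acq_factor
    )
  })
  planes <- maybe_poisson(planes, imaging)
  image_stack(simplify2array_frames(planes),
    frame_interval = NA_real_, pixel_size = imaging$pixel_size,
    z_spacing = imaging$zstack$spacing,
    role = if (at_time == 0) "prestack" else "poststack"
  )
}

maybe_poisson <- function(frames, imaging) {
  if (imaging$noise_model != "poisson") return(frames)
  lapply(frames, function(f) {
    out <- f
    out[] <- rpois(length(f), f)
    out
  })
}

simplify2array_frames <- function(frames) {
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  arr
}
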