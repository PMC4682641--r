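# Small shared fixtures. Tests that need statistical power build their own
# larger configurations.

small_config <- function(k_off = 1.3, bound = 0.5, n = 400, ...) {
  config_two_state(k_off, bound_fraction = bound, n_molecules = n, ...)
}

small_geometry <- function() {
  nucleus_geometry(
    nucleus_radius = 1.0,
    foci = tibble::tibble(
      x = c(0.45, -0.45), y = c(0.3, 0.3), z = 0, radius = 0.12
    )
  )
}

fast_imaging <- function(noise_model = "none", ...) {
  imaging_config(n_frames = 40, bleach_frame = 6, noise_model = noise_model,
                 ...)
}

# uniform-intensity synthetic stack
uniform_stack <- function(value = 7, n_frames = 4, ny = 8, nx = 8,
                          role = "timeseries") {
  image_stack(array(value, dim = c(n_frames, ny, nx)),
    frame_interval = 0.06, pixel_size = 0.08, role = role
  )
}

# one FLIP replicate: bleached cell plus an unbleached control cell
flip_replicate <- function(cfg, geo, img, seed) {
  e <- simulate_frap_experiment(cfg, geo, img, seed = seed)
  ctrl <- simulate_frap_experiment(cfg, geo, img, seed = seed + 10000,
                                   bleach_focus = NULL)
  rois <- list(
    focus_roi(geo, img, 1, label = "frap"),
    focus_roi(geo, img, 2, label = "flip"),
    focus_roi(geo, img, 3, label = "flip")
  )
  crois <- list(list(
    focus_roi(geo, img, 2, label = "control"),
    focus_roi(geo, img, 3, label = "control")
  ))
  flip_analysis(e$timeseries, rois, list(ctrl$timeseries), crois)
}

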