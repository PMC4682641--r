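#' @section Kinetic states:
#' Molecules exchange among three states: `FREE` (diffusing nucleoplasmic
#' pool), `CHROM` (bound to an H3K9-methylated chromatin focus), and `RNA`
#' (bound to nucleoplasmic heterochromatic RNA). RNA-bound molecules do not
#' contribute to focus signal.
#' @name kinetic-states
#' @keywords internal
NULL

KINETIC_STATES <- c("FREE", "CHROM", "RNA")

#' Build a state-transition rate matrix
#'
#' Constructs the 3x3 matrix of first-order exchange rates (1/s) among the
#' `FREE`, `CHROM`, and `RNA` states. Entry `[i, j]` is the rate of leaving
#' state `i` for state `j`; the diagonal is unused and kept at zero.
#'
#' @param free_to_chrom,chrom_to_free,free_to_rna,rna_to_free,chrom_to_rna,rna_to_chrom
#'   Non-negative rates in 1/s.
#' @return A named 3x3 numeric matrix.
#' @export
#' @examples
#' exchange_rates(free_to_chrom = 3, chrom_to_free = 1.3)
exchange_rates <- function(free_to_chrom = 0, chrom_to_free = 0,
                           free_to_rna = 0, rna_to_free = 0,
                           chrom_to_rna = 0, rna_to_chrom = 0) {
  q <- matrix(0, 3, 3, dimnames = list(KINETIC_STATES, KINETIC_STATES))
  q["FREE", "CHROM"] <- free_to_chrom
  q["CHROM", "FREE"] <- chrom_to_free
  q["FREE", "RNA"] <- free_to_rna
  q["RNA", "FREE"] <- rna_to_free
  q["CHROM", "RNA"] <- chrom_to_rna
  q["RNA", "CHROM"] <- rna_to_chrom
  if (any(q < 0) || any(!is.finite(q))) {
    abort("All exchange rates must be finite and >= 0.")
  }
  q
}

check_rate_matrix <- function(rate_matrix) {
  if (!is.matrix(rate_matrix) || !identical(dim(rate_matrix), c(3L, 3L))) {
    abort("`rate_matrix` must be a 3x3 matrix over states FREE, CHROM, RNA.")
  }
  if (is.null(dimnames(rate_matrix))) {
    dimnames(rate_matrix) <- list(KINETIC_STATES, KINETIC_STATES)
  }
  rate_matrix <- rate_matrix[KINETIC_STATES, KINETIC_STATES]
  diag(rate_matrix) <- 0
  if (any(rate_matrix < 0) || any(!is.finite(rate_matrix))) {
    abort("All exchange rates must be finite and >= 0.")
  }
  rate_matrix
}

#' Kinetic model configuration
#'
#' Bundles everything the simulator needs to know about the molecules: how
#' many there are, how they exchange among the free, chromatin-bound, and
#' RNA-bound states, how chromatin binding is distributed over foci, what
#' share of each focus is permanently immobile, and how efficient the bleach
#' pulse is.
#'
#' @param n_molecules Total number of molecules (immobile ones included).
#' @param rate_matrix 3x3 matrix from [exchange_rates()]; entry `[i, j]` is
#'   the i -> j rate in 1/s, diagonal unused.
#' @param focus_weights Relative chromatin-binding propensity per focus;
#'   normalized to sum to 1.
#' @param immobile_fraction Immobile share of each focus's chromatin-bound
#'   fluorescence: the proportion of a focus's steady-state signal carried by
#'   molecules that never exchange (exit rate 0). The ground-truth mobile
#'   fraction of a bleached focus is `1 - immobile_fraction`.
#' @param bleach_efficiency Probability that a molecule inside the bleach
#'   region during the bleach window loses fluorescence.
#' @return An object of class `kinetic_config`.
#' @export
#' @examples
#' kinetic_config(rate_matrix = exchange_rates(3, 1.3))
kinetic_config <- function(n_molecules = 10000,
                           rate_matrix = exchange_rates(),
                           focus_weights = c(1, 1, 1),
                           immobile_fraction = 0,
                           bleach_efficiency = 1) {
  rate_matrix <- check_rate_matrix(rate_matrix)
  if (n_molecules < 1) abort("`n_molecules` must be >= 1.")
  if (any(focus_weights < 0) || sum(focus_weights) <= 0) {
    abort("`focus_weights` must be non-negative and sum to a positive value.")
  }
  if (immobile_fraction < 0 || immobile_fraction > 1) {
    abort("`immobile_fraction` must lie in [0, 1].")
  }
  if (bleach_efficiency <= 0 || bleach_efficiency > 1) {
    abort("`bleach_efficiency` must lie in (0, 1].")
  }
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      states = KINETIC_STATES,
      rate_matrix = rate_matrix,
      focus_weights = focus_weights / sum(focus_weights),
      immobile_fraction = immobile_fraction,
      bleach_efficiency = bleach_efficiency
    ),
    class = "kinetic_config"
  )
}

#' Stationary distribution of the mobile three-state chain
#'
#' Solves the global balance equations `pi Q = 0`, `sum(pi) = 1` for the
#' continuous-time chain over FREE, CHROM, RNA. States with no in- or
#' out-rates receive zero mass; if no state exchanges at all the distribution
#' is undefined and an error is raised.
#'
#' @param rate_matrix 3x3 rate matrix (see [exchange_rates()]).
#' @return Named numeric vector of stationary occupancies.
#' @export
stationary_distribution <- function(rate_matrix) {
  q <- check_rate_matrix(rate_matrix)
  active <- which(rowSums(q) > 0 | colSums(q) > 0)
  if (length(active) == 0) {
    abort("All rates are zero: the stationary distribution is undefined.")
  }
  qa <- q[active, active, drop = FALSE]
  gen <- qa
  diag(gen) <- -rowSums(qa)
  # pi G = 0 with sum constraint: replace one balance equation
  a <- t(gen)
  a[nrow(a), ] <- 1
  b <- c(rep(0, nrow(a) - 1), 1)
  pi_active <- solve(a, b)
  pi_full <- setNames(numeric(3), KINETIC_STATES)
  pi_full[active] <- pi_active
  if (any(pi_full < -1e-10)) abort("Rate matrix yields no valid stationary distribution.")
  pmax(pi_full, 0) / sum(pmax(pi_full, 0))
}

#' Number of immobile molecules implied by a config
#'
#' The immobile fraction is defined as the immobile share of each focus's
#' chromatin-bound fluorescence; given the mobile stationary chromatin
#' occupancy `pi_C`, the implied immobile count solves
#' `I / (I + (N - I) pi_C) = phi`.
#' @keywords internal
n_immobile <- function(config) {
  phi <- config$immobile_fraction
  if (phi <= 0) return(0L)
  pi_c <- stationary_distribution(config$rate_matrix)[["CHROM"]]
  if (pi_c <= 0) abort("Immobile fraction > 0 requires nonzero chromatin occupancy.")
  n <- config$n_molecules
  as.integer(round(n * phi * pi_c / (1 - phi * (1 - pi_c))))
}

#' Nuclear geometry
#'
#' Describes the nucleus (a sphere) and its chromatin foci. Fission yeast
#' nuclei carry two to six bright heterochromatic foci, most commonly three.
#'
#' @param nucleus_radius Nucleus radius in micrometres.
#' @param foci Data frame with columns `x`, `y`, `z` (centre, um) and
#'   `radius` (um); one row per focus, 2 to 6 rows.
#' @return An object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(nucleus_radius = 1.2,
                             foci = default_foci(nucleus_radius)) {
  foci <- as_tibble(foci)
  stopifnot(all(c("x", "y", "z", "radius") %in% names(foci)))
  k <- nrow(foci)
  if (k < 2 || k > 6) abort("Geometry must contain between 2 and 6 foci.")
  d_centre <- sqrt(foci$x^2 + foci$y^2 + foci$z^2)
  if (any(d_centre + foci$radius > nucleus_radius + 1e-9)) {
    abort("All foci must lie inside the nucleus.")
  }
  dd <- as.matrix(stats::dist(foci[, c("x", "y", "z")]))
  rr <- outer(foci$radius, foci$radius, `+`)
  diag(dd) <- Inf
  if (any(dd < rr)) abort("Foci must be pairwise non-overlapping.")
  structure(
    list(nucleus_radius = nucleus_radius, foci = foci),
    class = "nucleus_geometry"
  )
}

#' @rdname nucleus_geometry
#' @export
default_foci <- function(nucleus_radius = 1.2) {
  r <- 0.55 * nucleus_radius
  ang <- c(90, 210, 330) * pi / 180
  tibble(
    focus = 1:3,
    x = r * cos(ang), y = r * sin(ang), z = 0,
    radius = 0.15
  )
}

#' Imaging configuration
#'
#' Acquisition parameters for the rendered experiment: a 120-frame single
#' confocal plane time series at 60 ms intervals with a diffraction-limited
#' 20 ms bleach pulse, bracketed by whole-nucleus z-stacks.
#'
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames in the planar time series.
#' @param bleach_duration Bleach pulse length, s. The pulse ends exactly at
#'   the acquisition time of `bleach_frame`, so that frame is the first
#'   post-bleach sample.
#' @param bleach_frame Index (1-based) of the first post-bleach frame.
#' @param bleach_center Bleach spot centre `c(x, y, z)` in um, or `NULL` to
#'   centre the spot on the bleached focus at simulation time.
#' @param bleach_radius Bleach spot radius, um (diffraction-limited).
#' @param pixel_size Pixel pitch, um.
#' @param psf_axial_sigma Axial Gaussian width of the detection PSF, um.
#' @param z_drift_sigma,z_drift_tau Stationary standard deviation (um) and
#'   relaxation time (s) of the Ornstein-Uhlenbeck axial drift of each focus.
#'   Drift starts at z = 0 (the locus is focused at acquisition start).
#' @param acquisition_bleach_rate Fraction of fluorescence lost per acquired
#'   frame (0 disables acquisition photobleaching).
#' @param noise_model `"poisson"` or `"none"`.
#' @param gain Expected detector counts per fluorescent molecule.
#' @param zstack List with `n_planes` and `spacing` (um) for the pre/post
#'   whole-nucleus stacks.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(frame_interval = 0.060,
                           n_frames = 120,
                           bleach_duration = 0.020,
                           bleach_frame = 11,
                           bleach_center = NULL,
                           bleach_radius = 0.15,
                           pixel_size = 0.08,
                           psf_axial_sigma = 0.4,
                           z_drift_sigma = 0,
                           z_drift_tau = 2,
                           acquisition_bleach_rate = 0,
                           noise_model = c("poisson", "none"),
                           gain = 10,
                           zstack = list(n_planes = 13, spacing = 0.3)) {
  noise_model <- match.arg(noise_model)
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  if (bleach_radius <= 0) abort("`bleach_radius` must be > 0.")
  if (bleach_frame < 2 || bleach_frame > n_frames) {
    abort("`bleach_frame` must leave at least one pre-bleach frame.")
  }
  structure(
    list(
      frame_interval = frame_interval, n_frames = as.integer(n_frames),
      bleach_duration = bleach_duration, bleach_frame = as.integer(bleach_frame),
      bleach_center = bleach_center, bleach_radius = bleach_radius,
      pixel_size = pixel_size, psf_axial_sigma = psf_axial_sigma,
      z_drift_sigma = z_drift_sigma, z_drift_tau = z_drift_tau,
      acquisition_bleach_rate = acquisition_bleach_rate,
      noise_model = noise_model, gain = gain, zstack = zstack
    ),
    class = "imaging_config"
  )
}

frame_times <- function(imaging) {
  (seq_len(imaging$n_frames) - 1) * imaging$frame_interval
}

#' Bleach specification
#'
#' Identifies the bleached focus and the effective bleach of the diffusing
#' pool (the share of FREE/RNA molecules caught inside the diffraction-limited
#' spot, by default the spot-to-nucleus volume ratio).
#'
#' @param focus Index of the bleached focus.
#' @param efficiency Bleach probability inside the spot; defaults to the
#'   config's `bleach_efficiency` where used.
#' @param pool_fraction Fraction of pool molecules inside the spot, or `NULL`
#'   to derive it from geometry.
#' @export
bleach_spec <- function(focus = 1, efficiency = NULL, pool_fraction = NULL) {
  structure(list(focus = as.integer(focus), efficiency = efficiency,
                 pool_fraction = pool_fraction),
            class = "bleach_spec")
}

#' @rdname bleach_spec
#' @param geometry A [nucleus_geometry()].
#' @param bleach_radius Spot radius, um.
#' @export
pool_bleach_fraction <- function(geometry, bleach_radius) {
  (bleach_radius / geometry$nucleus_radius)^3
}

#' Preset: reaction-dominant two-state exchange
#'
#' A FREE <-> CHROM configuration in the reaction-dominant regime (pool much
#' larger than any single focus), where normalized recovery of a bleached
#' focus is `1 - exp(-k_off t)` to good approximation and a one-component fit
#' returns `k_off` directly.
#'
#' @param k_off Chromatin dissociation rate, 1/s.
#' @param bound_fraction Total steady-state chromatin occupancy (spread over
#'   the foci); small values keep the regime reaction-dominant.
#' @param n_molecules,immobile_fraction,bleach_efficiency Passed through to
#'   [kinetic_config()].
#' @export
config_two_state <- function(k_off, bound_fraction = 0.09, n_molecules = 10000,
                             immobile_fraction = 0, bleach_efficiency = 1) {
  if (bound_fraction <= 0 || bound_fraction >= 1) {
    abort("`bound_fraction` must lie in (0, 1).")
  }
  k_on <- k_off * bound_fraction / (1 - bound_fraction)
  kinetic_config(
    n_molecules = n_molecules,
    rate_matrix = exchange_rates(free_to_chrom = k_on, chrom_to_free = k_off),
    immobile_fraction = immobile_fraction,
    bleach_efficiency = bleach_efficiency
  )
}

#' Preset: heterochromatin-like three-state exchange
#'
#' Builds a three-state configuration whose mobile stationary occupancies are
#' `occupancy` (default 25% free, 65% chromatin-bound, 10% RNA-bound: most
#' fluorescence sits in the foci, so bleaching one of three foci removes
#' roughly a fifth to a quarter of total nuclear fluorescence) and whose rate
#' scale is calibrated so the mean-field expected half-recovery time of a
#' bleached focus equals `t_half` under `geometry`. The transition topology is
#' all-to-all with entry rates proportional to target occupancy, a modeling
#' choice that contains both the direct CHROM <-> FREE exchange and the
#' CHROM -> RNA -> FREE release cycle.
#'
#' @param t_half Target half-recovery time, s: the value a one-component fit
#'   to the mean recovery curve reports under `imaging` (the measured
#'   observable, not the exact half-crossing of the underlying curve).
#' @param occupancy Named target occupancies for FREE, CHROM, RNA.
#' @param geometry Geometry used for the calibration (default geometry).
#' @param imaging Frame grid used for the calibration.
#' @param bleach Bleach specification used for the calibration.
#' @inheritParams config_two_state
#' @export
config_heterochromatin <- function(t_half = 0.535,
                                   occupancy = c(FREE = 0.25, CHROM = 0.65, RNA = 0.10),
                                   geometry = nucleus_geometry(),
                                   imaging = imaging_config(),
                                   bleach = bleach_spec(),
                                   n_molecules = 10000,
                                   immobile_fraction = 0,
                                   bleach_efficiency = 1) {
  occupancy <- occupancy[KINETIC_STATES] / sum(occupancy)
  make_cfg <- function(m) {
    q <- m * matrix(occupancy, 3, 3, byrow = TRUE,
                    dimnames = list(KINETIC_STATES, KINETIC_STATES))
    diag(q) <- 0
    kinetic_config(
      n_molecules = n_molecules, rate_matrix = q,
      immobile_fraction = immobile_fraction,
      bleach_efficiency = bleach_efficiency
    )
  }
  th <- function(m) {
    expected_fitted_halftime(make_cfg(m), geometry, imaging, bleach) - t_half
  }
  scale <- uniroot(th, c(1e-2, 1e3), tol = 1e-6)$root
  make_cfg(scale)
}

#' Ground truth for a simulated bleach experiment
#'
#' Collects the quantities the analysis pipeline is supposed to recover from
#' data generated under `config`/`geometry`: per-state steady-state
#' occupancies (immobile molecules included), the chromatin exit rate, the
#' expected half-recovery time of the bleached focus from the mean-field
#' solution, the true mobile fraction, and the expected share of total
#' fluorescence destroyed by the bleach.
#'
#' @param config A [kinetic_config()].
#' @param geometry A [nucleus_geometry()].
#' @param bleach A [bleach_spec()].
#' @param imaging Optional [imaging_config()]; when given, the estimand of
#'   the one-component fit under that frame grid is added as
#'   `t_half_fitted` (see [expected_fitted_halftime()]).
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(config, geometry, bleach = bleach_spec(),
                         imaging = NULL) {
  pi_mob <- stationary_distribution(config$rate_matrix)
  n <- config$n_molecules
  n_imm <- n_immobile(config)
  m <- n - n_imm
  occ <- c(pi_mob * m, IMMOBILE = n_imm) / n
  q <- config$rate_matrix
  k_exit <- sum(q["CHROM", c("FREE", "RNA")])
  eff <- bleach$efficiency %||% config$bleach_efficiency
  w <- config$focus_weights[bleach$focus]
  pool_frac <- bleach$pool_fraction %||% 0
  bleached_share <- eff * (w * (pi_mob[["CHROM"]] * m + n_imm) +
    pool_frac * m * (pi_mob[["FREE"]] + pi_mob[["RNA"]])) / n
  structure(
    list(
      occupancy = occ,
      chrom_exit_rate = k_exit,
      t_half = expected_halftime(config, geometry, bleach),
      t_half_fitted = if (!is.null(imaging)) {
        expected_fitted_halftime(config, geometry, imaging, bleach)
      },
      mobile_fraction = 1 - config$immobile_fraction,
      bleached_share = unname(bleached_share)
    ),
    class = "ground_truth"
  )
}

#' Read or write a simulation configuration file
#'
#' Round-trips the kinetic, geometric, and imaging configuration through a
#' YAML file whose keys mirror the constructor arguments.
#'
#' @param path Path to a YAML file.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- raw$kinetic_config
  cfg$rate_matrix <- check_rate_matrix(
    matrix(unlist(cfg$rate_matrix), 3, 3, byrow = TRUE,
           dimnames = list(KINETIC_STATES, KINETIC_STATES))
  )
  geom <- raw$nucleus_geometry
  img <- raw$imaging_config
  list(
    kinetic_config = do.call(kinetic_config, cfg),
    nucleus_geometry = nucleus_geometry(
      nucleus_radius = geom$nucleus_radius,
      foci = as_tibble(lapply(geom$foci, unlist))
    ),
    imaging_config = do.call(imaging_config, img)
  )
}

#' @rdname read_simulation_config
#' @param config,geometry,imaging Objects to serialize.
#' @export
write_simulation_config <- function(config, geometry, imaging, path) {
  out <- list(
    kinetic_config = list(
      n_molecules = config$n_molecules,
      rate_matrix = apply(config$rate_matrix, 1, as.list, simplify = FALSE),
      focus_weights = config$focus_weights,
      immobile_fraction = config$immobile_fraction,
      bleach_efficiency = config$bleach_efficiency
    ),
    nucleus_geometry = list(
      nucleus_radius = geometry$nucleus_radius,
      foci = lapply(as.list(geometry$foci[, c("x", "y", "z", "radius")]), as.list)
    ),
    imaging_config = imaging[setdiff(names(imaging), "bleach_center")]
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
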