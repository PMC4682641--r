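#' Mean-field expected recovery curve
#'
#' Deterministic solution of the same linear exchange scheme the stochastic
#' simulator realizes. The mobile compartments (FREE, RNA, CHROM at each
#' focus) evolve under the generator built from the rate matrix and focus
#' weights; the expected fluorescent signal of the bleached focus is obtained
#' by propagating the post-bleach fluorescent mass with the matrix
#' exponential. In the reaction-dominant two-state limit (pool much larger
#' than the focus) the normalized curve reduces to `1 - exp(-k_off t)`.
#'
#' @param config A [kinetic_config()].
#' @param geometry A [nucleus_geometry()].
#' @param bleach A [bleach_spec()].
#' @param times Times (s) after the bleach at which to evaluate the curve.
#' @return Tibble with columns `time`, `focus_signal` (expected fluorescent
#'   molecule count at the bleached focus, immobile molecules included), and
#'   `normalized` (signal divided by its pre-bleach expectation).
#' @export
meanfield_recovery <- function(config, geometry, bleach = bleach_spec(),
                               times) {
  stopifnot(inherits(config, "kinetic_config"))
  k_foci <- nrow(geometry$foci)
  w <- rep_len(config$focus_weights, k_foci)
  w <- w / sum(w)
  jb <- bleach$focus
  if (jb < 1 || jb > k_foci) abort("Bleached focus index out of range.")
  eff <- bleach$efficiency %||% config$bleach_efficiency
  pool_frac <- bleach$pool_fraction %||% 0

  gen <- expanded_generator(config$rate_matrix, w)
  pi_mob <- stationary_distribution(config$rate_matrix)
  n <- config$n_molecules
  n_imm <- n_immobile(config)
  m <- n - n_imm
  imm_per_focus <- n_imm * w

  # expected mobile molecule mass per compartment, pre-bleach
  mass0 <- c(pi_mob[["FREE"]], pi_mob[["RNA"]], pi_mob[["CHROM"]] * w) * m
  # fluorescent survival per compartment after the bleach
  survive <- c(1 - pool_frac * eff, 1 - pool_frac * eff, rep(1, k_foci))
  survive[2 + jb] <- 1 - eff
  fluor0 <- mass0 * survive

  col_jb <- 2 + jb
  prop <- generator_propagator(gen)
  sig <- vapply(times, function(t) sum(fluor0 * prop(t)[, col_jb]), numeric(1))
  imm_signal <- imm_per_focus[jb] * (1 - eff)
  pre <- mass0[col_jb] + imm_per_focus[jb]
  tibble(
    time = times,
    focus_signal = sig + imm_signal,
    normalized = (sig + imm_signal) / pre
  )
}

# matrix-exponential propagator: eigendecomposition when well conditioned,
# Matrix::expm otherwise
generator_propagator <- function(gen) {
  eg <- tryCatch(eigen(gen), error = function(e) NULL)
  if (!is.null(eg) && abs(det(eg$vectors)) > 1e-10) {
    v <- eg$vectors
    vinv <- solve(v)
    vals <- eg$values
    function(t) Re(v %*% (exp(vals * t) * vinv))
  } else {
    function(t) as.matrix(Matrix::expm(gen * t))
  }
}

# generator over compartments (FREE, RNA, CHROM_1..K); entry rates into CHROM
# split by focus weight, exits identical across foci
expanded_generator <- function(rate_matrix, w) {
  q <- check_rate_matrix(rate_matrix)
  k <- length(w)
  g <- matrix(0, 2 + k, 2 + k)
  g[1, 2] <- q["FREE", "RNA"]
  g[2, 1] <- q["RNA", "FREE"]
  for (j in seq_len(k)) {
    g[1, 2 + j] <- q["FREE", "CHROM"] * w[j]
    g[2, 2 + j] <- q["RNA", "CHROM"] * w[j]
    g[2 + j, 1] <- q["CHROM", "FREE"]
    g[2 + j, 2] <- q["CHROM", "RNA"]
  }
  diag(g) <- -rowSums(g)
  g
}

#' Estimand of the one-component fit under a sampling scheme
#'
#' The infinite-data limit of the analysis pipeline: evaluates the exact
#' mean-field recovery at the post-bleach frame times, anchors it at the
#' first post-bleach sample, fits the one-component model, and returns its
#' half-recovery time. When the true recovery is multi-exponential (bright
#' foci drawing on a finite shared pool) this differs from the exact
#' half-crossing time of the curve ([expected_halftime()]); it is the value
#' an unbiased estimator of the fitted t1/2 converges to.
#'
#' @inheritParams meanfield_recovery
#' @param imaging An [imaging_config()] supplying the frame grid.
#' @return Half-recovery time in seconds.
#' @export
expected_fitted_halftime <- function(config, geometry, imaging,
                                     bleach = bleach_spec()) {
  n_post <- imaging$n_frames - imaging$bleach_frame + 1
  tt <- (seq_len(n_post) - 1) * imaging$frame_interval
  mf <- meanfield_recovery(config, geometry, bleach, tt)
  y <- mf$normalized - mf$normalized[1]
  fit <- fit_one_component(tt, y / max(y[length(y)], 1e-12))
  fit$t_half
}

#' Expected half-recovery time of the mean-field curve
#'
#' Time (from the bleach) at which the expected recovery of the bleached
#' focus reaches half of its asymptotic gain, solved by bisection on the
#' mean-field solution.
#'
#' @inheritParams meanfield_recovery
#' @param horizon Upper bracket for the search, s.
#' @return Half-recovery time in seconds.
#' @export
expected_halftime <- function(config, geometry, bleach = bleach_spec(),
                              horizon = 60) {
  value_at <- function(t) {
    meanfield_recovery(config, geometry, bleach, t)$normalized
  }
  y0 <- value_at(0)
  yinf <- value_at(horizon)
  target <- y0 + 0.5 * (yinf - y0)
  if (yinf <= y0 + 1e-12) abort("No recovery: the expected curve is flat.")
  bisect(function(t) value_at(t) - target, 0, horizon, tol = 1e-6)
}

# plain bisection root finder; f(lo) and f(hi) must bracket the root
bisect <- function(f, lo, hi, tol = 1e-9, max_iter = 200L) {
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) abort("Bisection endpoints do not bracket a root.")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  mid
}
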