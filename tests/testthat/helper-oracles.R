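# Independent oracles used across tests. These deliberately avoid the code
# paths they check: dense grid search instead of profiled optimization,
# fine-step explicit Euler integration instead of the matrix exponential.

# dense (a, b) grid search for the one-component least-squares problem
grid_search_one_component <- function(times, values, a_range = c(0.5, 1.5),
                                      b_range = c(0.1, 20), n_a = 2000,
                                      n_b = 2000) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_a)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_b)
  syy <- sum(values^2)
  best <- list(sse = Inf)
  # SSE(a, b) = Syy - 2 a Sym(b) + a^2 Smm(b): scan b, vectorize over a
  for (j in seq_len(n_b)) {
    m <- 1 - exp(-b_grid[j] * times)
    sym <- sum(values * m)
    smm <- sum(m^2)
    sse_a <- syy - 2 * a_grid * sym + a_grid^2 * smm
    i <- which.min(sse_a)
    if (sse_a[i] < best$sse) {
      best <- list(sse = sse_a[i], a = a_grid[i], b = b_grid[j],
                   da = diff(a_range) / (n_a - 1), db = diff(b_range) / (n_b - 1))
    }
  }
  best
}

# explicit Euler integration of p' = p G for the expanded compartment system
euler_recovery <- function(config, geometry, bleach, times, dt = 1e-4) {
  k_foci <- nrow(geometry$foci)
  w <- rep_len(config$focus_weights, k_foci)
  w <- w / sum(w)
  gen <- frapkin:::expanded_generator(config$rate_matrix, w)
  pi_mob <- stationary_distribution(config$rate_matrix)
  n_imm <- frapkin:::n_immobile(config)
  m <- config$n_molecules - n_imm
  eff <- bleach$efficiency %||% config$bleach_efficiency
  pool_frac <- bleach$pool_fraction %||% 0
  mass0 <- c(pi_mob[["FREE"]], pi_mob[["RNA"]], pi_mob[["CHROM"]] * w) * m
  survive <- c(1 - pool_frac * eff, 1 - pool_frac * eff, rep(1, k_foci))
  survive[2 + bleach$focus] <- 1 - eff
  p <- mass0 * survive
  col <- 2 + bleach$focus
  out <- numeric(length(times))
  t_now <- 0
  stopifnot(!is.unsorted(times))
  for (i in seq_along(times)) {
    while (t_now < times[i] - 1e-12) {
      h <- min(dt, times[i] - t_now)
      p <- p + h * as.vector(p %*% gen)
      t_now <- t_now + h
    }
    out[i] <- p[col]
  }
  imm_sig <- n_imm * w[bleach$focus] * (1 - eff)
  pre <- mass0[col] + n_imm * w[bleach$focus]
  (out + imm_sig) / pre
}

# stationary distribution by brute-force propagation of the jump chain
euler_stationary <- function(rate_matrix, t_end = 200, dt = 1e-3) {
  gen <- rate_matrix
  diag(gen) <- 0
  diag(gen) <- -rowSums(gen)
  p <- c(1, 0, 0)
  for (i in seq_len(round(t_end / dt))) p <- p + dt * as.vector(p %*% gen)
  p / sum(p)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
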