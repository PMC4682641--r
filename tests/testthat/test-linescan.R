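test_that("gliding average: identity, constants, and linear ramps", {
  x <- rep(3.5, 50)
  expect_equal(gliding_average(x, 40), x)
  y <- rnorm(30)
  expect_equal(gliding_average(y, 1), y)
  ramp <- seq(0, 10, length.out = 200)
  sm <- gliding_average(ramp, 11)
  # a centred moving mean of a line is the line (away from the edges)
  expect_equal(sm[6:195], ramp[6:195], tolerance = 1e-12)
  expect_error(gliding_average(y, 31), "exceeds")
  expect_error(gliding_average(y, 0), ">= 1")
})

test_that("smoothing commutes with affine rescaling and preserves the mean", {
  withr::with_seed(12, {
    x <- cumsum(rnorm(300))
    a <- gliding_average(2 * x + 7, 40)
    b <- 2 * gliding_average(x, 40) + 7
    expect_equal(a, b, tolerance = 1e-12)
    # interior windows are mean-preserving
    expect_equal(mean(gliding_average(x, 41)[21:280]), mean(x[21:280]),
                 tolerance = 0.2)
  })
})

test_that("relative intensity is 1 without a bleach and cancels shared drift", {
  cfg <- config_two_state(7.8, bound_fraction = 0.12, n_molecules = 3000)
  ls <- simulate_linescan(cfg, seed = 61, bleach = FALSE)
  rel <- relative_intensity(ls)
  expect_equal(mean(rel$relative), 1, tolerance = 0.05)
  # two-sample check on the per-position means of the two series
  wide <- ls$scans |>
    dplyr::filter(position %in% ls$bleach_positions) |>
    dplyr::group_by(series, position) |>
    dplyr::summarise(m = mean(intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = series, values_from = m)
  expect_gt(stats::t.test(wide$frap, wide$ctrl, paired = TRUE)$p.value, 0.01)
  # multiplying both series by the same illumination drift changes nothing
  drift <- 1 + 0.3 * sin(seq_len(nrow(ls$scans) / 2) / 37)
  scans2 <- ls$scans
  for (id in c("frap", "ctrl")) {
    sel <- scans2$series == id
    scans2$intensity[sel] <- scans2$intensity[sel] *
      rep(drift, each = length(ls$positions))[seq_len(sum(sel))]
  }
  rel2 <- relative_intensity(scans2, ls$bleach_positions, ls$bleach_frame)
  expect_equal(rel2$relative, rel$relative, tolerance = 1e-9)
})

test_that("fast two-state exchange is recovered from the line scan", {
  # average a few replicate curves, as done for published line-scan traces
  for (k in c(7.8, 14.1)) {
    cfg <- config_two_state(k, bound_fraction = 0.12, n_molecules = 10000)
    rels <- lapply(1:3, function(s) {
      relative_intensity(simulate_linescan(cfg, seed = 70 * k + s))
    })
    avg <- rels[[1]]
    avg$relative <- rowMeans(sapply(rels, function(r) r$relative))
    est <- linescan_halftime(avg)
    expect_equal(est, 1000 * log(2) / k, tolerance = 0.15)
  }
})

test_that("a frozen system never recovers and says so", {
  cfg <- kinetic_config(
    n_molecules = 3000,
    rate_matrix = exchange_rates(free_to_chrom = 50, chrom_to_free = 1e-9)
  )
  ls <- simulate_linescan(cfg, seed = 99)
  rel <- relative_intensity(ls)
  expect_error(linescan_halftime(rel), "No recovery")
  # the bleached stripe stays at its bleach depth
  post <- rel$relative[rel$time > max(rel$time) - 0.2]
  early <- rel$relative[seq(ls$bleach_frame, ls$bleach_frame + 50)]
  expect_equal(mean(post), mean(early), tolerance = 0.1)
})

test_that("kinetic regimes order their half-times as expected", {
  regimes <- c(slow = 1.296, mid = 7.8, fast = 14.1)
  img <- linescan_imaging(n_frames = 1200)
  ths <- vapply(seq_along(regimes), function(i) {
    cfg <- config_two_state(regimes[i], bound_fraction = 0.12,
                            n_molecules = 10000)
    rels <- lapply(1:2, function(s) {
      relative_intensity(simulate_linescan(cfg, imaging = img,
                                           seed = 1000 * i + s))
    })
    avg <- rels[[1]]
    avg$relative <- rowMeans(sapply(rels, function(r) r$relative))
    linescan_halftime(avg)
  }, numeric(1))
  expect_true(ths[1] > ths[2] && ths[2] > ths[3])
})

test_that("lines that miss the nucleus are rejected", {
  expect_error(linescan_geometry(nucleus_radius = 0.1),
               "foci|inside|nucleus")
})
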