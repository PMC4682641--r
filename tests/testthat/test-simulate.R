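test_that("state counts always sum to the number of molecules", {
  cfg <- kinetic_config(
    n_molecules = 600,
    rate_matrix = exchange_rates(1.7, 0.9, 0.4, 2.2, 0.6, 0.3),
    immobile_fraction = 0.2, focus_weights = c(1, 1)
  )
  traj <- simulate_molecules(cfg, small_geometry(), duration = 3, seed = 1)
  probe <- sort(c(0, runif(20, 0, 3), 3, traj$time[c(5, 50, 500)]))
  occ <- occupancy_counts(traj, probe)
  expect_true(all(occ$total == 600))
})

test_that("a frozen system never changes state", {
  cfg <- kinetic_config(n_molecules = 50, rate_matrix = exchange_rates(),
                        focus_weights = c(1, 1))
  traj <- simulate_molecules(cfg, small_geometry(), duration = 5, seed = 2,
                             initial_state = "CHROM")
  occ <- occupancy_counts(traj, c(0, 1, 2.5, 5))
  expect_true(all(occ$CHROM_1 + occ$CHROM_2 == 50))
  expect_true(all(occ$FREE == 0))
  expect_equal(nrow(traj), 50) # only the initial events exist
})

test_that("symmetric two-state exchange occupies both states equally", {
  cfg <- kinetic_config(n_molecules = 4000,
                        rate_matrix = exchange_rates(2, 2),
                        focus_weights = c(1, 1))
  traj <- simulate_molecules(cfg, small_geometry(), duration = 4, seed = 3)
  occ <- occupancy_counts(traj, seq(1, 4, by = 0.5))
  frac <- mean((occ$CHROM_1 + occ$CHROM_2) / occ$total)
  expect_lt(abs(frac - 0.5), 3 / sqrt(4000))
})

test_that("three-state occupancies match the stationary distribution", {
  q <- exchange_rates(1.7, 0.9, 0.4, 2.2, 0.6, 0.3)
  cfg <- kinetic_config(n_molecules = 10000, rate_matrix = q,
                        focus_weights = c(1, 1))
  traj <- simulate_molecules(cfg, small_geometry(), duration = 2, seed = 4)
  occ <- occupancy_counts(traj, 2)
  pi_hat <- c(occ$FREE, occ$CHROM_1 + occ$CHROM_2, occ$RNA) / 10000
  pi_true <- euler_stationary(q)
  se <- sqrt(pi_true * (1 - pi_true) / 10000)
  expect_true(all(abs(pi_hat - pi_true) < 3 * se))
})

test_that("identical config and seed give bit-identical trajectories", {
  cfg <- small_config()
  a <- simulate_molecules(cfg, small_geometry(), 3, seed = 11)
  b <- simulate_molecules(cfg, small_geometry(), 3, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  img <- fast_imaging(noise_model = "poisson")
  ra <- render_timeseries(a, small_geometry(), img, seed = 5)
  rb <- render_timeseries(b, small_geometry(), img, seed = 5)
  expect_identical(ra$timeseries$data, rb$timeseries$data)
})

test_that("negative rates and bad durations are rejected", {
  q <- exchange_rates()
  q["FREE", "CHROM"] <- -1
  expect_error(kinetic_config(rate_matrix = q), "rates")
  expect_error(
    simulate_molecules(small_config(), small_geometry(), duration = 0),
    "duration"
  )
})

test_that("bleaching the whole nucleus at full efficiency leaves nothing", {
  cfg <- small_config(n = 300)
  geo <- small_geometry()
  img <- fast_imaging(bleach_center = c(0, 0, 0), bleach_radius = 1.0)
  traj <- simulate_molecules(cfg, geo, 2, seed = 6)
  traj <- apply_bleach(traj, geo, img, bleach_time = 0.3, seed = 7)
  occ <- occupancy_counts(traj, c(0.5, 1, 2), fluorescent_only = TRUE)
  expect_true(all(occ$total == 0))
  # before the bleach everything still counts as fluorescent
  occ0 <- occupancy_counts(traj, 0.1, fluorescent_only = TRUE)
  expect_equal(occ0$total, 300)
})

test_that("fluorescence lost tracks the bleached focus's share", {
  # pool made negligible: nearly all molecules chromatin-bound on 3 equal foci
  cfg <- config_two_state(1.3, bound_fraction = 0.995, n_molecules = 6000)
  geo <- nucleus_geometry()
  img <- imaging_config()
  traj <- simulate_molecules(cfg, geo, 2, seed = 8)
  traj <- apply_bleach(traj, geo, img, bleach_time = 0.5, focus = 1, seed = 9)
  lost <- 1 - sum(attr(traj, "fluorescent")) / 6000
  expect_lt(abs(lost - 1 / 3), 0.03)
})

test_that("default-geometry bleach removes 20-35% of nuclear fluorescence", {
  cfg <- config_heterochromatin(n_molecules = 5000)
  geo <- nucleus_geometry()
  img <- imaging_config()
  traj <- simulate_molecules(cfg, geo, 2, seed = 10)
  traj <- apply_bleach(traj, geo, img, bleach_time = 0.5, focus = 1, seed = 11)
  lost <- 1 - sum(attr(traj, "fluorescent")) / 5000
  expect_gt(lost, 0.20)
  expect_lt(lost, 0.35)
})

test_that("bleach regions outside the nucleus or window are rejected", {
  cfg <- small_config()
  geo <- small_geometry()
  traj <- simulate_molecules(cfg, geo, 2, seed = 12)
  img_out <- fast_imaging(bleach_center = c(0.95, 0, 0), bleach_radius = 0.2)
  expect_error(apply_bleach(traj, geo, img_out, 0.3), "inside the nucleus")
  expect_error(apply_bleach(traj, geo, fast_imaging(), 5), "duration")
})

test_that("fluorescent molecule count is non-increasing over time", {
  cfg <- config_heterochromatin(n_molecules = 1000)
  geo <- nucleus_geometry()
  img <- imaging_config()
  traj <- simulate_molecules(cfg, geo, 7.2, seed = 13)
  traj <- apply_bleach(traj, geo, img, bleach_time = 0.58, seed = 14)
  occ <- occupancy_counts(traj, seq(0, 7.2, by = 0.3), fluorescent_only = TRUE)
  expect_true(all(diff(occ$total) <= 0))
})
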