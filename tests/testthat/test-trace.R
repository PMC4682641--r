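test_that("extract_trace averages the ROI pixels", {
  st <- uniform_stack(value = 7)
  tr <- extract_trace(st, roi_circle(c(4, 4), 2))
  expect_equal(tr$intensity, rep(7, 4))
  # a 1-pixel circle returns exactly that pixel's value
  st$data[2, 4, 5] <- 99
  tr1 <- extract_trace(st, roi_circle(c(3, 4), 0.4))
  expect_equal(tr1$intensity, st$data[, 4, 5])
  expect_error(extract_trace(uniform_stack(role = "prestack"),
                             roi_circle(c(4, 4), 2)), "time-series")
})

test_that("extracted traces are proportional to fluorescent counts", {
  cfg <- small_config(k_off = 2, bound = 0.7, n = 800)
  geo <- small_geometry()
  img <- fast_imaging() # noise-free, no drift
  e <- simulate_frap_experiment(cfg, geo, img, seed = 5)
  tr <- extract_trace(e$timeseries, e$locus_roi)
  r <- stats::cor(tr$intensity, e$counts$CHROM_1 +
    (e$counts$FREE + e$counts$RNA) * 0) # focus signal dominates the ROI
  expect_gt(r, 0.999)
})

test_that("background subtraction zeroes the minimum and ignores offsets", {
  tr <- frap_trace(1:3, (0:2) * 0.06, c(5, 2, 4))
  expect_equal(subtract_background(tr)$intensity, c(3, 0, 2))
  tr_const <- frap_trace(1:3, (0:2) * 0.06, rep(4, 3))
  expect_equal(subtract_background(tr_const)$intensity, rep(0, 3))
  withr::with_seed(1, {
    for (i in 1:20) {
      y <- runif(30, 0, 10)
      off <- runif(1, -50, 50)
      a <- subtract_background(frap_trace(1:30, (0:29) * 0.1, y))
      b <- subtract_background(frap_trace(1:30, (0:29) * 0.1, y + off))
      expect_equal(a$intensity, b$intensity)
    }
  })
})

test_that("the bleach frame is the frame after the largest drop", {
  tr <- frap_trace(1:5, (0:4) * 0.06, c(10, 10, 2, 4, 6))
  out <- detect_bleach_frame(tr)
  expect_equal(bleach_index(out), 3L) # 1-based frame holding the dropped value
  expect_equal(out$time[3], 0) # time realigned to the first post-bleach frame
  expect_error(
    detect_bleach_frame(frap_trace(1:5, (0:4) * 0.06, 1:5)),
    "No bleach"
  )
  expect_error(detect_bleach_frame(frap_trace(1:2, c(0, 0.06), c(1, 2))),
               "3 frames")
})

test_that("bleach detection finds the true frame despite noise", {
  # ground truth: bleach at frame 17 of a 60-frame exponential recovery
  hits <- withr::with_seed(42, {
    sum(vapply(1:100, function(i) {
      t_post <- (0:43) * 0.06
      y <- c(
        rnorm(16, 1, 0.03),
        0.15 + 0.85 * (1 - exp(-1.3 * t_post)) + rnorm(44, 0, 0.03)
      )
      tr <- frap_trace(1:60, (0:59) * 0.06, y)
      bleach_index(detect_bleach_frame(tr)) == 17L
    }, logical(1)))
  })
  expect_gte(hits, 99)
})

test_that("normalization pins the plateau mean at one", {
  y <- c(rep(10, 5), 2, 4, 6, 7, rep(4, 15))
  tr <- frap_trace(seq_along(y), (seq_along(y) - 1) * 0.06, y)
  tr <- detect_bleach_frame(subtract_background(tr))
  norm <- normalize_trace(tr)
  expect_equal(mean(utils::tail(norm$normalized, 15)), 1, tolerance = 1e-12)
  # the trailing constant block maps exactly to 1
  expect_equal(utils::tail(norm$normalized, 15), rep(1, 15))
  # normalizing twice changes nothing
  expect_identical(normalize_trace(norm)$normalized, norm$normalized)
})

test_that("normalization is invariant to positive rescaling", {
  withr::with_seed(7, {
    y <- c(rep(1, 5), 0.1 + 0.9 * (1 - exp(-1.3 * (0:54) * 0.06)))
    y <- y + rnorm(60, 0, 0.01)
    make <- function(v) {
      normalize_trace(detect_bleach_frame(subtract_background(
        frap_trace(1:60, (0:59) * 0.06, v)
      )))
    }
    for (s in c(0.5, 3, 117)) {
      expect_equal(make(y * s)$normalized, make(y)$normalized,
                   tolerance = 1e-12)
    }
  })
})

test_that("default-acquisition traces normalize with a unit plateau", {
  cfg <- config_heterochromatin(n_molecules = 2000)
  e <- simulate_frap_experiment(cfg, nucleus_geometry(), imaging_config(),
                                seed = 9)
  tr <- normalize_trace(detect_bleach_frame(subtract_background(
    extract_trace(e$timeseries, e$locus_roi)
  )))
  expect_equal(nrow(tr), 120)
  expect_equal(mean(utils::tail(tr$normalized, 15)), 1, tolerance = 1e-12)
})

test_that("degenerate and short traces are handled explicitly", {
  y <- c(rep(10, 5), 2, 4, 6)
  tr <- detect_bleach_frame(subtract_background(
    frap_trace(1:8, (0:7) * 0.06, y)
  ))
  expect_warning(normalize_trace(tr), "post-bleach")
  flat <- frap_trace(1:20, (0:19) * 0.06, c(rep(5, 4), rep(0, 16)))
  flat <- detect_bleach_frame(subtract_background(flat))
  expect_error(normalize_trace(flat), "plateau")
})

test_that("average_traces aligns at the bleach and averages pointwise", {
  mk <- function(vals) {
    tr <- frap_trace(seq_along(vals), (seq_along(vals) - 1) * 0.06, vals)
    normalize_trace(detect_bleach_frame(subtract_background(tr)))
  }
  up <- function(v) c(rep(1.2, 4), v * 0.96 + 0.2, rep(1.16, 15)) * 5
  a <- mk(up(c(0, 0.5, 1)))
  b <- mk(up(c(0, 0.7, 1)))
  avg <- average_traces(list(a, b))
  expect_equal(nrow(avg), nrow(a))
  expect_true(all(avg$n == 2))
  ab <- average_traces(list(a, a))
  expect_equal(ab$mean_normalized, a$normalized)
  expect_error(average_traces(list()), "No traces")
  raw <- detect_bleach_frame(subtract_background(
    frap_trace(1:22, (0:21) * 0.06, up(c(0, 0.5, 1)))
  ))
  expect_error(average_traces(list(a, raw)), "normalized")
})
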