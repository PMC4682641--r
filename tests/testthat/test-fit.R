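test_that("noiseless one-component data are recovered exactly", {
  tt <- seq(0, 7.2, by = 0.06)
  y <- 1 - exp(-log(2) * tt)
  fit <- fit_one_component(tt, y)
  expect_equal(fit$params[["a"]], 1, tolerance = 1e-6)
  expect_equal(fit$params[["b"]], log(2), tolerance = 1e-6)
  expect_equal(fit$t_half, 1, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("profiled optimization matches the dense grid-search oracle", {
  withr::with_seed(101, {
    for (i in 1:5) {
      n <- sample(10:50, 1)
      tt <- sort(runif(n, 0, 6))
      tt[1] <- 0
      y <- runif(1, 0.7, 1.3) * (1 - exp(-runif(1, 0.3, 10) * tt)) +
        rnorm(n, 0, 0.05)
      # oracle equivalence on the same constrained problem
      fit <- fit_one_component(tt, y, a_max = 1.5, b_range = c(0.1, 20))
      oracle <- grid_search_one_component(tt, y)
      expect_lte(fit$rss, oracle$sse + 1e-6)
    }
  })
  # a well-conditioned 20-point trace also pins the parameters to the grid
  withr::with_seed(115, {
    tt <- seq(0, 3.8, by = 0.2)
    y <- 0.95 * (1 - exp(-1.7 * tt)) + rnorm(20, 0, 0.02)
    fit <- fit_one_component(tt, y, a_max = 1.5, b_range = c(0.1, 20))
    oracle <- grid_search_one_component(tt, y)
    expect_lte(fit$rss, oracle$sse + 1e-6)
    expect_lt(abs(fit$params[["a"]] - oracle$a), oracle$da)
    expect_lt(abs(fit$params[["b"]] - oracle$b), oracle$db)
  })
})

test_that("noiseless two-component mixtures are recovered within 1%", {
  tt <- seq(0, 12, by = 0.06)
  y <- 0.6 * (1 - exp(-10 * tt)) + 0.4 * (1 - exp(-0.5 * tt))
  fit <- fit_two_component(tt, y)
  expect_equal(fit$params[["a"]], 0.6, tolerance = 0.01)
  expect_equal(fit$params[["b"]], 10, tolerance = 0.01)
  expect_equal(fit$params[["c"]], 0.4, tolerance = 0.01)
  expect_equal(fit$params[["d"]], 0.5, tolerance = 0.01)
  expect_true(fit$params[["b"]] >= fit$params[["d"]]) # ordering enforced
})

test_that("the two-component fit never loses to the nested model", {
  withr::with_seed(202, {
    for (i in 1:10) {
      tt <- seq(0, 6, by = 0.12)
      y <- runif(1, 0.8, 1.2) * (1 - exp(-runif(1, 0.5, 5) * tt)) +
        rnorm(length(tt), 0, 0.04)
      f1 <- fit_one_component(tt, y)
      f2 <- fit_two_component(tt, y)
      expect_lte(f2$rss, f1$rss + 1e-8)
    }
  })
})

test_that("a single-component truth collapses the two-component fit", {
  tt <- seq(0, 7.2, by = 0.06)
  y <- 0.9 * (1 - exp(-1.3 * tt))
  f1 <- fit_one_component(tt, y)
  f2 <- fit_two_component(tt, y)
  expect_lt(abs(f2$rss - f1$rss), 1e-8)
  expect_equal(halftime_from_curve(f2), halftime_from_curve(f1),
               tolerance = 1e-4)
})

test_that("equal-rate mixtures behave as one component", {
  tt <- seq(0, 6, by = 0.06)
  y <- 0.5 * (1 - exp(-2 * tt)) + 0.5 * (1 - exp(-2 * tt))
  f2 <- fit_two_component(tt, y)
  expect_equal(halftime_from_curve(f2), 1000 * log(2) / 2, tolerance = 0.1)
})

test_that("fits are scale equivariant", {
  withr::with_seed(303, {
    tt <- seq(0, 6, by = 0.06)
    y <- 0.8 * (1 - exp(-1.1 * tt)) + rnorm(length(tt), 0, 0.02)
    base <- fit_one_component(tt, y)
    for (s in c(0.25, 2)) {
      scaled <- fit_one_component(tt, s * y)
      expect_equal(scaled$params[["a"]], s * base$params[["a"]],
                   tolerance = 1e-6)
      expect_equal(scaled$params[["b"]], base$params[["b"]], tolerance = 1e-6)
      expect_equal(scaled$t_half, base$t_half, tolerance = 1e-8)
    }
  })
})

test_that("half-times convert to milliseconds correctly", {
  tt <- seq(0, 7.2, by = 0.06)
  f <- fit_one_component(tt, 1 - exp(-log(2) * tt))
  expect_equal(halftime_from_curve(f), 1000, tolerance = 1e-3)
  f2 <- fit_one_component(tt, 1 - exp(-1.2956 * tt))
  expect_equal(halftime_from_curve(f2), 535.0, tolerance = 0.1)
})

test_that("model selection follows the nested F-test", {
  tt <- seq(0, 7.2, by = 0.06)
  y <- 1 - exp(-1.3 * tt) + withr::with_seed(8, rnorm(length(tt), 0, 0.02))
  f1 <- fit_one_component(tt, y)
  f2 <- fit_two_component(tt, y)
  sel <- select_model(f1, f2)
  expect_equal(sel$model, "one_component")
  expect_gte(sel$p_value, 0.05)
  # identical residuals give F = 0, p = 1
  sel0 <- select_model(f1, structure(
    modifyList(f2, list(rss = f1$rss)), class = "recovery_fit"
  ))
  expect_equal(sel0$f_statistic, 0)
  expect_equal(sel0$p_value, 1)
  # a clearly two-component truth is detected
  y2 <- 0.6 * (1 - exp(-10 * tt)) + 0.4 * (1 - exp(-0.5 * tt)) +
    withr::with_seed(9, rnorm(length(tt), 0, 0.01))
  sel2 <- fit_recovery(data.frame(time = tt, value = y2), model = "auto")
  expect_equal(sel2$model, "two_component")
})

test_that("degenerate fitting inputs error clearly", {
  expect_error(fit_one_component(c(0, 0.1), c(0, 1)), "3 post-bleach")
  expect_error(fit_two_component(c(0, 0.1, 0.2, 0.3), c(0, 1, 1, 1)),
               "5 post-bleach")
  expect_error(fit_one_component(c(-1, 0, 1), c(0, 0.3, 0.5)), "start at 0")
})

test_that("tidy and glance expose the fit in broom shape", {
  tt <- seq(0, 6, by = 0.06)
  fit <- fit_one_component(tt, 1 - exp(-1.3 * tt))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate[2], 1.3, tolerance = 1e-5)
  gl <- glance(fit)
  expect_equal(gl$model, "one_component")
  expect_equal(gl$t_half_ms, 1000 * log(2) / 1.3, tolerance = 1e-3)
  expect_s3_class(autoplot(fit), "ggplot")
})
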