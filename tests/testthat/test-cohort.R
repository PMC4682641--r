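test_that("box summaries follow the IQR/whisker convention", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 5)
  expect_equal(s$n_outliers, 0)
  sv <- summarize_group(7)
  expect_true(all(unlist(sv[c("median", "q1", "q3", "whisker_low",
                              "whisker_high")]) == 7))
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("uniform data produce essentially no 1.5 IQR outliers", {
  x <- withr::with_seed(31, runif(1000))
  s <- summarize_group(x)
  expect_lte(s$n_outliers / 1000, 0.005)
})

test_that("box summaries are permutation invariant and affine equivariant", {
  withr::with_seed(32, {
    x <- rnorm(200, 5, 2)
    s1 <- summarize_group(x)
    s2 <- summarize_group(sample(x))
    expect_equal(s1, s2)
    s3 <- summarize_group(3 * x + 1)
    expect_equal(s3$median, 3 * s1$median + 1)
    expect_equal(s3$q1, 3 * s1$q1 + 1)
    expect_equal(s3$iqr, 3 * s1$iqr)
  })
})

test_that("the Welch test handles identical, separated, and degenerate input", {
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  w1 <- welch_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(w1$p, 1e-3)
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_warning(wz <- welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(wz$p, 0)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("the Welch implementation matches stats::t.test", {
  withr::with_seed(33, {
    for (i in 1:100) {
      a <- rnorm(sample(3:40, 1), rnorm(1), runif(1, 0.5, 3))
      b <- rnorm(sample(3:40, 1), rnorm(1), runif(1, 0.5, 3))
      mine <- welch_t_test(a, b)
      ref <- stats::t.test(a, b, var.equal = FALSE)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("phase profiles summarise, test, and stay within their labels", {
  withr::with_seed(34, {
    rec <- experiment_records(
      experiment_id = sprintf("e%03d", 1:210),
      phase = rep(c("G1", "S", "G2"), times = c(40, 66, 104)),
      time_min = runif(210, 0, 180),
      t_half_ms = pmax(c(rnorm(40, 450, 150), rnorm(66, 550, 150),
                         rnorm(104, 550, 150)), 1)
    )
  })
  prof <- phase_profile(rec)
  expect_equal(sort(prof$summaries$phase), c("G1", "G2", "S"))
  expect_equal(nrow(prof$tests), 3)
  g1g2 <- prof$tests[prof$tests$group_a == "G1" & prof$tests$group_b == "G2", ]
  expect_lt(g1g2$p, 0.05)
  expect_s3_class(autoplot(prof), "ggplot")

  one <- phase_profile(experiment_records("a", phase = "G2",
                                          t_half_ms = c(500)))
  expect_equal(nrow(one$tests), 0)
  expect_equal(nrow(one$summaries), 1)
  unas <- phase_profile(experiment_records(c("a", "b"),
                                           t_half_ms = c(400, 500)))
  expect_equal(nrow(unas$tests), 0)
})

test_that("phase cohorts mirror the G1-lower power profile", {
  # G1 drawn lower than S and G2; G1-G2 should reject often, S-G2 rarely
  n_rep <- 30
  hits_g1g2 <- 0
  hits_sg2 <- 0
  withr::with_seed(35, {
    for (i in seq_len(n_rep)) {
      rec <- experiment_records(
        experiment_id = as.character(1:210),
        phase = rep(c("G1", "S", "G2"), times = c(40, 66, 104)),
        t_half_ms = pmax(c(rnorm(40, 450, 150), rnorm(66, 550, 150),
                           rnorm(104, 550, 150)), 1)
      )
      tst <- phase_profile(rec)$tests
      hits_g1g2 <- hits_g1g2 +
        (tst$p[tst$group_a == "G1" & tst$group_b == "G2"] < 0.05)
      hits_sg2 <- hits_sg2 +
        (tst$p[tst$group_a == "S" & tst$group_b == "G2"] >= 0.05)
    }
  })
  expect_gte(hits_g1g2 / n_rep, 0.8)
  expect_gte(hits_sg2 / n_rep, 0.7)
})

test_that("records validate phases and half-times", {
  expect_error(experiment_records("a", phase = "M", t_half_ms = 100), "phase")
  expect_error(experiment_records("a", t_half_ms = -5), "t_half_ms")
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- experiment_records(c("a", "b"), condition = "wt", phase = "G2",
                            time_min = c(10, 20), t_half_ms = c(500, 600),
                            f_m = c(0.9, 1.0))
  readr::write_csv(rec, path)
  back <- read_experiment_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
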