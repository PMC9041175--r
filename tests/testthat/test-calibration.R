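# calibration statistics: OLS, LOD/LOQ, RSD, precision, inverse prediction

test_that("a perfect line gives r2 = 1 and zero detection limits", {
  s <- data.frame(concentration = c(1, 2, 3, 4), response = c(2, 4, 6, 8))
  fit <- fit_calibration(s)
  expect_equal(fit$b, 2)
  expect_equal(fit$a, 0)
  expect_equal(fit$r2, 1)
  expect_equal(fit$lod, 0)
  expect_equal(fit$loq, 0)
})

test_that("published vitamin-B12 series reproduces its validation figures", {
  fit <- fit_calibration(example_series("b12"))
  expect_equal(round(fit$r2, 3), 0.988)
  expect_equal(round(fit$lod, 1), 2.7)
  expect_equal(round(fit$loq, 1), 8.3)
  expect_equal(fit$unit, "ppm")
})

test_that("published phosphate series reproduces its validation figures", {
  fit <- fit_calibration(example_series("phosphate"))
  expect_equal(round(fit$r2, 3), 0.989)
  expect_equal(round(fit$lod, 1), 0.2)
  expect_equal(round(fit$loq, 1), 0.5)
})

test_that("fit matches the closed-form OLS oracle on random small series", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 0, 20))
    y <- 0.3 + 0.05 * x + rnorm(n, 0, 0.05)
    fit <- fit_calibration(data.frame(concentration = x, response = y))
    oracle <- brute_ols(x, y)
    for (fld in c("a", "b", "se_a", "se_b", "r2", "residual_sd"))
      expect_equal(fit[[fld]], oracle[[fld]], tolerance = 1e-10)
    # LOQ/LOD = 10/3.3 to machine precision whenever the slope is positive
    if (fit$b > 0) expect_equal(fit$loq / fit$lod, 10 / 3.3, tolerance = 1e-12)
  }
})

test_that("r2 is invariant under affine rescaling of both axes", {
  set.seed(23)
  x <- c(0, 1, 2, 4, 8); y <- 0.1 + 0.2 * x + rnorm(5, 0, 0.05)
  r2 <- fit_calibration(data.frame(concentration = x, response = y))$r2
  r2b <- fit_calibration(data.frame(concentration = 3 * x + 2,
                                    response = 0.5 * y + 10))$r2
  expect_equal(r2b, r2)
})

test_that("degenerate designs and nonpositive slopes are handled", {
  expect_error(fit_calibration(data.frame(concentration = c(1, 2),
                                          response = c(1, 2))),
               "3 distinct")
  down <- fit_calibration(data.frame(concentration = c(1, 2, 3, 4),
                                     response = c(8, 6, 4, 2)))
  expect_equal(down$flag, "not_applicable")
  expect_true(is.na(down$lod) && is.na(down$loq))
})

test_that("rsd matches hand arithmetic and flags a zero mean", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_error(rsd(1), "at least 2")
  z <- rsd(c(-1, 1))
  expect_true(is.na(z))
  expect_equal(attr(z, "flag"), "undefined_mean")
})

test_that("small-sample rsd has the expected Monte-Carlo distribution", {
  set.seed(31)
  # n = 3 replicates from N(0.1, 0.005^2), 10^4 trials
  draws <- matrix(rnorm(3 * 1e4, 0.1, 0.005), nrow = 3)
  rsds <- 100 * apply(draws, 2, sd) / colMeans(draws)
  expect_gte(median(rsds), 4)
  expect_lte(median(rsds), 6)
})

test_that("precision_table computes inter/intra RSD by the stated grouping", {
  # all identical -> all zero
  flat <- expand.grid(day = 1:3, replicate = 1:3, concentration = c(1, 2))
  flat$response <- 0.25
  p0 <- precision_table(flat)
  expect_true(all(p0$table$inter_rsd_pct == 0))
  expect_true(all(p0$table$intra_rsd_pct == 0))
  expect_equal(unname(p0$average), c(0, 0))
  # two days with day means 0.10 and 0.12
  two <- data.frame(concentration = 1, day = c(1, 1, 2, 2),
                    replicate = c(1, 2, 1, 2),
                    response = c(0.10, 0.10, 0.12, 0.12))
  p2 <- precision_table(two)
  expect_equal(p2$table$inter_rsd_pct, 100 * sd(c(0.10, 0.12)) / 0.11,
               tolerance = 1e-12)
  # single-replicate level is flagged NA and excluded from the average
  single <- data.frame(concentration = c(1, 1, 2), day = c(1, 2, 1),
                       replicate = 1, response = c(0.1, 0.11, 0.2))
  ps <- precision_table(single)
  expect_true(is.na(ps$table$intra_rsd_pct[1]))  # one replicate per day
  expect_true(is.na(ps$table$inter_rsd_pct[2]))  # one day only
  expect_true(is.finite(ps$average["inter_rsd_pct"]))
})

test_that("between-day variability pushes inter-day above intra-day RSD", {
  s <- make_calibration_series(slope = 0.01, intercept = 0.05,
                               levels = c(5, 10, 20), replicates = 3,
                               noise_sd = 0.0005, days = 3, day_sd = 0.01,
                               seed = 67)
  p <- precision_table(s)
  expect_true(all(p$table$inter_rsd_pct > p$table$intra_rsd_pct))
})

test_that("predict_concentration inverts the line and annotates limits", {
  fit <- fit_calibration(data.frame(concentration = c(0, 2, 4, 6),
                                    response = c(0, 1, 2, 3)))
  expect_equal(as.numeric(predict_concentration(fit, fit$a)), 0)
  fit$a <- 0; fit$b <- 0.5
  expect_equal(as.numeric(predict_concentration(fit, 1)), 2)
  # round-trip on a noiseless series
  s <- make_calibration_series(slope = 0.02, intercept = 0.01,
                               levels = c(2, 4, 8, 16))
  f2 <- fit_calibration(s)
  back <- predict_concentration(f2, s$response)
  expect_equal(as.numeric(back), s$concentration)
  # annotation against detection limits
  noisy <- fit_calibration(make_calibration_series(
    slope = 0.01, intercept = 0, levels = c(1, 2, 5, 10, 20),
    replicates = 2, noise_sd = 0.01, seed = 4))
  ann <- attr(predict_concentration(noisy, c(0.0005, 10)), "annotation")
  expect_equal(ann[1], "below_lod")
  expect_equal(ann[2], "ok")
})

test_that("linear_range_check flags a diverging top level but not a clean line", {
  clean <- data.frame(concentration = c(1, 2, 4, 8, 16),
                      response = c(0.1, 0.2, 0.4, 0.8, 1.6))
  expect_false(linear_range_check(clean)$divergent)
  bent <- clean
  bent$response[5] <- 1.6 * 0.7  # 30% rollover at the top level
  bent$response[1:4] <- bent$response[1:4] + c(1, -1, 1, -1) * 1e-4
  chk <- linear_range_check(bent)
  expect_true(chk$divergent)
  expect_equal(chk$top_level, 16)
  expect_error(linear_range_check(clean[1:3, ]), ">= 4")
})

test_that("linear_range_check false-positive rate stays below 5%", {
  set.seed(71)
  hits <- vapply(1:1000, function(i) {
    s <- make_calibration_series(slope = 0.05, intercept = 0.02,
                                 levels = c(1, 2, 4, 6, 8, 12, 16),
                                 replicates = 2, noise_sd = 0.01)
    linear_range_check(s)$divergent
  }, logical(1))
  expect_lt(mean(hits), 0.05)
})
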