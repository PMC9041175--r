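# spectra core: dark correction, accumulation, absorbance, interpolation

test_that("dark_correct does elementwise subtraction and validates inputs", {
  f <- make_frame(c(100, 200)); d <- make_frame(c(10, 10), role = "dark")
  expect_equal(dark_correct(f, f), c(0, 0))
  expect_equal(dark_correct(f, d), c(90, 190))
  # negativity preserved, not clipped
  expect_equal(dark_correct(d, f), c(-90, -190))
  expect_error(dark_correct(f, make_frame(c(1, 2, 3), role = "dark")),
               "pixel counts")
  expect_error(dark_correct(f, make_frame(c(10, 10), role = "dark",
                                          exposure = 100)),
               "exposure")
})

test_that("dark residual mean vanishes over an accumulated simulation", {
  m <- default_model()  # dark_mean = 30
  acc <- accumulate(acquire_frames(m, 50, role = "dark", seed = 101))
  flat30 <- structure(list(values = rep(30, 288), exposure_us = 200,
                           role = "dark", bits = 10L, n_frames = 1L,
                           frame_id = "const30"),
                      class = "accumulated_spectrum")
  resid <- dark_correct(acc, flat30)
  expect_lt(abs(mean(resid)), 3 * 11.5 / sqrt(50 * 288))
})

test_that("accumulate averages per pixel and validates the batch", {
  f1 <- make_frame(c(0, 2)); f2 <- make_frame(c(2, 0))
  one <- accumulate(f1)
  expect_equal(one$values, c(0, 2))
  expect_equal(one$n_frames, 1L)
  acc <- accumulate(list(f1, f2))
  expect_equal(acc$values, c(1, 1))
  expect_equal(acc$n_frames, 2L)
  expect_error(accumulate(list()), "at least one")
  expect_error(accumulate(list(f1, make_frame(c(1, 1), role = "dark"))),
               "mixed roles")
  expect_error(accumulate(list(f1, make_frame(c(1, 1), exposure = 10))),
               "unequal length or exposure")
})

test_that("accumulation shrinks per-pixel noise like sigma/sqrt(n)", {
  m <- default_model(dark_mean = 500)  # well away from the clip boundaries
  acc <- accumulate(acquire_frames(m, 50, role = "dark", seed = 7))
  # each pixel mean is one draw with sd ~ 11.5/sqrt(50) = 1.63
  expect_equal(sd(acc$values), 11.5 / sqrt(50), tolerance = 0.15)
})

test_that("compute_absorbance handles the identity and exact-ratio cases", {
  cal <- linear_cal()
  b <- make_frame(rep(500, 16), role = "baseline")
  s_same <- make_frame(rep(500, 16))
  a0 <- compute_absorbance(s_same, b, cal = cal)
  expect_true(all(a0$absorbance == 0))
  expect_true(all(a0$flags == "ok"))
  # (S - D) = 0.1 (B - D)  ->  A = 1 exactly
  d <- make_frame(rep(100, 16), role = "dark")
  s <- make_frame(rep(140, 16))  # (140-100) = 0.1*(500-100)
  a1 <- compute_absorbance(s, b, d, cal)
  expect_equal(a1$absorbance, rep(1, 16))
})

test_that("compute_absorbance flags nonpositive and saturated pixels", {
  cal <- linear_cal()
  b <- make_frame(c(rep(500, 14), 500, 1023), role = "baseline")
  s <- make_frame(c(rep(250, 14), 90, 400))
  d <- make_frame(rep(100, 16), role = "dark")
  a <- compute_absorbance(s, b, d, cal)
  expect_equal(a$flags[15], "nonpositive_signal")  # S - D = -10
  expect_true(is.na(a$absorbance[15]))
  expect_equal(a$flags[16], "saturated")           # baseline at full scale
  expect_true(is.finite(a$absorbance[16]))
  # entirely unusable baseline
  expect_error(compute_absorbance(s, make_frame(rep(50, 16), role = "baseline"),
                                  make_frame(rep(90, 16), role = "dark"), cal),
               "unusable baseline")
})

test_that("simulated flat absorber is recovered within 0.02 at 50 frames", {
  m <- default_model()
  smp <- flat_sample(0.5)
  bl <- accumulate(acquire_frames(m, 50, role = "baseline", seed = 21))
  dk <- accumulate(acquire_frames(m, 50, role = "dark", seed = 22))
  sf <- accumulate(acquire_frames(m, 50, sample = smp, role = "sample",
                                  seed = 23))
  a <- compute_absorbance(sf, bl, dk, m$calibration)
  band <- a$wavelengths >= 480 & a$wavelengths <= 620 & a$flags == "ok"
  expect_gt(sum(band), 30)
  expect_lt(abs(mean(a$absorbance[band]) - 0.5), 0.02)
})

test_that("absorbance is additive for sequential attenuations (noiseless)", {
  m <- default_model(dark_rms = 1e-6, dark_mean = 0)
  m$source$peak_counts <- 1000
  bl <- acquire_frame(m, role = "baseline", seed = 1)
  spec_for <- function(a_flat) {
    sf <- acquire_frame(m, flat_sample(a_flat), role = "sample", seed = 1)
    compute_absorbance(sf, bl, cal = m$calibration)
  }
  a1 <- spec_for(0.2); a2 <- spec_for(0.3); a12 <- spec_for(0.5)
  band <- a1$wavelengths >= 470 & a1$wavelengths <= 620
  expect_equal(a12$absorbance[band], (a1$absorbance + a2$absorbance)[band],
               tolerance = 0.01)
})

test_that("absorbance_at interpolates linearly and respects flags", {
  spec <- absorbance_spectrum(c(500, 502), c(0.1, 0.3))
  expect_equal(absorbance_at(spec, 500), 0.1)   # exact grid hit
  expect_equal(absorbance_at(spec, 501), 0.2)   # midpoint
  expect_error(absorbance_at(spec, 499), "outside")
  holed <- absorbance_spectrum(c(500, 502, 504), c(0.1, NA, 0.3),
                               c("ok", "nonpositive_signal", "ok"))
  got <- absorbance_at(holed, 501)
  expect_true(is.na(got))
  expect_equal(attr(got, "flag"), "undefined_neighbor")
})

test_that("assay-wavelength queries match a dense-grid oracle within the interpolation bound", {
  # broad source so the signal is strong at all three assay wavelengths;
  # near-noiseless detector so only interpolation error remains
  m <- instrument_model(
    source = source_model(data.frame(center = 600, fwhm = 300, amplitude = 1),
                          peak_counts = 1000),
    detector = detector_model(dark_mean = 0, dark_rms = 1e-6))
  band <- analyte_spectrum("dye", data.frame(shape = "gauss", center = 600,
                                             width = 120, eps = 0.6))
  smp <- sample_model(list(list(analyte = band, concentration = 1)))
  bl <- acquire_frame(m, role = "baseline", seed = 3)
  sf <- acquire_frame(m, smp, role = "sample", seed = 3)
  a <- compute_absorbance(sf, bl, cal = m$calibration)

  # independent dense-grid forward model: direct quadrature of the slit
  # convolution (no shared code with the acquisition path's FIR filter)
  dense <- seq(420, 780, by = 0.25)
  sg <- 300 / (2 * sqrt(2 * log(2)))
  src <- exp(-0.5 * ((dense - 600) / sg)^2)
  se <- 120 / (2 * sqrt(2 * log(2)))
  Tt <- 10^(-(0.6 * exp(-0.5 * ((dense - 600) / se)^2)))
  w <- dnorm(outer(dense, dense, "-"), sd = 15 / (2 * sqrt(2 * log(2))))
  blur <- function(y) as.numeric(w %*% y) / rowSums(w)
  a_oracle <- log10(blur(src) / blur(src * Tt))

  bound <- max(abs(diff(diff(a$absorbance)))) / 2 + 0.002  # + quantization slack
  for (lam in c(550, 600, 700)) {
    truth <- approx(dense, a_oracle, xout = lam)$y
    expect_lt(abs(absorbance_at(a, lam) - truth), bound)
  }
})
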