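# Shared fixtures and independent oracles.

default_model <- function(...) instrument_model(detector = detector_model(...))

# flat absorber: eps constant over a wide band covering the working range
flat_analyte <- function(eps, center = 600, width = 1000) {
  analyte_spectrum("flat", data.frame(shape = "flat", center = center,
                                      width = width, eps = eps))
}

flat_sample <- function(absorbance) {
  sample_model(list(list(analyte = flat_analyte(absorbance), concentration = 1)))
}

# a tiny linear calibration map for hand-checkable spectra tests
linear_cal <- function(n_pixels = 16, lam0 = 500, step = 10) {
  wavelength_calibration(c(lam0, step), pixel_range = c(0L, n_pixels - 1L),
                         working_range = c(lam0, lam0 + step * (n_pixels - 1)))
}

make_frame <- function(counts, role = "sample", exposure = 200, bits = 10) {
  raw_spectrum(counts, exposure_us = exposure, role = role, bits = bits)
}

# independent textbook OLS oracle: explicit Sxx/Sxy closed forms, no lm()
brute_ols <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  b <- sxy / sxx
  a <- ybar - b * xbar
  res <- y - a - b * x
  sse <- sum(res^2)
  sst <- sum((y - ybar)^2)
  s2 <- sse / (n - 2)
  list(a = a, b = b,
       se_a = sqrt(s2 * (1 / n + xbar^2 / sxx)),
       se_b = sqrt(s2 / sxx),
       r2 = 1 - sse / sst,
       residual_sd = sqrt(s2))
}
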