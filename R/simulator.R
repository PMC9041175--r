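#' LED source model
#'
#' Emission shape as a sum of Gaussian bands (center, FWHM, relative
#' amplitude) plus an overall intensity scale expressed as the expected peak
#' signal in ADC counts (above dark) at the reference exposure.
#'
#' @param bands Data frame with columns `center` (nm), `fwhm` (nm),
#'   `amplitude` (relative, >= 0); at least one band.
#' @param peak_counts Expected dark-subtracted counts at the brightest pixel
#'   with no sample, at the detector's reference exposure.
#' @return An object of class `source_model`.
#' @export
source_model <- function(bands, peak_counts = 950) {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1,
            all(c("center", "fwhm", "amplitude") %in% names(bands)),
            all(bands$amplitude >= 0), all(bands$fwhm > 0), peak_counts > 0)
  structure(list(bands = bands, peak_counts = peak_counts),
            class = "source_model")
}

#' Default warm-white LED source
#'
#' A blue pump band near 450 nm plus a broad phosphor band near 560 nm, with
#' amplitudes chosen so the intensity at 550 nm sits at roughly half the
#' spectral maximum -- the operating point at which the reference device was
#' characterised. The true emission curve of a wide-gamut warm-white LED is
#' only available graphically, so these parameters are a repository choice.
#'
#' @param peak_counts See [source_model()].
#' @return A `source_model`.
#' @export
default_source <- function(peak_counts = 950) {
  source_model(data.frame(center = c(450, 560), fwhm = c(20, 120),
                          amplitude = c(1.0, 0.55)),
               peak_counts = peak_counts)
}

# relative emission intensity of a source at wavelengths lam (nm)
source_emission <- function(source, lam) {
  out <- numeric(length(lam))
  for (i in seq_len(nrow(source$bands))) {
    b <- source$bands[i, ]
    s <- b$fwhm / (2 * sqrt(2 * log(2)))
    out <- out + b$amplitude * exp(-0.5 * ((lam - b$center) / s)^2)
  }
  out
}

#' Analyte absorptivity profile
#'
#' Molar (or mass) absorptivity as a function of wavelength, parameterised as
#' Gaussian and/or flat bands. Units of `eps` are absorbance per
#' concentration-unit per cm; concentration units are opaque labels (ppm, uM,
#' mmol/L) and are never converted.
#'
#' @param name Analyte label.
#' @param bands Data frame with columns `shape` (`"gauss"` or `"flat"`),
#'   `center`, `width` (FWHM for `gauss`; full width for `flat`), `eps`
#'   (peak/plateau absorptivity, >= 0).
#' @return An object of class `analyte_spectrum`.
#' @export
analyte_spectrum <- function(name, bands) {
  stopifnot(is.character(name), is.data.frame(bands), nrow(bands) >= 1,
            all(c("shape", "center", "width", "eps") %in% names(bands)),
            all(bands$eps >= 0), all(bands$width > 0),
            all(bands$shape %in% c("gauss", "flat")))
  structure(list(name = name, bands = bands), class = "analyte_spectrum")
}

#' Absorptivity of an analyte at given wavelengths
#' @param analyte An [analyte_spectrum()].
#' @param lam Wavelengths in nm.
#' @return Nonnegative absorptivity values.
#' @export
absorptivity <- function(analyte, lam) {
  out <- numeric(length(lam))
  for (i in seq_len(nrow(analyte$bands))) {
    b <- analyte$bands[i, ]
    if (b$shape == "gauss") {
      s <- b$width / (2 * sqrt(2 * log(2)))
      out <- out + b$eps * exp(-0.5 * ((lam - b$center) / s)^2)
    } else {
      out <- out + ifelse(abs(lam - b$center) <= b$width / 2, b$eps, 0)
    }
  }
  out
}

#' Sample in the optical path
#'
#' @param constituents List of `list(analyte = <analyte_spectrum>,
#'   concentration = <nonnegative number>)` entries; may be empty (a blank).
#' @param path_length Cuvette path length in cm; default 1.0 (standard
#'   10 mm x 10 mm cuvette).
#' @return An object of class `sample_model`.
#' @export
sample_model <- function(constituents = list(), path_length = 1.0) {
  stopifnot(path_length > 0)
  for (ct in constituents) {
    stopifnot(inherits(ct$analyte, "analyte_spectrum"),
              is.numeric(ct$concentration), ct$concentration >= 0)
  }
  structure(list(constituents = constituents, path_length = path_length),
            class = "sample_model")
}

#' Beer-Lambert transmittance of a sample
#'
#' `T(lambda) = 10^(-sum_i eps_i(lambda) * c_i * l)`; an empty sample
#' transmits fully.
#'
#' @param sample A [sample_model()].
#' @param lam Wavelengths in nm (vectorised).
#' @return Transmittance in `[0, 1]`.
#' @export
sample_transmission <- function(sample, lam) {
  stopifnot(inherits(sample, "sample_model"))
  a_total <- numeric(length(lam))
  for (ct in sample$constituents)
    a_total <- a_total +
      absorptivity(ct$analyte, lam) * ct$concentration * sample$path_length
  10^(-a_total)
}

#' Detector model
#'
#' @param n_pixels Number of sensor pixels; default 288.
#' @param bits ADC depth; default 10 (full scale 1023).
#' @param dark_mean Mean dark level in counts; default 30.
#' @param dark_rms RMS dark (read + dark) noise in counts; default 11.5.
#' @param slit_fwhm Spectral resolution (Gaussian slit function FWHM) in nm;
#'   default 15.
#' @param exposure_ref Reference exposure in microseconds at which
#'   `peak_counts` applies; default 200.
#' @param shot_noise Add Poisson shot noise on the expected signal? Off by
#'   default: the additive Gaussian model already reproduces the dark-noise
#'   RMS and per-pixel SNR the device is characterised by.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(n_pixels = 288L, bits = 10L, dark_mean = 30,
                           dark_rms = 11.5, slit_fwhm = 15,
                           exposure_ref = 200, shot_noise = FALSE) {
  stopifnot(n_pixels >= 2, bits >= 1, dark_rms > 0, slit_fwhm > 0,
            exposure_ref > 0, dark_mean >= 0)
  structure(list(n_pixels = as.integer(n_pixels), bits = as.integer(bits),
                 dark_mean = dark_mean, dark_rms = dark_rms,
                 slit_fwhm = slit_fwhm, exposure_ref = exposure_ref,
                 shot_noise = isTRUE(shot_noise)),
            class = "detector_model")
}

#' Full virtual spectrometer
#'
#' @param source A [source_model()].
#' @param detector A [detector_model()].
#' @param calibration A [wavelength_calibration()] covering the detector's
#'   pixel range.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(source = default_source(),
                             detector = detector_model(),
                             calibration = default_calibration()) {
  stopifnot(inherits(source, "source_model"),
            inherits(detector, "detector_model"),
            inherits(calibration, "wavelength_calibration"))
  if (calibration$pixel_range[2] - calibration$pixel_range[1] + 1L !=
      detector$n_pixels)
    stop("calibration pixel range does not cover the detector's ",
         detector$n_pixels, " pixels")
  structure(list(source = source, detector = detector,
                 calibration = calibration),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf("<instrument_model> %d px / %d-bit, slit %g nm, dark %g +/- %g counts\n",
              x$detector$n_pixels, x$detector$bits, x$detector$slit_fwhm,
              x$detector$dark_mean, x$detector$dark_rms))
  print(x$calibration)
  invisible(x)
}

# Gaussian blur of a regularly sampled function; edge-padded so the kernel
# integrates to 1 everywhere (signal conserved away from range edges).
gaussian_blur <- function(y, dx, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * s / dx))
  k <- dnorm(seq(-half, half) * dx, sd = s)
  k <- k / sum(k)
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  out <- stats::filter(ypad, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + length(y))])
}

# Noiseless expected counts per pixel for a model/sample/exposure.
# The continuous source*transmission product is blurred by the slit function
# on a dense grid, then sampled at the pixel wavelengths; the source alone is
# normalised so its blurred maximum over the pixels equals peak_counts at the
# reference exposure.
expected_counts <- function(model, sample = NULL, exposure = NULL,
                            dense_dx = 0.5) {
  det <- model$detector
  exposure <- exposure %||% det$exposure_ref
  px <- seq(model$calibration$pixel_range[1], model$calibration$pixel_range[2])
  lam_px <- pixel_to_wavelength(model$calibration, px)
  pad <- 4 * det$slit_fwhm
  lam_dense <- seq(lam_px[1] - pad, lam_px[length(lam_px)] + pad, by = dense_dx)

  src <- source_emission(model$source, lam_dense)
  src_blur <- gaussian_blur(src, dense_dx, det$slit_fwhm)
  norm <- max(approx(lam_dense, src_blur, xout = lam_px)$y)

  sig <- src
  if (!is.null(sample)) sig <- sig * sample_transmission(sample, lam_dense)
  sig_blur <- gaussian_blur(sig, dense_dx, det$slit_fwhm)
  sig_px <- approx(lam_dense, sig_blur, xout = lam_px)$y

  det$dark_mean +
    (exposure / det$exposure_ref) * model$source$peak_counts * sig_px / norm
}

#' Acquire one simulated frame
#'
#' Expected counts are `dark_mean + scale(exposure) * slit-blurred(source *
#' transmission)` at each pixel's wavelength; Gaussian noise of sd `dark_rms`
#' is added before quantization, then counts are rounded and clipped to the
#' ADC range. Identical seeds reproduce identical frames. For `role = "dark"`
#' the source is off and only the dark level plus noise is read out.
#'
#' @param model An [instrument_model()].
#' @param sample Optional [sample_model()]; ignored for dark frames.
#' @param role Frame role: `"sample"`, `"baseline"` or `"dark"`.
#' @param exposure Exposure in microseconds; default the detector reference.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [raw_spectrum()].
#' @export
acquire_frame <- function(model, sample = NULL,
                          role = c("sample", "baseline", "dark"),
                          exposure = NULL, seed = NULL) {
  role <- match.arg(role)
  det <- model$detector
  exposure <- exposure %||% det$exposure_ref
  if (exposure < 0) stop("exposure must be nonnegative")
  mu <- if (role == "dark") rep(det$dark_mean, det$n_pixels)
        else expected_counts(model, sample, exposure)
  draw <- function() {
    y <- mu + rnorm(det$n_pixels, 0, det$dark_rms)
    if (det$shot_noise) {
      sig <- pmax(mu - det$dark_mean, 0)
      y <- y + (stats::rpois(det$n_pixels, sig) - sig)
    }
    pmin(pmax(round(y), 0), 2^det$bits - 1)
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  raw_spectrum(counts, exposure_us = exposure, role = role, bits = det$bits,
               frame_id = sprintf("sim-%s-%s", role,
                                  if (is.null(seed)) "unseeded" else seed))
}

#' Acquire a batch of simulated frames
#'
#' Frames are drawn from one seeded stream, so a given `(seed, n)` pair is
#' fully reproducible and frames within the batch are independent.
#'
#' @inheritParams acquire_frame
#' @param n Number of frames.
#' @return A list of [raw_spectrum()] frames.
#' @export
acquire_frames <- function(model, n, sample = NULL,
                           role = c("sample", "baseline", "dark"),
                           exposure = NULL, seed = NULL) {
  role <- match.arg(role)
  gen <- function() lapply(seq_len(n), function(i)
    acquire_frame(model, sample, role, exposure))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' RGB emission fixture for wavelength-accuracy testing
#'
#' Simulates an RGB LED with each colour turned on separately: three
#' narrow-band Gaussian sources at known centers, acquired through the
#' instrument's slit and noise model. Because Gaussian slit blur preserves the
#' center of a Gaussian band, the true peak positions equal the band centers.
#'
#' @param model An [instrument_model()]; its source is replaced per channel.
#' @param centers True emission peak centers in nm (blue, green, red defaults
#'   inside the working range).
#' @param fwhm Emission FWHM in nm; default 20.
#' @param n_frames Frames per channel; default 50.
#' @param seed Optional integer seed.
#' @param noiseless If `TRUE`, dark noise is turned off (expected counts only).
#' @return A list with one element per channel: `frames` (list of
#'   [raw_spectrum()]) and `true_center` (nm).
#' @export
make_rgb_fixture <- function(model = instrument_model(),
                             centers = c(blue = 465, green = 525, red = 625),
                             fwhm = 20, n_frames = 50, seed = NULL,
                             noiseless = FALSE) {
  build <- function(center, sd_seed) {
    ch_model <- model
    ch_model$source <- source_model(
      data.frame(center = center, fwhm = fwhm, amplitude = 1),
      peak_counts = model$source$peak_counts)
    if (noiseless) {
      mu <- expected_counts(ch_model)
      counts <- pmin(pmax(round(mu), 0), 2^model$detector$bits - 1)
      frames <- list(raw_spectrum(counts, model$detector$exposure_ref,
                                  role = "sample", bits = model$detector$bits,
                                  frame_id = sprintf("rgb-%g-noiseless", center)))
    } else {
      frames <- acquire_frames(ch_model, n_frames, role = "sample",
                               seed = sd_seed)
    }
    list(frames = frames, true_center = unname(center))
  }
  seeds <- if (is.null(seed)) vector("list", length(centers))
           else as.list(seed + seq_along(centers) - 1L)
  out <- Map(build, centers, seeds)
  names(out) <- names(centers) %||% paste0("channel", seq_along(centers))
  out
}

#' Synthetic concentration-response calibration series
#'
#' Draws `response = intercept + slope * concentration + N(0, noise_sd)` per
#' replicate, optionally with a day-level random shift to emulate inter-day
#' variability for precision studies.
#'
#' @param slope Absorbance per concentration unit.
#' @param intercept Absorbance at zero concentration.
#' @param levels Concentration levels (nonempty, declared unit is opaque).
#' @param replicates Replicates per level per day; default 1.
#' @param noise_sd Within-day absorbance noise sd; default 0.
#' @param days Number of days; default 1.
#' @param day_sd Between-day sd of a common additive shift; default 0.
#' @param seed Optional integer seed.
#' @return A data frame with columns `concentration`, `response`, `day`,
#'   `replicate`.
#' @export
make_calibration_series <- function(slope, intercept = 0, levels,
                                    replicates = 1L, noise_sd = 0,
                                    days = 1L, day_sd = 0, seed = NULL) {
  stopifnot(length(levels) >= 1, noise_sd >= 0, day_sd >= 0,
            replicates >= 1, days >= 1)
  gen <- function() {
    grid <- expand.grid(replicate = seq_len(replicates), day = seq_len(days),
                        concentration = levels)
    shift <- rnorm(days, 0, day_sd)
    grid$response <- intercept + slope * grid$concentration +
      shift[grid$day] + rnorm(nrow(grid), 0, noise_sd)
    grid[, c("concentration", "response", "day", "replicate")]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
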