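#' RMS dark noise
#'
#' Per-pixel sample standard deviation (n-1 denominator) across repeated dark
#' frames, averaged over pixels -- the "average of standard deviations"
#' convention used to characterise line-sensor dark noise.
#'
#' @param dark_frames List of at least two equal-length [raw_spectrum()]
#'   frames.
#' @return RMS dark noise in counts.
#' @export
rms_dark_noise <- function(dark_frames) {
  if (length(dark_frames) < 2)
    stop("rms_dark_noise() needs at least 2 frames")
  npx <- length(frame_values(dark_frames[[1]]))
  m <- matrix(vapply(dark_frames, frame_values, numeric(npx)), nrow = npx)
  mean(apply(m, 1, sd))
}

#' Dynamic range of the detector
#'
#' Ratio of the ADC full scale `2^bits - 1` to the RMS dark noise. The raw
#' ratio is conventionally quoted for this figure; a decibel form
#' `10 * log10(ratio)` is reported alongside. (Vendor-style datasheets
#' sometimes label the raw ratio itself "dB"; both numbers are returned so
#' either convention can be read off.)
#'
#' @param rms_dark RMS dark noise in counts, > 0.
#' @param bits ADC depth; default 10.
#' @return A named list with `ratio` and `db`.
#' @export
dynamic_range <- function(rms_dark, bits = 10L) {
  if (!is.numeric(rms_dark) || rms_dark <= 0)
    stop("rms_dark must be positive")
  ratio <- (2^bits - 1) / rms_dark
  list(ratio = ratio, db = 10 * log10(ratio))
}

#' Signal-to-noise ratio at a wavelength
#'
#' At the pixel nearest the query wavelength: mean count over repeated frames
#' divided by their standard deviation (n-1 denominator), with a
#' `10 * log10` decibel form. A zero standard deviation yields an infinite
#' ratio with `flag = "zero_noise"` rather than an error.
#'
#' @param frames List of at least two illuminated [raw_spectrum()] frames.
#' @param cal A [wavelength_calibration()].
#' @param lambda Query wavelength in nm, within the working range.
#' @return Named list: `ratio`, `db`, `pixel`, `wavelength_nm`, `mean`, `sd`,
#'   `flag` (`"ok"` or `"zero_noise"`).
#' @export
snr <- function(frames, cal, lambda) {
  if (length(frames) < 2) stop("snr() needs at least 2 frames")
  if (lambda < cal$working_range[1] || lambda > cal$working_range[2])
    stop("query wavelength outside the working range")
  px <- working_pixels(cal)
  lam <- pixel_to_wavelength(cal, px)
  p <- px[which.min(abs(lam - lambda))]
  vals <- vapply(frames, function(f) frame_values(f)[p + 1L], numeric(1))
  m <- mean(vals); s <- sd(vals)
  if (s == 0)
    return(list(ratio = Inf, db = Inf, pixel = p,
                wavelength_nm = lam[which.min(abs(lam - lambda))],
                mean = m, sd = s, flag = "zero_noise"))
  list(ratio = m / s, db = 10 * log10(m / s), pixel = p,
       wavelength_nm = lam[which.min(abs(lam - lambda))],
       mean = m, sd = s, flag = "ok")
}

#' SNR from summary statistics
#'
#' Ratio and decibel form from an already-measured mean and standard
#' deviation at one pixel (useful when only the operating-point statistics
#' are recorded, not the raw frames).
#'
#' @param mean_counts Mean signal in counts.
#' @param sd_counts Standard deviation in counts, > 0.
#' @return Named list with `ratio` and `db` (`10 * log10(ratio)`).
#' @export
snr_from_stats <- function(mean_counts, sd_counts) {
  if (sd_counts <= 0) stop("sd_counts must be positive")
  ratio <- mean_counts / sd_counts
  list(ratio = ratio, db = 10 * log10(ratio))
}

#' Per-pixel SNR spectrum
#'
#' Mean/sd per pixel across repeated frames, restricted to the working range.
#'
#' @inheritParams snr
#' @param normalize Divide the ratio by its maximum (the "normalized SNR
#'   spectrum" view)? Default `FALSE`.
#' @return Data frame with `pixel`, `wavelength_nm`, `mean`, `sd`, `ratio`.
#' @export
snr_spectrum <- function(frames, cal, normalize = FALSE) {
  if (length(frames) < 2) stop("snr_spectrum() needs at least 2 frames")
  px <- working_pixels(cal)
  m <- vapply(frames, frame_values,
              numeric(length(frame_values(frames[[1]]))))[px + 1L, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  ratio <- ifelse(s > 0, mu / s, Inf)
  if (normalize) {
    fin <- is.finite(ratio)
    if (any(fin)) ratio <- ratio / max(ratio[fin])
  }
  data.frame(pixel = px, wavelength_nm = pixel_to_wavelength(cal, px),
             mean = mu, sd = s, ratio = ratio)
}

#' Emission peak wavelength
#'
#' Locates the emission maximum of a frame (or accumulated spectrum) in
#' wavelength space. `method = "argmax"` returns the wavelength of the
#' maximal pixel -- the convention matching grid-limited peak comparisons,
#' where differences below half an adjacent-pixel step are not resolvable.
#' `method = "parabolic"` refines to the sub-pixel vertex of the parabola
#' through the maximal pixel and its two neighbours (fit in wavelength space);
#' if the maximum sits on a boundary pixel the parabola is undefined and the
#' result falls back to argmax with attribute `flag = "boundary_fallback"`.
#'
#' @param frame A [raw_spectrum()] or [accumulate()] output.
#' @param cal A [wavelength_calibration()].
#' @param method `"argmax"` (default) or `"parabolic"`.
#' @param restrict_to_working Only consider pixels inside the working range?
#'   Default `TRUE`.
#' @return Peak wavelength in nm.
#' @export
peak_wavelength <- function(frame, cal, method = c("argmax", "parabolic"),
                            restrict_to_working = TRUE) {
  method <- match.arg(method)
  y_all <- frame_values(frame)
  px <- if (restrict_to_working) working_pixels(cal)
        else seq(cal$pixel_range[1], cal$pixel_range[2])
  y <- y_all[px + 1L]
  lam <- pixel_to_wavelength(cal, px)
  i <- which.max(y)
  if (method == "argmax") return(lam[i])
  if (i == 1L || i == length(y)) {
    out <- lam[i]
    attr(out, "flag") <- "boundary_fallback"
    return(out)
  }
  # vertex of the parabola through (lam, y) at i-1, i, i+1
  x <- lam[(i - 1):(i + 1)]; v <- y[(i - 1):(i + 1)]
  d21 <- (v[2] - v[1]) / (x[2] - x[1])
  d32 <- (v[3] - v[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0) {  # flat or concave-up triple: no interior vertex
    out <- lam[i]
    attr(out, "flag") <- "boundary_fallback"
    return(out)
  }
  (x[1] + x[2]) / 2 - d21 / (2 * curv)
}

#' Wavelength accuracy from matched peak lists
#'
#' Mean absolute difference between measured and reference emission-peak
#' wavelengths, with the per-peak detail.
#'
#' @param measured,reference Equal-length, order-matched numeric vectors of
#'   peak wavelengths in nm.
#' @return List with `mean_abs_delta_nm` and a per-peak data frame `peaks`.
#' @export
wavelength_accuracy <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("measured and reference peak lists differ in length")
  d <- abs(measured - reference)
  list(mean_abs_delta_nm = mean(d),
       peaks = data.frame(measured_nm = measured, reference_nm = reference,
                          abs_delta_nm = d))
}

#' Instrument figures-of-merit report
#'
#' Bundles the detector characterisation: RMS dark noise, dynamic range
#' (ratio and dB), the SNR spectrum and the SNR at a query wavelength, and --
#' when peak fixtures are supplied -- wavelength accuracy.
#'
#' @param dark_frames List of >= 2 dark [raw_spectrum()] frames.
#' @param illuminated_frames List of >= 2 illuminated frames.
#' @param cal A [wavelength_calibration()].
#' @param snr_lambda Query wavelength for the headline SNR; default 540 nm.
#' @param measured_peaks,reference_peaks Optional matched peak lists for
#'   [wavelength_accuracy()].
#' @return An object of class `fom_report`.
#' @export
fom_report <- function(dark_frames, illuminated_frames, cal,
                       snr_lambda = 540, measured_peaks = NULL,
                       reference_peaks = NULL) {
  rms <- rms_dark_noise(dark_frames)
  bits <- dark_frames[[1]]$bits
  dr <- dynamic_range(rms, bits)
  rep <- list(
    rms_dark = rms,
    bits = bits,
    dynamic_range_ratio = dr$ratio,
    dynamic_range_db = dr$db,
    snr_at_query = snr(illuminated_frames, cal, snr_lambda),
    snr_by_wavelength = snr_spectrum(illuminated_frames, cal),
    wavelength_accuracy = if (!is.null(measured_peaks))
      wavelength_accuracy(measured_peaks, reference_peaks) else NULL)
  structure(rep, class = "fom_report")
}

#' @export
print.fom_report <- function(x, ...) {
  cat("<fom_report>\n")
  cat(sprintf("  RMS dark noise: %.2f counts (%d-bit ADC)\n", x$rms_dark, x$bits))
  cat(sprintf("  dynamic range:  %.1f (%.1f dB)\n",
              x$dynamic_range_ratio, x$dynamic_range_db))
  q <- x$snr_at_query
  cat(sprintf("  SNR @ %.0f nm:  %.1f (%.0f dB) [%s]\n",
              q$wavelength_nm, q$ratio, q$db, q$flag))
  if (!is.null(x$wavelength_accuracy))
    cat(sprintf("  wavelength accuracy: mean |delta| = %.2f nm over %d peaks\n",
                x$wavelength_accuracy$mean_abs_delta_nm,
                nrow(x$wavelength_accuracy$peaks)))
  invisible(x)
}
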