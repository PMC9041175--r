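#' Raw detector frame
#'
#' One readout of the line sensor: integer ADC counts per pixel plus the
#' acquisition metadata needed to combine frames safely. Counts are validated
#' against the ADC full scale `2^bits - 1`.
#'
#' @param counts Integer vector of ADC counts, one per pixel.
#' @param exposure_us Exposure time in microseconds.
#' @param role One of `"dark"`, `"baseline"`, `"sample"`.
#' @param bits ADC depth; full scale is `2^bits - 1`. Default 10.
#' @param frame_id Opaque label; autogenerated when `NULL`.
#' @param timestamp Optional POSIXct acquisition time.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(counts, exposure_us, role = c("sample", "baseline", "dark"),
                         bits = 10L, frame_id = NULL, timestamp = NULL) {
  role <- match.arg(role)
  stopifnot(is.numeric(counts), length(counts) >= 1, is.numeric(exposure_us),
            exposure_us >= 0, bits >= 1)
  if (any(counts != round(counts)))
    stop("counts must be integer-valued ADC readings")
  full <- 2^bits - 1
  bad <- which(counts < 0 | counts > full)
  if (length(bad))
    stop("count out of ADC range [0, ", full, "] at pixel ", bad[1] - 1L)
  structure(
    list(counts = as.integer(counts), exposure_us = as.numeric(exposure_us),
         role = role, bits = as.integer(bits),
         frame_id = frame_id %||% sprintf("frame-%s-%d", role,
                                          sample.int(.Machine$integer.max, 1)),
         timestamp = timestamp),
    class = "raw_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum '%s'> role=%s, %d px, %g us, %d-bit, counts %d..%d\n",
              x$frame_id, x$role, length(x$counts), x$exposure_us, x$bits,
              min(x$counts), max(x$counts)))
  invisible(x)
}

# uniform access to pixel values of raw or accumulated frames
frame_values <- function(x) {
  if (inherits(x, "raw_spectrum")) as.numeric(x$counts)
  else if (inherits(x, "accumulated_spectrum")) x$values
  else stop("expected a raw_spectrum or accumulated_spectrum")
}

frame_meta <- function(x) {
  list(exposure_us = x$exposure_us, role = x$role, bits = x$bits,
       frame_id = x$frame_id,
       n_frames = if (inherits(x, "accumulated_spectrum")) x$n_frames else 1L)
}

#' Subtract a dark frame
#'
#' Elementwise `frame - dark`. Negative residuals are preserved, not clipped:
#' nonpositive corrected signal is flagged downstream where it matters
#' (absorbance), so noise statistics stay honest.
#'
#' @param frame,dark Frames of equal pixel count and equal exposure
#'   ([raw_spectrum()] or [accumulate()] output).
#' @return Numeric vector of dark-corrected per-pixel values.
#' @export
dark_correct <- function(frame, dark) {
  f <- frame_values(frame); d <- frame_values(dark)
  if (length(f) != length(d))
    stop("frame and dark have different pixel counts (", length(f), " vs ",
         length(d), ")")
  if (!isTRUE(all.equal(frame$exposure_us, dark$exposure_us)))
    stop("frame and dark have different exposures; frames of unequal exposure are never combined")
  f - d
}

#' Average repeated frames
#'
#' Per-pixel arithmetic mean of repeated frames of the same role, length and
#' exposure (the "accumulation" mode of the desktop software). Averaging is
#' performed on counts, before any log transform.
#'
#' @param frames A list of [raw_spectrum()] frames (a single frame is accepted).
#' @return An `accumulated_spectrum`: real-valued per-pixel means plus the
#'   shared metadata and `n_frames`.
#' @export
accumulate <- function(frames) {
  if (inherits(frames, "raw_spectrum")) frames <- list(frames)
  if (length(frames) == 0) stop("accumulate() needs at least one frame")
  roles <- vapply(frames, function(f) f$role, character(1))
  if (length(unique(roles)) != 1)
    stop("cannot accumulate frames of mixed roles: ",
         paste(unique(roles), collapse = ", "))
  lens <- vapply(frames, function(f) length(frame_values(f)), integer(1))
  expo <- vapply(frames, function(f) f$exposure_us, numeric(1))
  if (length(unique(lens)) != 1 || length(unique(expo)) != 1)
    stop("cannot accumulate frames of unequal length or exposure")
  m <- rowMeans(vapply(frames, frame_values, numeric(lens[1])))
  structure(
    list(values = m, exposure_us = expo[1], role = roles[1],
         bits = frames[[1]]$bits, n_frames = length(frames),
         frame_id = sprintf("acc-%s-n%d", roles[1], length(frames))),
    class = "accumulated_spectrum")
}

#' @export
print.accumulated_spectrum <- function(x, ...) {
  cat(sprintf("<accumulated_spectrum> role=%s, %d px, n_frames=%d, mean %.1f\n",
              x$role, length(x$values), x$n_frames, mean(x$values)))
  invisible(x)
}

#' Wavelength-indexed absorbance spectrum
#'
#' Constructor used by [compute_absorbance()]; rarely called directly.
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param absorbance Unitless absorbance per grid point; `NA` where undefined.
#' @param flags Character per-point quality flags: `"ok"`, `"saturated"`,
#'   `"nonpositive_signal"`.
#' @param provenance Named list identifying the sample/baseline/dark frames.
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, flags = NULL,
                                provenance = list()) {
  n <- length(wavelengths)
  flags <- flags %||% rep("ok", n)
  stopifnot(length(absorbance) == n, length(flags) == n)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(flags == "nonpositive_signal" & is.finite(absorbance)))
    stop("nonpositive_signal points must carry an undefined value, not a finite number")
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance),
                 flags = as.character(flags), provenance = provenance),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  ok <- x$flags == "ok"
  cat(sprintf("<absorbance_spectrum> %d points, %.1f-%.1f nm, %d flagged\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              sum(!ok)))
  if (any(ok))
    cat(sprintf("  A range (ok points): %.4f .. %.4f\n",
                min(x$absorbance[ok]), max(x$absorbance[ok])))
  invisible(x)
}

#' @export
as.data.frame.absorbance_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, absorbance = x$absorbance,
             flag = x$flags, stringsAsFactors = FALSE)
}

#' Single-beam absorbance from sample, baseline and dark frames
#'
#' Computes `A(p) = log10((B(p) - D(p)) / (S(p) - D(p)))` per pixel, the
#' standard single-beam transmission absorbance with the blank (baseline)
#' spectrum as the reference intensity, then maps pixels to wavelengths and
#' restricts to the calibration's working range.
#'
#' Pixels where the dark-corrected sample or baseline signal is nonpositive
#' get `NA` and flag `"nonpositive_signal"`; pixels where any input frame sits
#' at the ADC full scale are flagged `"saturated"` (value still reported).
#' When no dark frame is given `D = 0` -- the device has no shutter, so a
#' measured dark is optional by design; the residual offset then biases low
#' absorbances (documented limitation).
#'
#' @param sample,baseline Sample and blank frames ([raw_spectrum()] or
#'   [accumulate()] output) of equal length and exposure.
#' @param dark Optional dark frame; zero if absent.
#' @param cal A [wavelength_calibration()]; defaults to [default_calibration()].
#' @return An [absorbance_spectrum()].
#' @export
compute_absorbance <- function(sample, baseline, dark = NULL,
                               cal = default_calibration()) {
  s <- frame_values(sample); b <- frame_values(baseline)
  if (length(s) != length(b)) stop("sample and baseline have different pixel counts")
  if (!isTRUE(all.equal(sample$exposure_us, baseline$exposure_us)))
    stop("sample and baseline have different exposures")
  full <- 2^sample$bits - 1
  if (is.null(dark)) {
    d <- rep(0, length(s)); dark_sat <- rep(FALSE, length(s))
    dark_id <- NA_character_
  } else {
    d <- frame_values(dark)
    if (length(d) != length(s)) stop("dark frame has a different pixel count")
    dark_sat <- d >= full
    dark_id <- dark$frame_id
  }
  bd <- b - d; sd_ <- s - d
  if (all(bd <= 0))
    stop("unusable baseline: baseline is entirely at or below the dark level")

  px <- working_pixels(cal)
  if (max(px) + 1L > length(s))
    stop("frames have fewer pixels than the calibration map expects")
  idx <- px + 1L  # pixel indices are 0-based, R vectors 1-based
  lam <- pixel_to_wavelength(cal, px)

  valid <- bd[idx] > 0 & sd_[idx] > 0
  a <- rep(NA_real_, length(idx))
  a[valid] <- log10(bd[idx][valid] / sd_[idx][valid])
  flags <- rep("ok", length(idx))
  flags[s[idx] >= full | b[idx] >= full | dark_sat[idx]] <- "saturated"
  flags[!valid] <- "nonpositive_signal"

  absorbance_spectrum(
    lam, a, flags,
    provenance = list(sample = sample$frame_id, baseline = baseline$frame_id,
                      dark = dark_id,
                      n_frames_sample = frame_meta(sample)$n_frames,
                      n_frames_baseline = frame_meta(baseline)$n_frames))
}

#' Absorbance at a single wavelength
#'
#' Linear interpolation between the two bracketing grid points (the pixel
#' pitch, ~2.2 nm, is far below the 15 nm optical resolution, so higher-order
#' interpolation adds nothing). An exact grid hit returns the stored value.
#'
#' @param spec An [absorbance_spectrum()].
#' @param lambda Query wavelength in nm, inside the spectrum's grid.
#' @return Absorbance value; `NA` with attribute `flag = "undefined_neighbor"`
#'   when a bracketing grid point is undefined.
#' @export
absorbance_at <- function(spec, lambda) {
  stopifnot(inherits(spec, "absorbance_spectrum"), length(lambda) == 1)
  w <- spec$wavelengths
  if (lambda < w[1] || lambda > w[length(w)])
    stop(sprintf("wavelength %.1f nm outside the spectrum range %.1f-%.1f nm",
                 lambda, w[1], w[length(w)]))
  hit <- which(w == lambda)
  if (length(hit)) return(spec$absorbance[hit[1]])
  hi <- which(w > lambda)[1]; lo <- hi - 1L
  a <- spec$absorbance[c(lo, hi)]
  if (anyNA(a)) {
    out <- NA_real_
    attr(out, "flag") <- "undefined_neighbor"
    return(out)
  }
  a[1] + (a[2] - a[1]) * (lambda - w[lo]) / (w[hi] - w[lo])
}
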