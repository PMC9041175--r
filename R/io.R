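# Plain-text interchange formats. CSV dialect: comma-separated, UTF-8, LF,
# with `# key=value` header metadata lines before the column header.

read_hash_header <- function(lines) {
  hdr <- grep("^#", lines)
  kv <- list()
  for (i in hdr) {
    body <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0)
      kv[[substr(body, 1, eq - 1)]] <- substr(body, eq + 1, nchar(body))
  }
  list(meta = kv, n_header = if (length(hdr)) max(hdr) else 0L)
}

#' Write a raw frame to CSV
#'
#' Format: `# key=value` metadata lines (`bits`, `exposure_us`, `role`,
#' `n_pixels`, `frame_id`), then `pixel,count` rows with 0-based pixel
#' indices. Integer counts round-trip losslessly.
#'
#' @param frame A [raw_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "raw_spectrum"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# bits=%d", frame$bits),
           sprintf("# exposure_us=%g", frame$exposure_us),
           sprintf("# role=%s", frame$role),
           sprintf("# n_pixels=%d", length(frame$counts)),
           sprintf("# frame_id=%s", frame$frame_id),
           "pixel,count",
           sprintf("%d,%d", seq_along(frame$counts) - 1L, frame$counts))
  writeLines(hdr, con, sep = "\n")
  invisible(path)
}

#' Read a raw frame from CSV
#'
#' Validates the header keys, the ADC range of every count and the row count
#' against `n_pixels`; malformed rows are reported with their line number.
#'
#' @param path Path to a file written by [write_frame_csv()].
#' @return A [raw_spectrum()].
#' @export
read_frame_csv <- function(path) {
  lines <- readLines(path)
  h <- read_hash_header(lines)
  need <- c("bits", "exposure_us", "role", "n_pixels")
  miss <- setdiff(need, names(h$meta))
  if (length(miss))
    stop("frame CSV ", path, " is missing header key(s): ",
         paste(miss, collapse = ", "))
  body <- lines[(h$n_header + 1):length(lines)]
  body <- body[nzchar(body)]
  if (!length(body) || body[1] != "pixel,count")
    stop("frame CSV ", path, ": expected 'pixel,count' column header at line ",
         h$n_header + 1)
  rows <- body[-1]
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("frame CSV ", path, ": malformed row at line ",
         h$n_header + 1 + bad[1])
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(counts))
    stop("frame CSV ", path, ": non-numeric count at line ",
         h$n_header + 1 + which(is.na(counts))[1])
  n_pixels <- as.integer(h$meta$n_pixels)
  if (length(counts) != n_pixels)
    stop("frame CSV ", path, ": ", length(counts),
         " data rows but header says n_pixels=", n_pixels)
  raw_spectrum(counts, exposure_us = as.numeric(h$meta$exposure_us),
               role = h$meta$role, bits = as.integer(h$meta$bits),
               frame_id = h$meta$frame_id %||% basename(path))
}

#' Write an absorbance spectrum to CSV
#'
#' Columns `wavelength_nm,absorbance,flag`; reals carry 6 significant digits,
#' undefined points are written as `NA`. Provenance identifiers go into the
#' `#` header.
#'
#' @param spec An [absorbance_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_absorbance_csv <- function(spec, path) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  con <- file(path, "wb")
  on.exit(close(con))
  prov <- spec$provenance
  hdr <- unlist(lapply(names(prov), function(k)
    sprintf("# %s=%s", k, as.character(prov[[k]]))))
  fmt6 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  writeLines(c(hdr, "wavelength_nm,absorbance,flag",
               sprintf("%s,%s,%s", fmt6(spec$wavelengths),
                       fmt6(spec$absorbance), spec$flags)),
             con, sep = "\n")
  invisible(path)
}

#' Read an absorbance spectrum from CSV
#' @param path Path to a file written by [write_absorbance_csv()].
#' @return An [absorbance_spectrum()].
#' @export
read_absorbance_csv <- function(path) {
  lines <- readLines(path)
  h <- read_hash_header(lines)
  df <- read.csv(text = paste(lines[(h$n_header + 1):length(lines)],
                              collapse = "\n"),
                 stringsAsFactors = FALSE)
  stopifnot(all(c("wavelength_nm", "absorbance", "flag") %in% names(df)))
  absorbance_spectrum(df$wavelength_nm, df$absorbance, df$flag,
                      provenance = h$meta)
}

#' Read / write a calibration map as JSON
#'
#' Coefficient list is stored lowest order first.
#'
#' @param cal A [wavelength_calibration()].
#' @param path File path.
#' @return `write_calibration_json()` returns `path` invisibly;
#'   `read_calibration_json()` returns a [wavelength_calibration()].
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "wavelength_calibration"))
  jsonlite::write_json(
    list(coefficients = cal$coefficients,
         pixel_range = cal$pixel_range,
         working_range = cal$working_range),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  wavelength_calibration(j$coefficients, j$pixel_range, j$working_range)
}

#' Read a calibration series from CSV
#'
#' Columns `concentration,response` with optional `day` and `replicate`; a
#' `# unit=<label>` header line declares the (opaque) concentration unit.
#'
#' @param path File path.
#' @return A [calibration_series()].
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path)
  h <- read_hash_header(lines)
  df <- read.csv(text = paste(lines[(h$n_header + 1):length(lines)],
                              collapse = "\n"),
                 stringsAsFactors = FALSE)
  calibration_series(df, unit = h$meta$unit %||% "conc")
}

#' Write a calibration series to CSV
#' @param series A [calibration_series()] or conforming data frame.
#' @param path File path.
#' @param unit Unit label for the header; defaults to the series attribute.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, unit = NULL) {
  unit <- unit %||% attr(series, "unit") %||% "conc"
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s", unit), con, sep = "\n")
  df <- as.data.frame(unclass(series)[
    intersect(c("concentration", "response", "day", "replicate"),
              names(series))])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a full instrument configuration as JSON
#'
#' Serialises the source bands and intensity scale, all detector fields and
#' the calibration polynomial in one structured file, so a simulation is
#' reproducible from `(config, seed)` alone.
#'
#' @param model An [instrument_model()].
#' @param path File path.
#' @return `write_instrument_config()` returns `path` invisibly;
#'   `read_instrument_config()` returns an [instrument_model()].
#' @export
write_instrument_config <- function(model, path) {
  stopifnot(inherits(model, "instrument_model"))
  jsonlite::write_json(
    list(source = list(bands = model$source$bands,
                       peak_counts = model$source$peak_counts),
         detector = unclass(model$detector),
         calibration = list(coefficients = model$calibration$coefficients,
                            pixel_range = model$calibration$pixel_range,
                            working_range = model$calibration$working_range)),
    path, digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_instrument_config
#' @export
read_instrument_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  instrument_model(
    source = source_model(as.data.frame(j$source$bands), j$source$peak_counts),
    detector = detector_model(j$detector$n_pixels, j$detector$bits,
                              j$detector$dark_mean, j$detector$dark_rms,
                              j$detector$slit_fwhm, j$detector$exposure_ref,
                              isTRUE(j$detector$shot_noise)),
    calibration = wavelength_calibration(j$calibration$coefficients,
                                         j$calibration$pixel_range,
                                         j$calibration$working_range))
}

#' Packaged example calibration series
#'
#' Published validation series for this class of miniature spectrophotometer,
#' shipped as plain-text fixtures: `"b12"` (vitamin B12, 3-24 ppm, read at
#' 550 nm), `"phosphate"` (total phosphorus, 0-2 ppm, 700 nm) and
#' `"peroxidase"` (H2O2 via HRP/TMB, 0-264 uM, 600 nm; its upper level lies
#' beyond the linear range -- see [linear_range_check()]).
#'
#' @param name One of `"b12"`, `"phosphate"`, `"peroxidase"`.
#' @return A [calibration_series()].
#' @export
example_series <- function(name = c("b12", "phosphate", "peroxidase")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_calibration.csv"),
                      package = "vispec", mustWork = TRUE)
  read_series_csv(path)
}
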