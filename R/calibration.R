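#' Validate a concentration-response series
#'
#' @param x Data frame with numeric columns `concentration` and `response`
#'   (optionally `day` and `replicate` grouping labels).
#' @param unit Declared concentration unit label (opaque; e.g. `"ppm"`,
#'   `"uM"`). Never converted.
#' @return The data frame, classed `calibration_series`, with the unit as an
#'   attribute.
#' @export
calibration_series <- function(x, unit = "conc") {
  stopifnot(is.data.frame(x),
            all(c("concentration", "response") %in% names(x)))
  if (!all(is.finite(x$response))) stop("responses must be finite")
  if (!all(is.finite(x$concentration)) || any(x$concentration < 0))
    stop("concentrations must be finite and nonnegative")
  attr(x, "unit") <- unit
  class(x) <- unique(c("calibration_series", class(x)))
  x
}

#' Ordinary least-squares calibration fit with LOD/LOQ
#'
#' Fits `response = a + b * concentration` by unweighted OLS and derives the
#' analytical figures of merit: the coefficient of determination
#' `R^2 = 1 - SSE/SST`, the standard error of the intercept
#' `S_d = s * sqrt(1/n + xbar^2/Sxx)` (with `s^2 = SSE/(n-2)`), and the
#' limits of detection and quantification
#'
#' \deqn{LOD = 3.3 S_d / b, \qquad LOQ = 10 S_d / b.}
#'
#' The 3.3/10 multipliers follow the ICH-style convention (LOD < LOQ, ratio
#' 10/3.3 ~ 3); see the methods vignette for why this assignment is the one
#' consistent with published validation tables for this class of device.
#' Zero-concentration (blank) points take part in the fit. When the slope is
#' nonpositive the fit is still returned but LOD/LOQ are `NA` with flag
#' `"not_applicable"`.
#'
#' @param series A [calibration_series()] or a data frame with columns
#'   `concentration` and `response`; at least 3 distinct levels.
#' @return An object of class `calibration_fit` with elements `a`, `b`,
#'   `se_a`, `se_b`, `r2`, `lod`, `loq`, `n`, `dof`, `residual_sd`, `unit`,
#'   `flag`.
#' @export
fit_calibration <- function(series) {
  if (!inherits(series, "calibration_series")) series <- calibration_series(series)
  x <- series$concentration; y <- series$response
  if (length(unique(x)) < 3)
    stop("degenerate design: need >= 3 distinct concentration levels")
  if (var(x) == 0) stop("degenerate design: zero concentration variance")
  fit <- lm(y ~ x)
  # summary.lm warns on zero-residual input; a perfect synthetic line is a
  # legitimate series here (its limits are exactly zero)
  sm <- suppressWarnings(summary(fit))
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  se_a <- sm$coefficients[1, 2]; se_b <- sm$coefficients[2, 2]
  flag <- "ok"
  if (b > 0) {
    lod <- 3.3 * se_a / b
    loq <- 10 * se_a / b
  } else {
    lod <- NA_real_; loq <- NA_real_; flag <- "not_applicable"
  }
  structure(
    list(a = a, b = b, se_a = se_a, se_b = se_b, r2 = sm$r.squared,
         lod = lod, loq = loq, n = length(x), dof = fit$df.residual,
         residual_sd = sm$sigma, unit = attr(series, "unit") %||% "conc",
         flag = flag),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  A = %.4g + %.4g * c   (n = %d, dof = %d)\n", x$a, x$b, x$n, x$dof))
  cat(sprintf("  se(intercept) = %.4g, se(slope) = %.4g, residual sd = %.4g\n",
              x$se_a, x$se_b, x$residual_sd))
  cat(sprintf("  R^2 = %.3f\n", x$r2))
  if (x$flag == "ok")
    cat(sprintf("  LOD = %.1f %s, LOQ = %.1f %s\n", x$lod, x$unit, x$loq, x$unit))
  else
    cat("  LOD/LOQ not applicable (nonpositive slope)\n")
  invisible(x)
}

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` with the n-1 standard deviation. A zero mean gives `NA`
#' with attribute `flag = "undefined_mean"`.
#'
#' @param values At least two numeric values.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("rsd() needs at least 2 values")
  m <- mean(values)
  if (m == 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined_mean"
    return(out)
  }
  100 * sd(values) / m
}

#' Intra- and inter-day precision table
#'
#' Per concentration level: intra-day RSD is the RSD over replicates within a
#' day, averaged across days; inter-day RSD is the RSD over the day means.
#' Column averages are appended (the "Average" row of a validation table).
#' Levels with a single replicate or a single day are flagged `NA` for the
#' affected column and excluded from its average.
#'
#' @param series Data frame with columns `concentration`, `response`, `day`,
#'   `replicate`.
#' @return An object of class `precision_report`: element `table` (one row per
#'   level with `inter_rsd_pct`, `intra_rsd_pct`, `n_days`, `n_replicates`)
#'   and element `average` (named vector of column means over usable levels).
#' @export
precision_table <- function(series) {
  stopifnot(all(c("concentration", "response", "day") %in% names(series)))
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  levels_ <- sort(unique(series$concentration))
  rows <- lapply(levels_, function(cc) {
    sub <- series[series$concentration == cc, ]
    day_means <- tapply(sub$response, sub$day, mean)
    n_days <- length(day_means)
    inter <- if (n_days >= 2) as.numeric(rsd(as.numeric(day_means))) else NA_real_
    intra_by_day <- tapply(sub$response, sub$day, function(v)
      if (length(v) >= 2) as.numeric(rsd(v)) else NA_real_)
    intra <- if (all(is.na(intra_by_day))) NA_real_
             else mean(intra_by_day, na.rm = TRUE)
    data.frame(concentration = cc, inter_rsd_pct = inter,
               intra_rsd_pct = intra, n_days = n_days,
               n_replicates = max(tapply(sub$response, sub$day, length)))
  })
  tab <- do.call(rbind, rows)
  avg <- c(inter_rsd_pct = mean(tab$inter_rsd_pct, na.rm = TRUE),
           intra_rsd_pct = mean(tab$intra_rsd_pct, na.rm = TRUE))
  structure(list(table = tab, average = avg), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>\n")
  tab <- x$table
  tab$inter_rsd_pct <- round(tab$inter_rsd_pct, 2)
  tab$intra_rsd_pct <- round(tab$intra_rsd_pct, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("  Average: inter %.2f%%, intra %.2f%%\n",
              x$average["inter_rsd_pct"], x$average["intra_rsd_pct"]))
  invisible(x)
}

#' Inverse prediction from a calibration fit
#'
#' `c = (A - a) / b`, annotated against the fit's LOD and LOQ.
#'
#' @param fit A [fit_calibration()] result with nonzero slope.
#' @param absorbance Absorbance value(s).
#' @return Numeric concentration(s) with attribute `annotation`: `"ok"`,
#'   `"below_loq"` or `"below_lod"` per value.
#' @export
predict_concentration <- function(fit, absorbance) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$b == 0) stop("cannot invert a calibration with zero slope")
  conc <- (absorbance - fit$a) / fit$b
  ann <- rep("ok", length(conc))
  if (!is.na(fit$loq)) ann[conc < fit$loq] <- "below_loq"
  if (!is.na(fit$lod)) ann[conc < fit$lod] <- "below_lod"
  attr(conc, "annotation") <- ann
  conc
}

#' Check the top of the linear range
#'
#' Refits the calibration without the highest concentration level and
#' examines the externally studentized residual of that level's mean response
#' under the reduced fit. A residual beyond `threshold` flags the top level as
#' diverging from linearity (the onset of calibration-curve rollover).
#'
#' @param series A [calibration_series()] or conforming data frame with at
#'   least 4 distinct levels.
#' @param threshold Studentized-residual threshold; default 3.
#' @return List with `top_level`, `studentized_residual`, `threshold`,
#'   `divergent` (logical) and the reduced `fit`.
#' @export
linear_range_check <- function(series, threshold = 3) {
  if (!inherits(series, "calibration_series")) series <- calibration_series(series)
  levs <- sort(unique(series$concentration))
  if (length(levs) < 4) stop("linear_range_check() needs >= 4 distinct levels")
  top <- levs[length(levs)]
  keep <- series$concentration < top
  red <- series[keep, , drop = FALSE]
  x <- red$concentration; y <- red$response
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))$sigma
  n <- length(x); xbar <- mean(x); sxx <- sum((x - xbar)^2)
  ytop <- series$response[!keep]
  m <- length(ytop)
  yhat <- unname(coef(fit)[1] + coef(fit)[2] * top)
  pred_se <- s * sqrt(1 / m + 1 / n + (top - xbar)^2 / sxx)
  t_ext <- (mean(ytop) - yhat) / pred_se
  list(top_level = top, studentized_residual = t_ext, threshold = threshold,
       divergent = is.finite(t_ext) && abs(t_ext) > threshold,
       fit = fit_calibration(calibration_series(
         red, unit = attr(series, "unit") %||% "conc")))
}
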