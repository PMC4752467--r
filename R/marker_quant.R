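#' Fit a calibration curve for a marker compound
#'
#' Ordinary least squares of peak area on injected concentration,
#' `area = slope * conc + intercept`, with `r_squared` the squared Pearson
#' correlation.
#'
#' @param concentrations Injected concentrations (ug/mL), at least 3 distinct.
#' @param areas Corresponding peak areas.
#' @param analyte Optional analyte name.
#' @param lod,loq Optional detection/quantification limits (ug/mL); see
#'   [lod_loq()].
#' @return An object of class `calibration_curve`.
#' @export
fit_calibration <- function(concentrations, areas, analyte = NA_character_,
                            lod = NA_real_, loq = NA_real_) {
  if (length(concentrations) < 3L) {
    fq_stop("insufficient data: calibration needs at least 3 points")
  }
  if (length(areas) != length(concentrations)) {
    fq_stop("'concentrations' and 'areas' must have equal length")
  }
  if (stats::var(concentrations) == 0) {
    fq_stop("degenerate calibration: zero concentration variance")
  }
  fit <- stats::lm(areas ~ concentrations)
  calibration_curve(analyte = analyte,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r_squared = stats::cor(concentrations, areas)^2,
                    lod = lod, loq = loq,
                    linear_range = range(concentrations))
}

#' @rdname fit_calibration
#' @param slope,intercept,r_squared Curve parameters (slope > 0).
#' @param linear_range Length-2 numeric, low < high (ug/mL).
#' @export
calibration_curve <- function(analyte, slope, intercept, r_squared = NA_real_,
                              lod = NA_real_, loq = NA_real_,
                              linear_range = c(NA_real_, NA_real_)) {
  if (!is_scalar_number(slope) || slope <= 0) {
    fq_stop("calibration slope must be positive")
  }
  if (!anyNA(linear_range) && linear_range[1] >= linear_range[2]) {
    fq_stop("linear_range must satisfy low < high")
  }
  if (!is.na(lod) && !is.na(loq) && lod >= loq) fq_stop("need lod < loq")
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared, lod = lod, loq = loq,
                 linear_range = as.numeric(linear_range)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: y = %.4g x + %.4g (R2 = %.4f)\n",
              x$analyte, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a calibration curve to quantify a peak
#'
#' `conc = (area - intercept) / slope * dilution_factor`. Results outside the
#' curve's linear range or below the LOQ are flagged, not rejected: the
#' attributes `below_loq` and `outside_range` carry logical vectors aligned
#' with the result.
#'
#' @param curve A [calibration_curve()].
#' @param area Peak area(s).
#' @param dilution_factor Multiplier converting injected concentration
#'   (ug/mL) to concentration in the preparation (e.g. mg/L); supply the
#'   factor for your sample workup explicitly.
#' @return Numeric concentration(s) with flag attributes.
#' @export
quantify <- function(curve, area, dilution_factor = 1) {
  if (!inherits(curve, "calibration_curve")) {
    fq_stop("'curve' must be a calibration_curve")
  }
  injected <- (area - curve$intercept) / curve$slope
  out <- injected * dilution_factor
  attr(out, "below_loq") <- if (is.na(curve$loq)) rep(NA, length(out)) else
    injected < curve$loq
  attr(out, "outside_range") <- if (anyNA(curve$linear_range))
    rep(NA, length(out)) else
    injected < curve$linear_range[1] | injected > curve$linear_range[2]
  out
}

#' Detection and quantification limits from baseline noise
#'
#' Signal-to-noise based limits: LOD at S/N = 3 and LOQ at S/N = 10, i.e.
#' `lod = 3 * noise_sd / slope`, `loq = 10 * noise_sd / slope`.
#'
#' @param noise_sd Baseline noise standard deviation (area units).
#' @param slope Calibration slope (area per ug/mL).
#' @return Named numeric vector `c(lod = , loq = )` in ug/mL.
#' @export
lod_loq <- function(noise_sd, slope) {
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    fq_stop("'noise_sd' must be positive")
  }
  if (!is_scalar_number(slope) || slope <= 0) {
    fq_stop("'slope' must be positive")
  }
  c(lod = 3 * noise_sd / slope, loq = 10 * noise_sd / slope)
}

#' Percent contents relative to the across-batch mean, and P_7C
#'
#' Each marker content is expressed as percent of its unrounded across-batch
#' column mean, with not-detected (NA) entries contributing 0 to the mean
#' (so each percent column averages exactly 100). `p7c` is the per-batch
#' mean of the marker percent contents, with ND counted as 0 over all M
#' markers — a single scalar tracking how a batch's marker totals sit
#' relative to the cohort.
#'
#' @param contents Numeric B x M matrix or data.frame of contents (mg/L);
#'   `NA` marks not-detected.
#' @return A list: `percent` (B x M matrix, NA preserved where ND) and `p7c`
#'   (length-B vector).
#' @export
percent_contents <- function(contents) {
  m <- as.matrix(contents)
  if (!nrow(m)) fq_stop("need at least one batch")
  filled <- m
  filled[is.na(filled)] <- 0
  cm <- colMeans(filled)
  if (any(cm <= 0)) {
    fq_stop(sprintf("degenerate column (all-ND or zero mean): %s",
                    paste(colnames(m)[cm <= 0], collapse = ", ")))
  }
  percent <- sweep(m, 2, cm, "/") * 100
  pfill <- percent
  pfill[is.na(pfill)] <- 0
  list(percent = percent, p7c = rowMeans(pfill))
}

#' Column mean and relative standard deviation with the ND-as-zero convention
#'
#' Not-detected entries (NA) are counted as 0; the mean is over all B
#' entries and the RSD uses the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector (length >= 2); NA marks not-detected.
#' @return Named numeric vector `c(mean = , rsd = )` (rsd in percent).
#' @export
summarize_column <- function(values) {
  if (length(values) < 2L) fq_stop("need at least two values")
  v <- ifelse(is.na(values), 0, values)
  m <- mean(v)
  if (m == 0) fq_stop("undefined RSD: column mean is zero")
  c(mean = m, rsd = stats::sd(v) / m * 100)
}
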