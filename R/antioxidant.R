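#' DPPH percent inhibition from absorbances
#'
#' Radical-scavenging capacity at 517 nm:
#' \deqn{\%inhibition = \frac{A_{control} - A_{sample}}{A_{control}} \times 100}
#' Negative values (sample absorbing more than the control) are returned
#' as-is with a warning — they usually indicate sample colour interference.
#'
#' @param a_control Absorbance of the negative control (> 0).
#' @param a_sample Absorbance with the sample present.
#' @return Percent inhibition (vectorized).
#' @export
inhibition <- function(a_control, a_sample) {
  if (any(!is.finite(a_control)) || any(a_control <= 0)) {
    fq_stop("'a_control' must be positive")
  }
  out <- (a_control - a_sample) / a_control * 100
  if (any(out < 0)) warning("negative inhibition value(s) returned as-is")
  out
}

#' Estimate IC50 from a DPPH concentration series
#'
#' Fits a least-squares line of percent inhibition on concentration over the
#' tested range and inverts it at 50%: `ic50 = (50 - intercept) / slope`.
#' When 50% inhibition is not bracketed by the observed inhibitions the
#' estimate is an extrapolation and flagged as such.
#'
#' @param concentrations Sample concentrations (mg/mL), >= 3 distinct levels.
#' @param inhibitions Percent inhibition at each concentration.
#' @param batch_id Optional identifier.
#' @return An object of class `dpph_result` with fields `batch_id`,
#'   `concentrations`, `inhibitions`, `ic50` (mg/mL), `fit`
#'   (`c(slope, intercept)`) and `extrapolated`.
#' @examples
#' estimate_ic50(c(2, 4, 6), c(30, 50, 70))$ic50  # 4
#' @export
estimate_ic50 <- function(concentrations, inhibitions,
                          batch_id = NA_character_) {
  if (length(unique(concentrations)) < 3L) {
    fq_stop("need at least 3 distinct concentration levels")
  }
  if (length(inhibitions) != length(concentrations)) {
    fq_stop("'concentrations' and 'inhibitions' must have equal length")
  }
  fit <- stats::lm(inhibitions ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    fq_compute_stop(sprintf(
      "no dose-response: inhibition slope %.4g <= 0 for batch %s",
      slope, batch_id))
  }
  ic50 <- (50 - intercept) / slope
  structure(list(batch_id = batch_id,
                 concentrations = as.numeric(concentrations),
                 inhibitions = as.numeric(inhibitions),
                 ic50 = ic50,
                 fit = c(slope = slope, intercept = intercept),
                 extrapolated = !(min(inhibitions) <= 50 &&
                                    50 <= max(inhibitions))),
            class = "dpph_result")
}

#' @export
print.dpph_result <- function(x, ...) {
  cat(sprintf("<dpph_result> %s: IC50 = %.3g mg/mL%s\n", x$batch_id, x$ic50,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Detect negative (activity) peaks in a post-column 517 nm trace
#'
#' In an on-line DPPH assay antioxidant analytes bleach the radical and show
#' as negative excursions at 517 nm. The baseline is a rolling median over
#' `baseline_window` minutes; contiguous sub-baseline runs whose maximum
#' depth reaches `min_depth` are reported, apex at the deepest sample.
#'
#' @param time Uniformly sampled time axis (minutes, strictly increasing).
#' @param intensity Detector signal at 517 nm.
#' @param baseline_window Rolling-median window in minutes (default 2).
#' @param min_depth Minimum excursion depth (signal units); a sensible choice
#'   is about 3x the trace noise SD.
#' @return data.frame with columns `apex_time`, `depth` (positive
#'   magnitudes), one row per activity peak, in elution order.
#' @export
detect_activity_peaks <- function(time, intensity, baseline_window = 2,
                                  min_depth) {
  if (length(time) != length(intensity)) {
    fq_stop("'time' and 'intensity' must have equal length")
  }
  if (any(diff(time) <= 0)) fq_stop("'time' must be strictly increasing")
  if (!is_scalar_number(min_depth) || min_depth <= 0) {
    fq_stop("'min_depth' must be positive")
  }
  dt <- stats::median(diff(time))
  k <- max(3L, as.integer(round(baseline_window / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(intensity) - (1L - length(intensity) %% 2L))
  baseline <- stats::runmed(intensity, k, endrule = "median")
  resid <- intensity - baseline
  below <- resid < 0
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    depth <- -min(resid[seg])
    if (depth >= min_depth) {
      apex <- seg[which.min(resid[seg])]
      out[[length(out) + 1L]] <- data.frame(apex_time = time[apex],
                                            depth = depth)
    }
  }
  if (!length(out)) {
    return(data.frame(apex_time = numeric(0), depth = numeric(0)))
  }
  do.call(rbind, out)
}

#' Post-column reaction-coil delay from geometry and flow
#'
#' The lag between the 260 nm detector and the 517 nm detector equals the
#' coil volume divided by the combined flow: `pi * (id/2)^2 * length / flow`.
#' Defaults describe a 5000 mm x 0.18 mm i.d. coil at 0.8 + 0.3 = 1.1 mL/min,
#' giving about 0.116 min.
#'
#' @param length_mm Coil length (mm).
#' @param id_mm Coil internal diameter (mm).
#' @param flow_ml_min Combined flow rate through the coil (mL/min).
#' @return Delay in minutes.
#' @export
coil_delay <- function(length_mm = 5000, id_mm = 0.18, flow_ml_min = 1.1) {
  if (any(c(length_mm, id_mm, flow_ml_min) <= 0)) {
    fq_stop("coil dimensions and flow must be positive")
  }
  volume_ml <- pi * (id_mm / 2)^2 * length_mm / 1000
  volume_ml / flow_ml_min
}

#' Associate parent 260 nm peaks with 517 nm activity peaks
#'
#' Parent retention times are shifted by the post-column `delay` and matched
#' greedily (closest pairs first, one-to-one) to activity-peak apexes within
#' `tolerance`. Parents with no activity peak in reach map to `NA` — the
#' signature of a component with no detectable radical scavenging.
#'
#' @param parent_rt Named (or unnamed) numeric vector of parent retention
#'   times at 260 nm (minutes).
#' @param activity_peaks data.frame from [detect_activity_peaks()].
#' @param delay Post-column delay in minutes (>= 0); see [coil_delay()].
#' @param tolerance Matching tolerance in minutes.
#' @param batch_id Optional identifier.
#' @return An object of class `activity_fingerprint`: fields `batch_id`,
#'   `activity_peaks`, `associations` (integer index into `activity_peaks`
#'   per parent, NA when unmatched) and `delay`.
#' @export
associate_activity <- function(parent_rt, activity_peaks, delay = coil_delay(),
                               tolerance = 0.05, batch_id = NA_character_) {
  if (!is_scalar_number(delay) || delay < 0) fq_stop("'delay' must be >= 0")
  expected <- parent_rt + delay
  np <- length(expected); na <- nrow(activity_peaks)
  assoc <- rep(NA_integer_, np)
  if (na > 0 && np > 0) {
    d <- abs(outer(expected, activity_peaks$apex_time, "-"))
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used <- logical(na)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; a <- cand[i, 2]
        if (is.na(assoc[p]) && !used[a]) {
          assoc[p] <- a
          used[a] <- TRUE
        }
      }
    }
  }
  names(assoc) <- names(parent_rt) %||% as.character(seq_len(np))
  structure(list(batch_id = batch_id, activity_peaks = activity_peaks,
                 associations = assoc, delay = delay),
            class = "activity_fingerprint")
}
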