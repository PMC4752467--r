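# Bundled reference dataset: published per-batch summary values for 23
# commercial batches of Ixeris sonchifolia (Bunge) Hance injectable (ISHI).
# The raw chromatograms behind these summaries are not public; the package
# ships the printed per-batch tables as plain CSV so that the derived
# arithmetic (multi-wavelength integration, grading, percent contents) can be
# recomputed and checked.

ishi_file <- function(name) {
  system.file("extdata", name, package = "fingerqc", mustWork = TRUE)
}

#' Bundled ISHI reference tables
#'
#' `ishi_marker_contents()` returns the per-batch contents (mg/L) of the
#' seven marker compounds — uridine (UR), adenosine (AD), chlorogenic acid
#' (CGA), caffeic acid (CFA), chicoric acid (CCA),
#' luteolin-7-beta-D-glucuronide (LGR), luteolin-7-glucoside (LG) — plus the
#' off-line DPPH IC50 (mg/mL) for 23 batches; not-detected entries are `NA`.
#' `ishi_marker_percent()` returns the corresponding published percent
#' contents and P7C. `ishi_sqfm_table()` returns the published SQFM
#' evaluation (S_m, P_m, alpha, grade) per batch at 260/265/330/335/350 nm
#' plus the `"integrated"` rows (batch `"RFP"` is the reference evaluated
#' against itself). `ishi_calibration_curves()` returns the seven marker
#' calibration curves as a list of [calibration_curve()] objects.
#'
#' @return A data.frame (or list of `calibration_curve` for
#'   `ishi_calibration_curves()`).
#' @export
ishi_marker_contents <- function() {
  utils::read.csv(ishi_file("ishi_marker_contents.csv"), na.strings = "ND")
}

#' @rdname ishi_marker_contents
#' @export
ishi_marker_percent <- function() {
  utils::read.csv(ishi_file("ishi_marker_percent.csv"), na.strings = "ND")
}

#' @rdname ishi_marker_contents
#' @export
ishi_sqfm_table <- function() {
  utils::read.csv(ishi_file("ishi_sqfm_table.csv"),
                  colClasses = c(wavelength = "character"))
}

#' @rdname ishi_marker_contents
#' @export
ishi_calibration_curves <- function() {
  df <- utils::read.csv(ishi_file("ishi_calibration.csv"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    calibration_curve(analyte = df$analyte[i], slope = df$slope[i],
                      intercept = df$intercept[i],
                      r_squared = df$r_squared[i],
                      lod = df$lod[i], loq = df$loq[i],
                      linear_range = c(df$range_low[i], df$range_high[i]))
  })
  stats::setNames(out, df$analyte)
}
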