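#' Qualitative similarity of a sample fingerprint to a reference
#'
#' The cosine of the angle between the sample area vector x and the reference
#' area vector y:
#' \deqn{S_F = \frac{\sum x_i y_i}{\sqrt{\sum x_i^2}\sqrt{\sum y_i^2}}}
#' It measures similarity of the composition ratio but is dominated by large
#' peaks; see [ratio_similarity()] for the equal-weight complement.
#'
#' @param x,y Non-negative area vectors of equal length (n >= 2), neither
#'   all-zero.
#' @return A number in (0, 1] for valid non-negative inputs.
#' @examples
#' qualitative_similarity(c(1, 2, 3), c(3, 2, 1))  # 10/14
#' @export
qualitative_similarity <- function(x, y) {
  check_sqfm_pair(x, y)
  sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

#' Qualitative ratio similarity
#'
#' To give every peak equal weight, the sample is transformed to the ratio
#' vector r = (x1/y1, ..., xn/yn) and compared against the unit vector
#' (1, ..., 1):
#' \deqn{S_F' = \frac{\sum r_i}{\sqrt{n}\sqrt{\sum r_i^2}}}
#' Equals 1 exactly when x is proportional to y.
#'
#' @inheritParams qualitative_similarity
#' @param zero_policy What to do when some `y[i]` is 0: `"error"` (default)
#'   or `"drop"` the offending peak pairs with a warning. Common peaks built
#'   by [match_common_peaks()] have positive reference entries, so zeros
#'   normally indicate an upstream problem.
#' @return A number in (0, 1].
#' @export
ratio_similarity <- function(x, y, zero_policy = c("error", "drop")) {
  zero_policy <- match.arg(zero_policy)
  check_sqfm_pair(x, y)
  if (any(y == 0)) {
    if (zero_policy == "error") {
      fq_stop("reference vector has zero entries; see 'zero_policy'")
    }
    warning("dropping ", sum(y == 0), " peak pair(s) with zero reference area")
    x <- x[y > 0]; y <- y[y > 0]
    if (length(y) < 2L) fq_stop("fewer than two peaks left after dropping")
  }
  r <- x / y
  sum(r) / (sqrt(length(r)) * sqrt(sum(r^2)))
}

check_sqfm_pair <- function(x, y) {
  if (length(x) != length(y)) {
    fq_stop("fingerprint vectors must have equal length")
  }
  if (length(x) < 2L) fq_stop("fingerprint vectors need at least two peaks")
  check_area_vector(x, "x"); check_area_vector(y, "y")
  if (sum(x) == 0 || sum(y) == 0) {
    fq_stop("degenerate input: zero-norm fingerprint vector")
  }
  invisible(TRUE)
}

#' Evaluate one sample fingerprint against a reference by SQFM
#'
#' Computes the seven quantities of the systematic quantitative fingerprint
#' method for a sample vector x against a reference vector y:
#' qualitative similarity `S_F`, ratio similarity `S_F'`, macro qualitative
#' similarity `S_m = (S_F + S_F')/2`, projection content similarity
#' `C = 100 * sum(x*y)/sum(y^2)`, quantitative similarity
#' `P = 100 * S_F * sum(x)/sum(y)`, macro quantitative similarity
#' `P_m = (C + P)/2`, and the leveling coefficient `alpha = |1 - P/C|`.
#' `S_m` tracks composition, `P_m` overall content (100 means equal to the
#' reference), and `alpha` flags disproportion between the two content views.
#'
#' @param x Sample area vector.
#' @param y Reference areas: a numeric vector or a `reference_fingerprint`.
#' @param batch_id,wavelength Optional identifiers carried into the result.
#' @param zero_policy Passed to [ratio_similarity()].
#' @return An object of class `sqfm_result`: a list with fields `batch_id`,
#'   `wavelength`, `s_f`, `s_f_prime`, `s_m`, `c`, `p`, `p_m`, `alpha` and
#'   (once assigned) `grade`.
#' @examples
#' r <- sqfm_evaluate(c(2, 4, 6), c(1, 2, 3))
#' r$s_m    # 1: same composition
#' r$p_m    # 200: twice the content
#' @export
sqfm_evaluate <- function(x, y, batch_id = NA_character_,
                          wavelength = NA_integer_,
                          zero_policy = c("error", "drop")) {
  if (inherits(y, "reference_fingerprint")) {
    if (is.na(wavelength)) wavelength <- y$wavelength
    y <- y$areas
  }
  s_f <- qualitative_similarity(x, y)
  s_f_prime <- ratio_similarity(x, y, zero_policy = zero_policy)
  s_m <- (s_f + s_f_prime) / 2
  c_sim <- sum(x * y) / sum(y^2) * 100
  p_sim <- sum(x) / sum(y) * s_f * 100
  p_m <- (c_sim + p_sim) / 2
  alpha <- abs(1 - p_sim / c_sim)
  structure(list(batch_id = batch_id, wavelength = wavelength,
                 s_f = s_f, s_f_prime = s_f_prime, s_m = s_m,
                 c = c_sim, p = p_sim, p_m = p_m, alpha = alpha,
                 grade = NA_integer_),
            class = "sqfm_result")
}

#' @export
print.sqfm_result <- function(x, ...) {
  cat(sprintf(
    "<sqfm_result> %s @ %s nm: Sm=%.2f Pm=%.1f%% alpha=%.2f grade=%s\n",
    x$batch_id, x$wavelength, x$s_m, x$p_m, x$alpha,
    ifelse(is.na(x$grade), "?", x$grade)))
  invisible(x)
}

#' The eight-band SQFM quality grade table
#'
#' Grades 1 (best) to 7 each require a minimum macro qualitative similarity
#' `S_m`, a window on the macro quantitative similarity `P_m` (percent) and a
#' cap on the leveling coefficient `alpha`; grade 8 is the catch-all. The
#' default bands shipped with the package are
#' `S_m >= 0.95/0.90/0.85/0.80/0.70/0.60/0.50`,
#' `P_m` within 95-105 / 90-110 / 80-120 / 75-125 / 70-130 / 60-140 / 50-150,
#' and `alpha <= 0.05/0.10/0.15/0.20/0.25/0.30/0.35`. Alternative criteria
#' can be loaded from a CSV with columns
#' `grade,min_sm,pm_low,pm_high,max_alpha` (NA bounds = unconstrained).
#'
#' @param path CSV file; `default_grade_table()` loads the bundled bands.
#' @return A data.frame of class `grade_table` with 8 rows.
#' @export
read_grade_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("grade", "min_sm", "pm_low", "pm_high", "max_alpha")
  if (!all(need %in% names(df))) {
    fq_stop(sprintf("grade table must have columns %s",
                    paste(need, collapse = ", ")))
  }
  df <- df[order(df$grade), need]
  bounded <- !is.na(df$min_sm)
  if (any(diff(df$min_sm[bounded]) >= 0)) {
    fq_stop("min_sm must be strictly decreasing with grade")
  }
  if (any(diff(df$pm_low[!is.na(df$pm_low)]) >= 0) ||
      any(diff(df$pm_high[!is.na(df$pm_high)]) <= 0)) {
    fq_stop("P_m windows must be strictly nested outward")
  }
  if (any(diff(df$max_alpha[!is.na(df$max_alpha)]) <= 0)) {
    fq_stop("max_alpha must be strictly increasing with grade")
  }
  class(df) <- c("grade_table", "data.frame")
  df
}

#' @rdname read_grade_table
#' @export
default_grade_table <- function() {
  read_grade_table(system.file("extdata", "sqfm_grade_bands.csv",
                               package = "fingerqc", mustWork = TRUE))
}

#' Assign an SQFM quality grade
#'
#' Each of `S_m`, `P_m` and `alpha` receives the best (smallest) grade whose
#' band it satisfies; the final quality grade is the worst of the three.
#' Values exactly on a band edge satisfy that band (ties resolve to the
#' better grade).
#'
#' @param s_m Macro qualitative similarity (unitless).
#' @param p_m Macro quantitative similarity (percent).
#' @param alpha Leveling coefficient (unitless, >= 0).
#' @param table A [grade table][read_grade_table]; defaults to the bundled one.
#' @return Integer grade(s) in 1..8 (vectorized over the inputs).
#' @examples
#' assign_grade(0.96, 95.6, 0.02)   # 1
#' assign_grade(0.89, 89.5, 0.07)   # 3
#' assign_grade(0.87, 104.6, 0.25)  # 5
#' @export
assign_grade <- function(s_m, p_m, alpha, table = default_grade_table()) {
  n <- max(length(s_m), length(p_m), length(alpha))
  s_m <- rep_len(s_m, n); p_m <- rep_len(p_m, n); alpha <- rep_len(alpha, n)
  if (anyNA(s_m) || anyNA(p_m) || anyNA(alpha)) {
    fq_stop("grade inputs must be finite")
  }
  band <- function(value, ok) {
    # ok(value, band_row) -> logical; NA bound = always satisfied (catch-all)
    vapply(value, function(v) {
      hit <- which(vapply(seq_len(nrow(table)), function(g) ok(v, g), logical(1)))
      as.integer(hit[1])
    }, integer(1))
  }
  gs <- band(s_m, function(v, g) is.na(table$min_sm[g]) || v >= table$min_sm[g])
  gp <- band(p_m, function(v, g) is.na(table$pm_low[g]) ||
               (v >= table$pm_low[g] && v <= table$pm_high[g]))
  ga <- band(alpha, function(v, g) is.na(table$max_alpha[g]) ||
               v <= table$max_alpha[g])
  pmax(gs, gp, ga)
}

#' Evaluate every batch of a fingerprint matrix by SQFM
#'
#' Builds (or accepts) the reference fingerprint, evaluates each batch
#' against it and assigns grades.
#'
#' @param matrix A [fingerprint_matrix()].
#' @param reference Optional [reference fingerprint][build_reference_fingerprint];
#'   default is the all-batch mean of `matrix`.
#' @param grade_table Grade bands used by [assign_grade()].
#' @param zero_policy Passed to [ratio_similarity()].
#' @return A data.frame with one row per batch: `batch_id`, `wavelength`,
#'   `s_f`, `s_f_prime`, `s_m`, `c`, `p`, `p_m`, `alpha`, `grade`
#'   (full precision; see [format_sqfm()] for report rounding).
#' @export
sqfm_evaluate_matrix <- function(matrix, reference = NULL,
                                 grade_table = default_grade_table(),
                                 zero_policy = c("error", "drop")) {
  if (is.null(reference)) reference <- build_reference_fingerprint(matrix)
  rows <- lapply(seq_along(matrix$batch_ids), function(b) {
    r <- sqfm_evaluate(matrix$areas[b, ], reference,
                       batch_id = matrix$batch_ids[b],
                       wavelength = matrix$wavelength,
                       zero_policy = zero_policy)
    as.data.frame(unclass(r)[c("batch_id", "wavelength", "s_f", "s_f_prime",
                               "s_m", "c", "p", "p_m", "alpha")])
  })
  out <- do.call(rbind, rows)
  out$grade <- assign_grade(out$s_m, out$p_m, out$alpha, table = grade_table)
  out
}

#' Integrate per-wavelength SQFM results for one batch
#'
#' Multi-wavelength fingerprints are combined by the quadratic (root mean
#' square) mean over the m channels to avoid bias toward any one wavelength:
#' \deqn{S_m' = \sqrt{\tfrac1m \sum S_{m,i}^2}, \quad
#'       P_m' = \sqrt{\tfrac1m \sum P_{m,i}^2}, \quad
#'       \alpha' = \sqrt{\tfrac1m \sum \alpha_i^2}}
#' The integrated grade is assigned from the integrated triple.
#'
#' @param results Per-wavelength results for one batch: a list of
#'   `sqfm_result` objects or a data.frame with columns `batch_id`, `s_m`,
#'   `p_m`, `alpha` (one row per wavelength).
#' @param grade_table Grade bands used by [assign_grade()].
#' @return An object of class `integrated_sqfm` with fields `batch_id`,
#'   `s_m_prime`, `p_m_prime`, `alpha_prime`, `grade`, `channel_count`.
#' @export
integrate_channels <- function(results, grade_table = default_grade_table()) {
  if (inherits(results, "sqfm_result")) results <- list(results)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      as.data.frame(unclass(r)[c("batch_id", "s_m", "p_m", "alpha")])
    }))
  }
  if (!nrow(results)) fq_stop("no per-wavelength results supplied")
  ids <- unique(results$batch_id)
  if (length(ids) != 1L) {
    fq_stop(sprintf("mixed batch ids in integration: %s",
                    paste(ids, collapse = ", ")))
  }
  rms <- function(v) sqrt(mean(v^2))
  s_m_prime <- rms(results$s_m)
  p_m_prime <- rms(results$p_m)
  alpha_prime <- rms(results$alpha)
  structure(list(batch_id = ids,
                 s_m_prime = s_m_prime, p_m_prime = p_m_prime,
                 alpha_prime = alpha_prime,
                 grade = assign_grade(s_m_prime, p_m_prime, alpha_prime,
                                      table = grade_table),
                 channel_count = nrow(results)),
            class = "integrated_sqfm")
}

#' @export
print.integrated_sqfm <- function(x, ...) {
  cat(sprintf(
    "<integrated_sqfm> %s over %d channels: Sm'=%.2f Pm'=%.1f%% alpha'=%.2f grade=%d\n",
    x$batch_id, x$channel_count, x$s_m_prime, x$p_m_prime, x$alpha_prime,
    x$grade))
  invisible(x)
}

#' Round SQFM quantities to report precision
#'
#' Similarity-type values (`s_f`, `s_f_prime`, `s_m`, `s_m_prime`) are
#' reported to 2 decimals, percent-type values (`c`, `p`, `p_m`, `p_m_prime`)
#' to 1 decimal, and `alpha` to 2 decimals, using half-up rounding. Internal
#' computation is always full precision; rounding happens only at render time.
#'
#' @param x A data.frame of SQFM results (per-wavelength or integrated).
#' @return The data.frame with rounded numeric columns.
#' @export
format_sqfm <- function(x) {
  two <- intersect(c("s_f", "s_f_prime", "s_m", "s_m_prime",
                     "alpha", "alpha_prime"), names(x))
  one <- intersect(c("c", "p", "p_m", "p_m_prime"), names(x))
  for (col in two) x[[col]] <- round_half_up(x[[col]], 2)
  for (col in one) x[[col]] <- round_half_up(x[[col]], 1)
  x
}
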