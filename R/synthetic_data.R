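#' Specification of a synthetic multi-wavelength fingerprint study
#'
#' Describes a simulated cohort of injectable batches profiled at several
#' detection wavelengths, mirroring the structure of a real 23-batch,
#' 5-wavelength study: per-channel base peak profiles, batch-level content
#' scaling, per-peak multiplicative detector noise, planted
#' composition-shifted outlier batches (nucleoside near zero, phenolic acids
#' depressed, flavonoids elevated), and a linear link from 260 nm peak areas
#' to antioxidant activity (1/IC50).
#'
#' The base peak profiles, retention-time grids, peak classes and activity
#' coefficients are drawn once, deterministically from `seed`, when the spec
#' is constructed; the same spec therefore always generates byte-identical
#' data.
#'
#' @param n_batches Number of batches (default 23).
#' @param channels data.frame with columns `wavelength`, `n_peaks`; default
#'   the study shape 260/265/330/335/350 nm with 49/46/38/39/33 peaks.
#' @param content_scale_sd Relative SD of the per-batch global content scale
#'   (log-normal; default 0.08, matching an overall content spread of
#'   roughly 83-120%).
#' @param peak_noise_cv Relative SD of per-peak multiplicative noise
#'   (default 0.03).
#' @param outliers List of planted outliers, each
#'   `list(batch = <index>, folds = c(nucleoside=, phenolic=, flavonoid=,
#'   other=))`; `"default"` plants two composition-shifted batches at
#'   positions `n_batches - 2` and `n_batches`.
#' @param activity_intercept,activity_noise_sd Intercept and noise SD of the
#'   linear activity model `1/IC50 = b0 + sum(beta_j * area_j) + eps`.
#' @param absorbance_noise_sd Measurement noise on simulated DPPH
#'   absorbances (default 0, so the off-line pipeline recovers IC50 exactly).
#' @param trace_noise_sd Additive noise SD on the simulated 517 nm traces.
#' @param rt_jitter_sd Per-batch retention-time jitter (minutes) applied when
#'   exporting peak tables.
#' @param delay Post-column delay (minutes) used for the 517 nm traces;
#'   default from [coil_delay()].
#' @param seed Integer seed; fully determines all generated data.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_batches = 23,
                           channels = data.frame(
                             wavelength = c(260L, 265L, 330L, 335L, 350L),
                             n_peaks = c(49L, 46L, 38L, 39L, 33L)),
                           content_scale_sd = 0.08,
                           peak_noise_cv = 0.03,
                           outliers = "default",
                           activity_intercept = 0.05,
                           activity_noise_sd = 0.002,
                           absorbance_noise_sd = 0,
                           trace_noise_sd = 0.2,
                           rt_jitter_sd = 0.02,
                           delay = coil_delay(),
                           seed = 1) {
  if (n_batches < 1) fq_stop("need at least one batch")
  if (any(channels$n_peaks < 2)) fq_stop("each channel needs >= 2 peaks")
  if (content_scale_sd < 0 || peak_noise_cv < 0) {
    fq_stop("noise parameters must be non-negative")
  }

  if (identical(outliers, "default")) {
    outliers <- if (n_batches >= 3) list(
      list(batch = n_batches - 2L,
           folds = c(nucleoside = 0.02, phenolic = 0.40, flavonoid = 1.70,
                     other = 1.00)),
      list(batch = n_batches,
           folds = c(nucleoside = 0.01, phenolic = 0.35, flavonoid = 1.80,
                     other = 1.00))
    ) else list()
  }
  for (o in outliers) {
    if (o$batch < 1 || o$batch > n_batches) fq_stop("outlier batch out of range")
    if (any(o$folds < 0)) fq_stop("outlier fold-changes must be >= 0")
  }

  # marker-like positions on the canonical 49-peak 260 nm grid, rescaled to
  # each channel's peak count
  place <- function(pos, n) unique(pmin(n, pmax(1L, as.integer(round(pos / 49 * n)))))
  spec_channels <- with_seed(seed, lapply(seq_len(nrow(channels)), function(i) {
    n <- channels$n_peaks[i]
    classes <- rep("other", n)
    classes[place(c(4, 10), n)] <- "nucleoside"
    classes[place(c(24, 26, 34), n)] <- "phenolic"
    classes[place(c(38, 40), n)] <- "flavonoid"
    # retention grid: gaps >= 0.5 min so default matching is unambiguous
    gaps <- 0.5 + stats::rexp(n, rate = 1 / 0.6)
    rt <- 2 + cumsum(gaps)
    # minor peaks are random; marker peaks carry fixed base areas
    # proportional to typical mean contents (nucleosides ~3-4, phenolic
    # acids ~8-69, flavonoids 8-97 mg/L at ~25 area units per mg/L), so the
    # big phenolic/flavonoid peaks dominate the chromatogram as in real
    # preparations
    base <- stats::rlnorm(n, meanlog = log(40), sdlog = 0.6)
    base[classes == "nucleoside"] <-
      25 * rep_len(c(3.0, 4.3), sum(classes == "nucleoside"))
    base[classes == "phenolic"] <-
      25 * rep_len(c(7.5, 16.8, 68.9), sum(classes == "phenolic"))
    base[classes == "flavonoid"] <-
      25 * rep_len(c(97.1, 7.9), sum(classes == "flavonoid"))
    list(wavelength = channels$wavelength[i], n_peaks = n,
         classes = classes, retention_times = rt, base = base)
  }))

  # activity coefficients on channel 1: phenolics strongest, flavonoids
  # weaker, two unrelated positive peaks, two negative peaks, nucleosides 0
  ch1 <- spec_channels[[1]]
  beta <- numeric(ch1$n_peaks)
  other_idx <- which(ch1$classes == "other")
  pos_other <- other_idx[place(c(16, 17), length(other_idx))]
  neg_other <- setdiff(other_idx[place(c(8, 44), length(other_idx))], pos_other)
  share <- function(idx, total) if (length(idx)) total / length(idx) else numeric(0)
  total_link <- 0.18  # sum(beta * base) -> mean 1/IC50 ~ intercept + 0.18
  beta[ch1$classes == "phenolic"] <-
    share(which(ch1$classes == "phenolic"), 0.62 * total_link) /
    ch1$base[ch1$classes == "phenolic"]
  beta[ch1$classes == "flavonoid"] <-
    share(which(ch1$classes == "flavonoid"), 0.28 * total_link) /
    ch1$base[ch1$classes == "flavonoid"]
  beta[pos_other] <- share(pos_other, 0.13 * total_link) / ch1$base[pos_other]
  beta[neg_other] <- -share(neg_other, 0.03 * total_link) / ch1$base[neg_other]

  structure(list(n_batches = as.integer(n_batches),
                 channels = spec_channels,
                 content_scale_sd = content_scale_sd,
                 peak_noise_cv = peak_noise_cv,
                 outliers = outliers,
                 activity_beta = beta,
                 activity_intercept = activity_intercept,
                 activity_noise_sd = activity_noise_sd,
                 absorbance_noise_sd = absorbance_noise_sd,
                 trace_noise_sd = trace_noise_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 delay = delay,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d batches x %d channels (%s peaks), %d outlier(s), seed %d\n",
    x$n_batches, length(x$channels),
    paste(vapply(x$channels, function(c) c$n_peaks, integer(1)),
          collapse = "/"),
    length(x$outliers), x$seed))
  invisible(x)
}

fold_matrix <- function(spec, channel) {
  n <- channel$n_peaks
  folds <- matrix(1, spec$n_batches, n)
  for (o in spec$outliers) {
    folds[o$batch, ] <- o$folds[channel$classes]
  }
  folds
}

#' Generate multi-wavelength fingerprint matrices with known ground truth
#'
#' Batch b, peak j area = `base_j * scale_b * fold_bj * exp(noise)`: a shared
#' log-normal batch content scale, class-wise outlier fold-changes, and
#' log-normal per-peak noise with the spec's CV. All areas are strictly
#' positive and the output is fully determined by the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `matrices` (named list of [fingerprint_matrix()], one per
#'   wavelength) and `truth` (`scales`, per-channel `folds`, `classes`,
#'   `outlier_batches`, `seed`).
#' @export
generate_fingerprints <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) fq_stop("'spec' must be a synthetic_spec")
  if (any(vapply(spec$channels, function(c) any(c$base <= 0), logical(1)))) {
    fq_stop("spec error: base profile must be strictly positive")
  }
  B <- spec$n_batches
  batch_ids <- paste0("S", seq_len(B))
  sdlog_scale <- sqrt(log(1 + spec$content_scale_sd^2))
  sdlog_noise <- sqrt(log(1 + spec$peak_noise_cv^2))
  with_seed(spec$seed + 1L, {
    scales <- exp(stats::rnorm(B, 0, sdlog_scale))
    matrices <- list()
    folds_all <- list()
    for (ch in spec$channels) {
      folds <- fold_matrix(spec, ch)
      noise <- matrix(exp(stats::rnorm(B * ch$n_peaks, 0, sdlog_noise)),
                      B, ch$n_peaks)
      areas <- outer(scales, ch$base) * folds * noise
      matrices[[as.character(ch$wavelength)]] <- fingerprint_matrix(
        wavelength = ch$wavelength, batch_ids = batch_ids,
        peak_ids = sprintf("P%02d", seq_len(ch$n_peaks)),
        areas = areas, retention_times = ch$retention_times)
      folds_all[[as.character(ch$wavelength)]] <- folds
    }
    list(matrices = matrices,
         truth = list(scales = stats::setNames(scales, batch_ids),
                      folds = folds_all,
                      classes = lapply(spec$channels, `[[`, "classes"),
                      outlier_batches = as.integer(
                        vapply(spec$outliers, function(o) o$batch, numeric(1))),
                      seed = spec$seed))
  })
}

#' Generate antioxidant activity data tied to the fingerprints
#'
#' Builds, per batch: the true `1/IC50` from the linear activity model on the
#' 260 nm areas; an off-line DPPH absorbance series (concentrations 1-6
#' mg/mL, control absorbance 0.8) constructed so the off-line pipeline
#' ([inhibition()] + [estimate_ic50()]) recovers the true IC50; and an
#' on-line 517 nm trace with inverted Gaussian peaks (depth proportional to
#' `beta_j * area_bj`, positive-coefficient peaks only) shifted by the
#' post-column delay.
#'
#' @param spec A [synthetic_spec()].
#' @param fingerprints Output of [generate_fingerprints()] for `spec`.
#' @return A list: `inv_ic50`, `ic50` (named per batch), `absorbance`
#'   (long data.frame `batch_id, concentration, a_control, a_sample`),
#'   `traces` (`time`, `intensity` B x T matrix), and `truth` (`beta`,
#'   `depths`, `centers`, `delay`).
#' @export
generate_activity <- function(spec, fingerprints) {
  X <- fingerprints$matrices[[1]]$areas
  beta <- spec$activity_beta
  if (ncol(X) != length(beta)) {
    fq_stop("activity_beta length must match the first channel's peaks")
  }
  B <- nrow(X)
  batch_ids <- rownames(X)
  with_seed(spec$seed + 2L, {
    inv_ic50 <- drop(spec$activity_intercept + X %*% beta) +
      stats::rnorm(B, 0, spec$activity_noise_sd)
    if (any(inv_ic50 <= 0)) {
      fq_stop("spec error: non-positive 1/IC50 implies no dose response")
    }
    ic50 <- 1 / inv_ic50

    conc <- 1:6
    a_control <- 0.8
    absorbance <- do.call(rbind, lapply(seq_len(B), function(b) {
      inh <- 50 / ic50[b] * conc
      a_sample <- a_control * (1 - inh / 100) +
        stats::rnorm(length(conc), 0, spec$absorbance_noise_sd)
      data.frame(batch_id = batch_ids[b], concentration = conc,
                 a_control = a_control, a_sample = a_sample,
                 stringsAsFactors = FALSE)
    }))

    rt <- fingerprints$matrices[[1]]$retention_times
    time <- seq(0, max(rt) + 2, by = 0.02)
    contrib <- sweep(X, 2, pmax(beta, 0), "*")   # beta <= 0 -> no peak
    depths <- 40 * contrib / max(contrib)
    centers <- rt + spec$delay
    sigma <- 0.05
    intensity <- matrix(0, B, length(time), dimnames = list(batch_ids, NULL))
    for (b in seq_len(B)) {
      sig <- numeric(length(time))
      for (j in which(depths[b, ] > 0)) {
        sig <- sig - depths[b, j] * exp(-(time - centers[j])^2 / (2 * sigma^2))
      }
      intensity[b, ] <- sig + stats::rnorm(length(time), 0, spec$trace_noise_sd)
    }

    list(inv_ic50 = stats::setNames(inv_ic50, batch_ids),
         ic50 = stats::setNames(ic50, batch_ids),
         absorbance = absorbance,
         traces = list(time = time, intensity = intensity),
         truth = list(beta = beta, depths = depths, centers = centers,
                      delay = spec$delay))
  })
}

#' Export generated fingerprints as per-batch peak tables
#'
#' Converts the aligned matrices back into per-batch [peak_table()] objects,
#' applying a small per-batch retention-time jitter (the spec's
#' `rt_jitter_sd`) so that downstream [match_common_peaks()] is exercised
#' realistically.
#'
#' @param spec A [synthetic_spec()].
#' @param fingerprints Output of [generate_fingerprints()].
#' @return List of `peak_table` objects (batches x channels).
#' @export
as_peak_tables <- function(spec, fingerprints) {
  with_seed(spec$seed + 3L, {
    out <- list()
    for (fm in fingerprints$matrices) {
      for (b in seq_along(fm$batch_ids)) {
        rt <- fm$retention_times +
          stats::rnorm(length(fm$retention_times), 0, spec$rt_jitter_sd)
        out[[length(out) + 1L]] <- peak_table(
          batch_id = fm$batch_ids[b], wavelength = fm$wavelength,
          retention_time = rt, area = fm$areas[b, ],
          peak_id = fm$peak_ids)
      }
    }
    out
  })
}
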