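test_that("the default spec reproduces the study shape", {
  spec <- synthetic_spec(seed = 1)
  expect_equal(spec$n_batches, 23L)
  expect_equal(vapply(spec$channels, function(c) c$wavelength, integer(1)),
               c(260L, 265L, 330L, 335L, 350L))
  expect_equal(vapply(spec$channels, function(c) c$n_peaks, integer(1)),
               c(49L, 46L, 38L, 39L, 33L))
  expect_length(spec$outliers, 2)

  fp <- generate_fingerprints(spec)
  expect_named(fp$matrices, c("260", "265", "330", "335", "350"))
  expect_equal(fp$truth$outlier_batches, c(21L, 23L))
  expect_true(all(vapply(fp$matrices, function(m) all(m$areas > 0),
                         logical(1))))
})

test_that("the seed fully determines the output", {
  spec <- synthetic_spec(seed = 17)
  a <- generate_fingerprints(spec)
  b <- generate_fingerprints(spec)
  expect_identical(a, b)
  expect_identical(generate_activity(spec, a), generate_activity(spec, a))

  other <- generate_fingerprints(synthetic_spec(seed = 18))
  expect_false(identical(a$matrices[["260"]]$areas,
                         other$matrices[["260"]]$areas))
})

test_that("a noise-free, outlier-free world collapses to the base profile", {
  spec <- synthetic_spec(n_batches = 4, content_scale_sd = 0,
                         peak_noise_cv = 0, outliers = list(), seed = 3)
  fp <- generate_fingerprints(spec)
  X <- fp$matrices[[1]]$areas
  expect_true(all(apply(X, 2, function(col) max(abs(col - col[1]))) == 0))

  res <- sqfm_evaluate_matrix(fp$matrices[[1]])
  expect_equal(res$s_m, rep(1, 4))
  expect_equal(res$p_m, rep(100, 4))
  expect_equal(res$alpha, rep(0, 4))
  expect_equal(res$grade, rep(1L, 4))
})

test_that("a uniform batch fold shows up in P_m but not S_m or alpha", {
  spec <- synthetic_spec(n_batches = 5, content_scale_sd = 0,
                         peak_noise_cv = 0, seed = 4,
                         outliers = list(list(batch = 2,
                                              folds = c(nucleoside = 0.8,
                                                        phenolic = 0.8,
                                                        flavonoid = 0.8,
                                                        other = 0.8))))
  fp <- generate_fingerprints(spec)
  # evaluate against the unscaled base (batch 1), isolating the fold
  res <- sqfm_evaluate(fp$matrices[[1]]$areas[2, ],
                       fp$matrices[[1]]$areas[1, ])
  expect_equal(res$s_m, 1)
  expect_equal(res$p_m, 80)
  expect_equal(res$alpha, 0, tolerance = 1e-12)
})

test_that("composition-shifted outliers disrupt alpha and the grade", {
  spec <- synthetic_spec(
    seed = 1,
    outliers = list(list(batch = 12,
                         folds = c(nucleoside = 1, phenolic = 0.3,
                                   flavonoid = 1.6, other = 1))))
  fp <- generate_fingerprints(spec)
  res <- sqfm_evaluate_matrix(fp$matrices[[1]])
  expect_gt(res$alpha[12], max(res$alpha[-12]))
  expect_gte(res$grade[12], 4L)
})

test_that("generated absorbances round-trip through the off-line pipeline", {
  spec <- synthetic_spec(seed = 10, activity_noise_sd = 0,
                         absorbance_noise_sd = 0)
  fp <- generate_fingerprints(spec)
  act <- generate_activity(spec, fp)
  for (b in c("S1", "S12", "S21")) {
    d <- act$absorbance[act$absorbance$batch_id == b, ]
    r <- estimate_ic50(d$concentration,
                       inhibition(d$a_control, d$a_sample), b)
    expect_equal(r$ic50, unname(act$ic50[b]), tolerance = 1e-8)
    expect_lt(abs(1 / r$ic50 - act$inv_ic50[[b]]) / act$inv_ic50[[b]], 0.01)
  }
})

test_that("only positive-coefficient components leave activity peaks", {
  spec <- synthetic_spec(n_batches = 4, seed = 12, trace_noise_sd = 0)
  fp <- generate_fingerprints(spec)
  act <- generate_activity(spec, fp)
  beta <- act$truth$beta
  expect_true(all(act$truth$depths[, beta <= 0] == 0))
  # trace is exactly flat in a window around each non-active center
  tr <- act$traces
  for (j in which(beta <= 0)) {
    ctr <- act$truth$centers[j]
    near_active <- any(abs(act$truth$centers[beta > 0] - ctr) < 0.5)
    if (!near_active) {
      win <- abs(tr$time - ctr) < 0.1
      expect_equal(max(abs(tr$intensity["S1", win])), 0)
    }
  }
})

test_that("trace detection and association recover the generator truth", {
  spec <- synthetic_spec(n_batches = 3, seed = 14, trace_noise_sd = 0.02)
  fp <- generate_fingerprints(spec)
  act <- generate_activity(spec, fp)
  tr <- act$traces
  dt <- diff(tr$time)[1]
  min_depth <- 1
  pk <- detect_activity_peaks(tr$time, tr$intensity["S2", ],
                              min_depth = min_depth)
  truth <- which(act$truth$depths["S2", ] >= 2 * min_depth)
  # every sufficiently deep planted peak is found within one sampling step
  found <- vapply(act$truth$centers[truth], function(ctr) {
    any(abs(pk$apex_time - ctr) <= dt)
  }, logical(1))
  expect_true(all(found))

  # association with tolerance >= 2 steps recovers the parent map
  af <- associate_activity(fp$matrices[[1]]$retention_times, pk,
                           delay = spec$delay, tolerance = 2 * dt)
  expect_true(all(!is.na(af$associations[truth])))
  expect_true(all(is.na(af$associations[act$truth$beta <= 0])))
})

test_that("peak-table export jitters retention times but keeps areas", {
  spec <- synthetic_spec(n_batches = 3, seed = 15)
  fp <- generate_fingerprints(spec)
  tabs <- as_peak_tables(spec, fp)
  expect_length(tabs, 3 * 5)
  fm <- match_common_peaks(tabs[1:3], rt_tolerance = 0.2)
  expect_equal(length(fm$peak_ids), spec$channels[[1]]$n_peaks)
  expect_equal(unname(fm$areas), unname(fp$matrices[[1]]$areas))
})

test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_spec(n_batches = 0), "at least one batch")
  expect_error(synthetic_spec(outliers = list(list(batch = 99,
                                                   folds = c(other = 1)))),
               "out of range")
  expect_error(synthetic_spec(content_scale_sd = -1), "non-negative")
})
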