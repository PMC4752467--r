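test_that("PLS recovers an exact single-predictor relation", {
  x <- matrix(seq(1, 5), ncol = 1)
  m <- fit_pls(x, 2 * drop(x), n_components = 1, cv_folds = 2, seed = 1)
  expect_equal(unname(m$coefficients["x1"]), 2)
  expect_equal(unname(m$coefficients["(Intercept)"]), 0, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_equal(m$rmsee, 0, tolerance = 1e-10)
})

test_that("full-component PLS equals ordinary least squares", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(10, 0, 0.3)
  m <- fit_pls(X, y, n_components = 4, cv_folds = 5, seed = 1)
  b <- ols_oracle(X, y)
  pred_ols <- b[1] + X %*% b[-1]
  expect_equal(unname(predict(m, X)), drop(pred_ols), tolerance = 1e-8)
  expect_equal(unname(m$coefficients), b, tolerance = 1e-8)
})

test_that("OPLS with zero orthogonal components reduces to 1-component PLS", {
  set.seed(32)
  X <- matrix(rlnorm(60), 12, 5)
  y <- drop(X %*% runif(5)) + rnorm(12, 0, 0.2)
  p1 <- fit_pls(X, y, n_components = 1, cv_folds = 4, seed = 2)
  o0 <- fit_opls(X, y, n_orthogonal = 0, cv_folds = 4, seed = 2)
  expect_equal(predict(o0, X), predict(p1, X), tolerance = 1e-10)
  expect_equal(o0$coefficients, p1$coefficients, tolerance = 1e-10)
})

test_that("removing y-orthogonal variation improves the predictive fit", {
  set.seed(33)
  n <- 20
  t_pred <- rnorm(n)
  t_orth <- rnorm(n)             # structured variation unrelated to y
  X <- cbind(outer(t_pred, c(1, 0.8, 0.6)) + outer(t_orth, c(0.5, -1, 1)),
             t_orth + rnorm(n, 0, 0.05))
  y <- t_pred + rnorm(n, 0, 0.05)
  r2_pls1 <- fit_pls(X, y, n_components = 1, cv_folds = 5, seed = 3)$r2
  r2_opls <- fit_opls(X, y, n_orthogonal = 1, cv_folds = 5, seed = 3)$r2
  expect_gte(r2_opls, r2_pls1)
})

test_that("cross-validated Q2 never beats training R2 on seeded fits", {
  for (sd in 1:5) {
    set.seed(100 + sd)
    X <- matrix(rlnorm(23 * 8, log(50), 0.5), 23, 8)
    y <- drop(X %*% runif(8, 0, 0.01)) + rnorm(23, 0, 0.05)
    mp <- fit_pls(X, y, n_components = 2, cv_folds = 7, seed = sd)
    mo <- fit_opls(X, y, n_orthogonal = 1, cv_folds = 7, seed = sd)
    expect_lte(mp$q2, mp$r2)
    expect_lte(mo$q2, mo$r2)
  }
})

test_that("jack-knife intervals match a brute-force leave-one-out oracle", {
  set.seed(34)
  X <- matrix(rnorm(36), 12, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(12, 0, 0.4)
  fit_fun <- function(X, y) fit_pls(X, y, n_components = 3, cv_folds = 4,
                                    seed = 1)
  ci <- jackknife_ci(fit_fun, X, y, level = 0.95)

  full <- fit_fun(X, y)$coefficients
  B <- nrow(X)
  reps <- t(vapply(seq_len(B), function(i) {
    fit_fun(X[-i, , drop = FALSE], y[-i])$coefficients
  }, numeric(length(full))))
  se <- sqrt((B - 1) / B * colSums(sweep(reps, 2, colMeans(reps))^2))
  tq <- qt(0.975, B - 1)
  expect_equal(ci$estimate, unname(full))
  expect_equal(ci$se, unname(se), tolerance = 1e-10)
  expect_equal(ci$lower, unname(full - tq * se), tolerance = 1e-10)
  expect_equal(ci$upper, unname(full + tq * se), tolerance = 1e-10)
})

test_that("jack-knife intervals collapse on noise-free linear data", {
  set.seed(35)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, 2, 3))
  ci <- jackknife_ci(function(X, y) fit_pls(X, y, 3, cv_folds = 4, seed = 1),
                     X, y)
  expect_true(all(ci$upper - ci$lower < 1e-6))
  expect_equal(ci$estimate[-1], c(1, 2, 3), tolerance = 1e-8)
})

test_that("jack-knife intervals cover true zero coefficients", {
  # reduced-rep coverage check: nominal 95%, wide binomial slack at 40 reps
  cover <- 0; total <- 0
  for (r in 1:40) {
    set.seed(1000 + r)
    X <- matrix(rnorm(20 * 4), 20, 4)
    y <- X[, 1] + rnorm(20, 0, 0.5)
    ci <- jackknife_ci(function(X, y) fit_pls(X, y, 2, cv_folds = 5,
                                              seed = 1), X, y)
    zero <- ci[3:5, ]  # x2..x4 have true coefficient 0
    cover <- cover + sum(zero$lower <= 0 & 0 <= zero$upper)
    total <- total + nrow(zero)
  }
  expect_gte(cover / total, 0.88)
})

test_that("PCA screen decomposes variance and flags score outliers", {
  # collinear points: one component carries all variance
  t <- seq(-2, 2, length.out = 6)
  line <- cbind(t, 2 * t, -t) + 5
  p <- pca_screen(line, k = 2)
  expect_equal(p$explained_variance_pct[1], 100)

  # two points: the principal direction is (1,1)/sqrt(2)
  p2 <- pca_screen(rbind(c(0, 0), c(2, 2), c(1, 1)), k = 1)
  expect_equal(abs(p2$loadings[, 1]), rep(1 / sqrt(2), 2))

  # scores * t(loadings) reconstructs the centered data at full rank
  set.seed(36)
  M <- matrix(rnorm(30), 6, 5)
  pf <- pca_screen(M, k = 5)
  expect_equal(pf$scores %*% t(pf$loadings),
               sweep(M, 2, colMeans(M)), ignore_attr = TRUE)

  expect_error(pca_screen(M, k = 6), "at most")
})

test_that("planted composition outliers are flagged at the 95% level", {
  spec <- synthetic_spec(seed = 5)
  fp <- generate_fingerprints(spec)
  p <- pca_screen(fp$matrices[[1]]$areas, k = 2, confidence = 0.95)
  expect_equal(which(p$outlier_flags), c(S21 = 21L, S23 = 23L))
})

test_that("coefficients recover known generator betas", {
  # dedicated recovery scenario: 20 batches x 10 peaks, independent areas
  set.seed(37)
  X <- matrix(rlnorm(20 * 10, log(100), 0.4), 20, 10)
  beta <- c(2, -1.5, 1, 0.8, -0.6, 0.5, 0, 0, 0, 0) / 100
  y <- drop(X %*% beta) + rnorm(20, 0, 0.05)
  m <- fit_pls(X, y, n_components = 6, cv_folds = 5, seed = 1)
  b <- m$coefficients[-1]
  expect_gt(cor(b, beta), 0.95)

  # on the fingerprint generator: signs recovered for coefficients that are
  # clearly resolved (|estimate| > 2 * jack-knife SE)
  spec <- synthetic_spec(seed = 6)
  fp <- generate_fingerprints(spec)
  act <- generate_activity(spec, fp)
  keep <- setdiff(seq_len(23), c(21, 23))
  Xf <- fp$matrices[[1]]$areas[keep, ]
  yf <- act$inv_ic50[keep]
  fit_fun <- function(X, y) suppressWarnings(
    fit_pls(X, y, n_components = 2, cv_folds = 7, seed = 1))
  ci <- jackknife_ci(fit_fun, Xf, yf)
  est <- ci$estimate[-1]; se <- ci$se[-1]
  resolved <- which(abs(est) > 2 * se & act$truth$beta != 0)
  expect_gt(length(resolved), 0)
  expect_true(all(sign(est[resolved]) == sign(act$truth$beta[resolved])))
})

test_that("external validation reports RMSEP and per-sample errors", {
  set.seed(38)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, 2, 3))
  m <- fit_pls(X, y, n_components = 3, cv_folds = 5, seed = 1)
  ev <- evaluate_on_test(m, X, y)
  expect_equal(ev$rmsep, 0, tolerance = 1e-8)

  # seeded 16-train / 5-test split on generator data
  spec <- synthetic_spec(seed = 9)
  fp <- generate_fingerprints(spec)
  act <- generate_activity(spec, fp)
  non <- setdiff(seq_len(23), c(21, 23))
  test_idx <- local({set.seed(9); sample(non, 5)})
  train_idx <- setdiff(non, test_idx)
  X <- fp$matrices[[1]]$areas
  m2 <- suppressWarnings(fit_pls(X[train_idx, ], act$inv_ic50[train_idx],
                                 n_components = 2, cv_folds = 7, seed = 9))
  ev2 <- evaluate_on_test(m2, X[test_idx, ], act$inv_ic50[test_idx])
  expect_lt(ev2$rmsep, 3 * spec$activity_noise_sd)
  expect_length(ev2$relative_errors, 5)

  expect_error(evaluate_on_test(m, X, y[-1]), "do not match")
})

test_that("training without planted outliers usually predicts better", {
  wins <- 0
  for (sd in 1:10) {
    spec <- synthetic_spec(seed = sd)
    fp <- generate_fingerprints(spec)
    act <- generate_activity(spec, fp)
    X <- fp$matrices[[1]]$areas; y <- act$inv_ic50
    non <- setdiff(seq_len(23), c(21, 23))
    set.seed(sd)
    test_idx <- sample(non, 5)
    train_idx <- setdiff(non, test_idx)
    clean <- suppressWarnings(fit_pls(X[train_idx, ], y[train_idx], 2,
                                      cv_folds = 7, seed = sd))
    dirty <- suppressWarnings(fit_pls(X[c(train_idx, 21, 23), ],
                                      y[c(train_idx, 21, 23)], 2,
                                      cv_folds = 7, seed = sd))
    r_clean <- evaluate_on_test(clean, X[test_idx, ], y[test_idx])$rmsep
    r_dirty <- evaluate_on_test(dirty, X[test_idx, ], y[test_idx])$rmsep
    wins <- wins + (r_clean < r_dirty)
  }
  expect_gte(wins, 8)
})

test_that("degenerate modelling inputs are rejected or handled", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10), 1), "constant")
  expect_error(fit_pls(X, rnorm(10), 10), "n_components")
  Xz <- cbind(X, 5)  # constant column dropped with a warning
  expect_warning(m <- fit_pls(Xz, drop(X %*% c(1, 2)) + rnorm(10, 0, 0.1),
                              2, cv_folds = 5, seed = 1), "zero-variance")
  expect_length(m$coefficients, 3)  # intercept + 2 informative columns
})
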