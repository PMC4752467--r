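# Latent-variable regression of activity on fingerprint peak areas, plus the
# PCA screen used to spot composition outliers before modelling.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

scale_columns <- function(X, mode = c("uv", "center", "pareto")) {
  mode <- match.arg(mode)
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  scl <- switch(mode, uv = sds, center = rep(1, ncol(X)), pareto = sqrt(sds))
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# NIPALS PLS1 on already centered/scaled data. Stops early if X or the
# residual response is exhausted (rank deficiency).
pls_core <- function(X, y, a, tol = 1e-12) {
  n <- ncol(X)
  W <- P <- matrix(0, n, 0)
  q <- numeric(0)
  for (k in seq_len(a)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt < tol) break
    p <- drop(crossprod(X, t)) / tt
    qk <- sum(y * t) / tt
    X <- X - tcrossprod(t, p)
    y <- y - qk * t
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qk)
  }
  if (!ncol(W)) fq_compute_stop("PLS failed: no usable component")
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, q = q, b = b, a_used = ncol(W))
}

# Orthogonal signal correction: strips up to n_orth components of X-variation
# orthogonal to y, returns the filtered X and the filter vectors.
opls_filter <- function(X, y, n_orth, tol = 1e-12) {
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  W_o <- P_o <- matrix(0, ncol(X), 0)
  for (j in seq_len(n_orth)) {
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < tol) break
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
  }
  list(X = X, W_o = W_o, P_o = P_o)
}

# Compose the orthogonal filter into a single coefficient vector:
# b_total = (I - w_o1 p_o1') ... (I - w_ok p_ok') b
compose_opls_coef <- function(b, W_o, P_o) {
  for (j in rev(seq_len(ncol(W_o)))) {
    b <- b - W_o[, j] * sum(P_o[, j] * b)
  }
  b
}

latent_fit_scaled <- function(Xs, ys, kind, n_components, n_orthogonal) {
  if (kind == "pls") {
    core <- pls_core(Xs, ys, n_components)
    list(b_scaled = core$b, a_used = core$a_used, n_orth_used = 0L,
         filter = NULL)
  } else {
    flt <- opls_filter(Xs, ys, n_orthogonal)
    core <- pls_core(flt$X, ys, 1L)
    list(b_scaled = compose_opls_coef(core$b, flt$W_o, flt$P_o),
         a_used = 1L, n_orth_used = ncol(flt$W_o),
         filter = flt[c("W_o", "P_o")])
  }
}

latent_model_build <- function(X, y, kind, n_components, n_orthogonal,
                               cv_folds, seed, scale) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  B <- nrow(X)
  if (length(y) != B) fq_stop("'y' must have one entry per row of X")
  if (stats::sd(y) == 0) fq_stop("degenerate response: y is constant")
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  sc <- scale_columns(X, scale)
  y_center <- mean(y); y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale
  fit <- latent_fit_scaled(sc$X, ys, kind, n_components, n_orthogonal)

  b_raw <- y_scale * fit$b_scaled / sc$scale
  intercept <- y_center - sum(b_raw * sc$center)
  fitted <- drop(intercept + X %*% b_raw)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  a_tot <- fit$a_used + fit$n_orth_used
  r2 <- 1 - sum(res^2) / ss_tot
  rmsee <- sqrt(sum(res^2) / max(1, B - a_tot - 1))

  # seeded deterministic k-fold CV, each fold refit from scratch
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), B)))
  press <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    m <- tryCatch(
      suppressWarnings(latent_model_build_once(
        X[tr, , drop = FALSE], y[tr], kind, n_components, n_orthogonal,
        scale)),
      error = function(e) NULL)
    pred <- if (is.null(m)) mean(y[tr]) else
      drop(m$intercept + X[!tr, , drop = FALSE] %*% m$b_raw)
    press <- press + sum((y[!tr] - pred)^2)
  }
  q2 <- 1 - press / ss_tot
  rmsecv <- sqrt(press / B)

  structure(list(kind = kind, n_predictive = fit$a_used,
                 n_orthogonal = fit$n_orth_used,
                 x_center = sc$center, x_scale = sc$scale,
                 y_center = y_center, y_scale = y_scale,
                 scale_mode = scale,
                 coefficients = c(`(Intercept)` = intercept,
                                  stats::setNames(b_raw, colnames(X))),
                 columns = colnames(X),
                 r2 = r2, q2 = q2, rmsee = rmsee, rmsecv = rmsecv,
                 rmsep = NA_real_, jackknife_ci = NULL,
                 cv_folds = cv_folds, seed = seed, cv_partition = folds),
            class = "latent_model")
}

# lean refit used inside CV / jackknife loops
latent_model_build_once <- function(X, y, kind, n_components, n_orthogonal,
                                    scale) {
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  sc <- scale_columns(X, scale)
  y_center <- mean(y); y_scale <- stats::sd(y)
  fit <- latent_fit_scaled(sc$X, (y - y_center) / y_scale, kind,
                           n_components, n_orthogonal)
  b_raw_kept <- y_scale * fit$b_scaled / sc$scale
  b_raw <- stats::setNames(numeric(length(keep)), names(keep))
  b_raw[keep] <- b_raw_kept
  list(intercept = y_center - sum(b_raw_kept * sc$center), b_raw = b_raw)
}

#' Fit a PLS regression of activity on fingerprint peak areas
#'
#' NIPALS partial least squares (single response) on centered and, by
#' default, unit-variance scaled data. Coefficients are back-transformed to
#' the raw-area scale, so predictions take the plain linear form
#' `y = b0 + sum(b_i * area_i)`. Training fit is summarized by `r2` and
#' `rmsee`; predictive ability by `q2` and `rmsecv` from seeded k-fold
#' cross-validation (each fold refit from scratch, scaling recomputed on the
#' training part).
#'
#' @param X B x n matrix of peak areas (batches x peaks).
#' @param y Response vector, e.g. 1/IC50 per batch.
#' @param n_components Number of predictive latent components (>= 1,
#'   < B); fewer are used if X runs out of rank.
#' @param cv_folds Number of cross-validation folds (default 7).
#' @param seed Integer seed fixing the CV partition.
#' @param scale Column scaling: `"uv"` (unit variance, default), `"center"`
#'   or `"pareto"`.
#' @return An object of class `latent_model`; see [predict.latent_model()],
#'   [evaluate_on_test()], [jackknife_ci()].
#' @export
fit_pls <- function(X, y, n_components = 2, cv_folds = 7, seed = 1,
                    scale = c("uv", "center", "pareto")) {
  scale <- match.arg(scale)
  if (n_components < 1 || nrow(as.matrix(X)) <= n_components) {
    fq_stop("need 1 <= n_components < number of batches")
  }
  latent_model_build(X, y, "pls", n_components, 0L, cv_folds, seed, scale)
}

#' Fit an OPLS regression (orthogonal filtering + one predictive component)
#'
#' Removes up to `n_orthogonal` components of X-variation orthogonal to the
#' response (orthogonal signal correction), then fits a single predictive
#' PLS component on the filtered data. With `n_orthogonal = 0` the
#' predictions coincide with one-component PLS. The orthogonal filter is
#' folded into the returned raw-scale coefficient vector, so prediction is
#' again a plain linear form.
#'
#' @inheritParams fit_pls
#' @param n_orthogonal Number of orthogonal components to remove (>= 0,
#'   `B > n_orthogonal + 1`).
#' @return A `latent_model` with `kind = "opls"`.
#' @export
fit_opls <- function(X, y, n_orthogonal = 1, cv_folds = 7, seed = 1,
                     scale = c("uv", "center", "pareto")) {
  scale <- match.arg(scale)
  if (n_orthogonal < 0 || nrow(as.matrix(X)) <= n_orthogonal + 1) {
    fq_stop("need 0 <= n_orthogonal < number of batches - 1")
  }
  latent_model_build(X, y, "opls", 1L, as.integer(n_orthogonal), cv_folds,
                     seed, scale)
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf(
    "<latent_model> %s: %d predictive + %d orthogonal; R2=%.4f Q2=%.4f RMSEE=%.4g RMSECV=%.4g\n",
    toupper(x$kind), x$n_predictive, x$n_orthogonal, x$r2, x$q2, x$rmsee,
    x$rmsecv))
  invisible(x)
}

#' Predict from a fitted latent model
#'
#' @param object A `latent_model`.
#' @param newdata Matrix of peak areas with the model's columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.latent_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(object$columns) && is.null(colnames(newdata))) {
    colnames(newdata) <- object$columns
  }
  if (!all(object$columns %in% colnames(newdata))) {
    fq_stop("newdata lacks columns used by the model")
  }
  b <- object$coefficients
  drop(b[1] + newdata[, object$columns, drop = FALSE] %*% b[-1])
}

#' External validation of a latent model
#'
#' @param model A fitted `latent_model`.
#' @param X_test,y_test Test-set areas and responses, disjoint from training.
#' @return A list: `rmsep` (root mean square error of prediction),
#'   `relative_errors` (percent, per sample) and `predictions`.
#' @export
evaluate_on_test <- function(model, X_test, y_test) {
  X_test <- as.matrix(X_test)
  if (nrow(X_test) != length(y_test)) {
    fq_stop("X_test and y_test dimensions do not match")
  }
  pred <- predict(model, X_test)
  list(rmsep = sqrt(mean((y_test - pred)^2)),
       relative_errors = (pred - y_test) / y_test * 100,
       predictions = pred)
}

#' Jack-knife confidence intervals for latent-model coefficients
#'
#' Refits the model leaving out one batch at a time; the jack-knife standard
#' error of each coefficient is
#' `sqrt((B-1)/B * sum((theta_i - mean(theta))^2))` and the interval is the
#' full-data coefficient plus/minus the t(B-1) quantile times that SE.
#'
#' @param fit_fun Fitting closure `function(X, y)` returning a
#'   `latent_model` (e.g. `function(X, y) fit_pls(X, y, 2, seed = 1)`).
#' @param X,y Full training data (B >= 5 batches).
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `term`, `estimate`, `se`, `lower`,
#'   `upper` (intercept included).
#' @export
jackknife_ci <- function(fit_fun, X, y, level = 0.95) {
  X <- as.matrix(X)
  B <- nrow(X)
  if (B < 5L) fq_stop("jack-knife needs at least 5 batches")
  full <- fit_fun(X, y)
  coefs <- full$coefficients
  reps <- matrix(NA_real_, B, length(coefs),
                 dimnames = list(NULL, names(coefs)))
  for (i in seq_len(B)) {
    m <- tryCatch(
      suppressWarnings(fit_fun(X[-i, , drop = FALSE], y[-i])),
      error = function(e) {
        fq_compute_stop(sprintf("jack-knife replicate %d failed: %s", i,
                                conditionMessage(e)))
      })
    if (!identical(names(m$coefficients), names(coefs))) {
      fq_compute_stop(sprintf(
        "jack-knife replicate %d used different columns", i))
    }
    reps[i, ] <- m$coefficients
  }
  se <- sqrt((B - 1) / B * colSums(sweep(reps, 2, colMeans(reps))^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = B - 1)
  data.frame(term = names(coefs), estimate = unname(coefs), se = unname(se),
             lower = unname(coefs - tq * se), upper = unname(coefs + tq * se),
             stringsAsFactors = FALSE)
}

#' PCA screen for composition outliers
#'
#' Mean-centered (optionally unit-variance scaled) principal component
#' analysis by singular value decomposition, with Hotelling T-squared
#' flagging of batches whose score distance exceeds the chosen confidence
#' level.
#'
#' @param X B x n matrix of peak areas (B >= 3).
#' @param k Number of components (k <= min(B - 1, n)).
#' @param confidence Confidence level for the T-squared limit (default 0.95).
#' @param scale Scale columns to unit variance before decomposition?
#' @return An object of class `pca_result`: `scores` (B x k), `loadings`
#'   (n x k, orthonormal), `explained_variance_pct` (length k),
#'   `outlier_flags` (logical per batch), `t2`, `t2_limit`.
#' @export
pca_screen <- function(X, k = 2, confidence = 0.95, scale = FALSE) {
  X <- as.matrix(X)
  B <- nrow(X)
  if (B < 3L) fq_stop("PCA screen needs at least 3 batches")
  if (k > min(B - 1, ncol(X))) {
    fq_stop("k must be at most min(B - 1, n)")
  }
  sc <- scale_columns(X, if (scale) "uv" else "center")
  sv <- svd(sc$X)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  ev <- sv$d^2 / sum(sv$d^2) * 100
  lambda <- sv$d[seq_len(k)]^2 / (B - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  t2_limit <- k * (B - 1) / (B - k) * stats::qf(confidence, k, B - k)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = ev[seq_len(k)],
                 outlier_flags = stats::setNames(t2 > t2_limit, rownames(X)),
                 t2 = t2, t2_limit = t2_limit, k = k,
                 confidence = confidence),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components (%.1f%% variance); %d outlier(s) at %.0f%%\n",
              x$k, sum(x$explained_variance_pct), sum(x$outlier_flags),
              100 * x$confidence))
  invisible(x)
}
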