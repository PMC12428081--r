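# The optimization objective: decode theta -> fit pipeline + ridge under
# group-aware cross-validation -> negative RMSE, with any numerical
# failure converted into a fixed penalty so the optimizer learns to avoid
# ill-conditioned configurations instead of crashing.

#' Penalty score for ill-conditioned configurations
#'
#' Strictly worse than any achievable negative RMSE on bounded data.
#' @export
PENALTY_SCORE <- -1e6

#' Root mean squared error
#' @param y observed values.
#' @param yhat predictions.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (!length(y) || length(y) != length(yhat))
    stop("y and yhat must be non-empty and of equal length")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#' @param y observed values (non-constant, length >= 2).
#' @param yhat predictions.
#' @return `1 - SSres / SStot`.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) < 2 || length(y) != length(yhat))
    stop("need equal lengths >= 2")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("R^2 undefined for constant y")
  1 - sum((y - yhat)^2) / sstot
}

# --- ridge regression (normal equations, Cholesky, LS fallback) -------------

ridge_fit <- function(X, y, alpha) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + alpha
  b <- crossprod(Xc, y - ym)
  beta <- tryCatch({
    ch <- chol(A)
    backsolve(ch, forwardsolve(t(ch), b))
  }, error = function(e) NULL)
  if (is.null(beta))
    beta <- tryCatch(qr.solve(A, b), error = function(e)
      illcond("ridge: singular system"))
  beta <- as.numeric(beta)
  if (!all(is.finite(beta))) illcond("ridge: non-finite coefficients")
  list(beta = beta, xm = xm, intercept = ym)
}

ridge_predict <- function(fit, X) {
  as.numeric(sweep(X, 2, fit$xm) %*% fit$beta) + fit$intercept
}

# --- cross-validation strategy objects --------------------------------------

#' Cross-validation strategy descriptor
#'
#' @param method `"group_shuffle"` (default: 5 random group splits with a
#'   0.25 validation fraction) or `"leave_p_groups"`.
#' @param n_splits,test_frac,seed group-shuffle settings.
#' @param p_groups leave-P-groups-out setting.
#' @return An object of class `cv_strategy`.
#' @export
cv_strategy <- function(method = c("group_shuffle", "leave_p_groups"),
                        n_splits = 5, test_frac = 0.25, seed = 123L,
                        p_groups = 1) {
  method <- match.arg(method)
  structure(list(method = method, n_splits = n_splits,
                 test_frac = test_frac, seed = seed, p_groups = p_groups),
            class = "cv_strategy")
}

cv_folds <- function(s, cv) {
  switch(cv$method,
         group_shuffle = group_shuffle_split(s, cv$n_splits, cv$test_frac,
                                             cv$seed),
         leave_p_groups = leave_p_groups_out(s, cv$p_groups))
}

# --- fold-level scoring -----------------------------------------------------

# Fit pipeline + ridge on `train`, score RMSE on `holdout`.
fit_score_fold <- function(config, alpha, train, holdout, target,
                           seed = 0L) {
  fp <- fit_pipeline(config, train, seed = seed)
  tr <- fp$train_out
  te <- transform_pipeline(fp, holdout)
  rf <- ridge_fit(tr$absorbance, tr$targets[[target]], alpha)
  pred <- ridge_predict(rf, te$absorbance)
  if (!all(is.finite(pred))) illcond("non-finite predictions")
  rmse(holdout$targets[[target]], pred)
}

#' Cross-validated RMSE of one pipeline configuration
#'
#' Every fold refits the full pipeline state on its training side only.
#'
#' @param config a `pipeline_config`.
#' @param alpha ridge regularization strength.
#' @param train training `spectra_set` with targets.
#' @param target target component name.
#' @param cv a [cv_strategy()].
#' @param seed seed for randomized pipeline steps.
#' @return List with `rmse` (mean over folds), `r2`, `per_fold_rmse`,
#'   `status` (`"ok"` or `"ill_conditioned"`).
#' @export
evaluate_pipeline_cv <- function(config, alpha, train, target,
                                 cv = cv_strategy(), seed = 0L) {
  folds <- cv_folds(train, cv)
  per_fold <- numeric(0)
  r2s <- numeric(0)
  res <- tryCatch({
    for (fd in folds) {
      tr <- subset_rows(train, fd$train)
      va <- subset_rows(train, fd$validation)
      fp <- fit_pipeline(config, tr, seed = seed)
      pr <- ridge_predict(
        ridge_fit(fp$train_out$absorbance, tr$targets[[target]], alpha),
        transform_pipeline(fp, va)$absorbance)
      if (!all(is.finite(pr))) illcond("non-finite predictions")
      per_fold <- c(per_fold, rmse(va$targets[[target]], pr))
      if (length(unique(va$targets[[target]])) > 1)
        r2s <- c(r2s, r_squared(va$targets[[target]], pr))
    }
    list(rmse = mean(per_fold),
         r2 = if (length(r2s)) mean(r2s) else NA_real_,
         per_fold_rmse = per_fold, status = "ok")
  }, specopt_illcond = function(e)
    list(rmse = Inf, r2 = NA_real_, per_fold_rmse = numeric(0),
         status = "ill_conditioned", message = conditionMessage(e)))
  res
}

#' Objective evaluation for the pipeline optimizer
#'
#' Decodes `theta` into (pipeline configuration, ridge strength) and
#' scores it.  Default branch: mean negative RMSE over group-aware CV
#' folds, each fold fitting all pipeline state on its own training side.
#' If `test` is supplied *and* `allow_test = TRUE`, the pipeline is
#' instead fitted on all training rows and scored on `test` (negative
#' RMSE); selecting pipelines on test data biases the final assessment,
#' so this branch is off by default and `test` is ignored with a warning.
#' Numerical failures anywhere return the fixed [PENALTY_SCORE] rather
#' than propagating.
#'
#' @param theta length-2 optimizer vector (index coordinate, log10 ridge
#'   strength).
#' @param space a `search_space`.
#' @param train training `spectra_set` with targets.
#' @param target target component name.
#' @param cv a [cv_strategy()].
#' @param test optional external test `spectra_set`.
#' @param allow_test enable the external-test branch (default `FALSE`).
#' @param seed seed for randomized pipeline steps.
#' @param log_file optional path; one JSON line per evaluation is
#'   appended (decoded steps, alpha, per-fold RMSE, status).
#' @return Scalar score (negative RMSE, or the penalty).
#' @export
objective_evaluate <- function(theta, space, train, target,
                               cv = cv_strategy(), test = NULL,
                               allow_test = FALSE, seed = 0L,
                               log_file = NULL) {
  dec <- decode_theta(theta, space)
  if (!is.null(test) && !allow_test) {
    warning("external test set supplied but allow_test = FALSE; ",
            "falling back to cross-validation (selecting pipelines on ",
            "test data biases assessment)", call. = FALSE)
    test <- NULL
  }
  if (!is.null(test)) {
    res <- tryCatch({
      r <- fit_score_fold(dec$config, dec$alpha, train, test, target,
                          seed = seed)
      list(rmse = r, per_fold_rmse = r, status = "ok")
    }, specopt_illcond = function(e)
      list(rmse = Inf, per_fold_rmse = numeric(0),
           status = "ill_conditioned", message = conditionMessage(e)))
  } else {
    res <- evaluate_pipeline_cv(dec$config, dec$alpha, train, target, cv,
                                seed = seed)
  }
  score <- if (res$status == "ok") -res$rmse else PENALTY_SCORE
  if (!is.null(log_file)) {
    line <- jsonlite::toJSON(list(
      pipeline = pipeline_label(dec$config), alpha = dec$alpha,
      per_fold_rmse = res$per_fold_rmse, status = res$status,
      score = score), auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = log_file, append = TRUE)
  }
  score
}
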