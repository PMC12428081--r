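# Stage 2: the winning preprocessing pipeline is frozen and six standard
# regressors are tuned on the training groups and evaluated exactly once
# on the held-out test groups.  The estimators themselves are delegated
# to established libraries behind a uniform fit/predict contract; the
# bespoke content here is the tuning and leakage-guarded evaluation
# protocol.

#' Model specification for the stage-2 harness
#'
#' Search spaces: PLS latent variables 2..min(10, n_features); SVR (RBF)
#' C in \[0.1, 100\], epsilon in \[0.01, 1\], gamma in \[1e-4, 1\] on a log
#' scale; elastic net l1_ratio in \[0.1, 0.9\], lambda in \[1e-4, 1\]; GBM
#' 50-300 rounds, learning rate 0.01-0.3, depth 3-10, minimum split size
#' 2-10.  `ridgecv` and `lassolarscv` carry no Bayesian-optimization
#' search space: they select their regularization internally (log-spaced
#' 1e-6..1e6 ridge grid; 5-fold CV lasso path).
#'
#' @param name one of `"pls"`, `"svr"`, `"ridgecv"`, `"lassolarscv"`,
#'   `"elastic_net"`, `"gbm"`.
#' @param ninit,niter Bayesian-optimization budget (defaults: 5/100 for
#'   all tuned models except PLS at 5/10).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("pls", "svr", "ridgecv", "lassolarscv",
                                "elastic_net", "gbm"),
                       ninit = NULL, niter = NULL) {
  name <- match.arg(name)
  space <- switch(name,
    pls = list(params = "n_components", lower = 2, upper = 10,
               integer = TRUE),
    svr = list(params = c("C", "epsilon", "log10_gamma"),
               lower = c(0.1, 0.01, -4), upper = c(100, 1, 0)),
    elastic_net = list(params = c("l1_ratio", "alpha"),
                       lower = c(0.1, 1e-4), upper = c(0.9, 1)),
    gbm = list(params = c("n_estimators", "learning_rate", "max_depth",
                          "min_samples_split"),
               lower = c(50, 0.01, 3, 2), upper = c(300, 0.3, 10, 10),
               integer = c(TRUE, FALSE, TRUE, TRUE)),
    NULL)
  ninit <- ninit %||% 5
  niter <- niter %||% if (name == "pls") 10 else 100
  structure(list(name = name, search = space, ninit = ninit,
                 niter = niter),
            class = "model_spec")
}

#' All six stage-2 model specifications
#' @param ... passed to [model_spec()] (budget overrides).
#' @return Named list of `model_spec`s.
#' @export
model_specs <- function(...) {
  nm <- c("pls", "svr", "ridgecv", "lassolarscv", "elastic_net", "gbm")
  stats::setNames(lapply(nm, model_spec, ...), nm)
}

# --- uniform fit/predict contract over the estimator backends ---------------

fit_regressor <- function(spec, X, y, params = list(), seed = 0L) {
  name <- spec$name
  if (name == "pls") {
    nc <- min(as.integer(params$n_components %||% 2),
              ncol(X), nrow(X) - 1)
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    fit <- mixOmics::pls(X, data.frame(y = y), ncomp = nc,
                         mode = "regression", scale = FALSE)
    return(list(kind = "pls", fit = fit, ncomp = nc,
                cols = colnames(X)))
  }
  if (name == "svr") {
    fit <- with_seed(seed, e1071::svm(
      X, y, type = "eps-regression", kernel = "radial",
      cost = params$C %||% 1, epsilon = params$epsilon %||% 0.1,
      gamma = 10^(params$log10_gamma %||% log10(1 / ncol(X))),
      scale = FALSE))
    return(list(kind = "svr", fit = fit))
  }
  if (name == "ridgecv") {
    grid <- 10^seq(-6, 6, length.out = 25)
    folds <- min(5, nrow(X))
    errs <- vapply(grid, function(a) {
      fold_id <- rep_len(seq_len(folds), nrow(X))
      sq <- 0
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        rf <- ridge_fit(X[tr, , drop = FALSE], y[tr], a)
        sq <- sq + sum((y[!tr] - ridge_predict(rf, X[!tr, , drop = FALSE]))^2)
      }
      sq
    }, numeric(1))
    a <- grid[which.min(errs)]
    return(list(kind = "ridgecv", fit = ridge_fit(X, y, a), alpha = a))
  }
  if (name == "lassolarscv") {
    fit <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5,
                                             standardize = TRUE))
    return(list(kind = "glmnet", fit = fit))
  }
  if (name == "elastic_net") {
    l1 <- params$l1_ratio %||% 0.5
    lam <- params$alpha %||% 0.01
    fit <- glmnet::glmnet(X, y, alpha = l1, lambda = lam,
                          standardize = TRUE)
    return(list(kind = "glmnet_fixed", fit = fit, lambda = lam))
  }
  if (name == "gbm") {
    fit <- with_seed(seed, xgboost::xgboost(
      x = X, y = y, objective = "reg:squarederror",
      nrounds = as.integer(params$n_estimators %||% 100),
      learning_rate = params$learning_rate %||% 0.1,
      max_depth = as.integer(params$max_depth %||% 3),
      min_child_weight = as.integer(params$min_samples_split %||% 2),
      nthreads = 1, verbosity = 0))
    return(list(kind = "xgb", fit = fit))
  }
  stop("unknown model: ", name)
}

predict_regressor <- function(model, X) {
  out <- switch(model$kind,
    pls = {
      colnames(X) <- model$cols
      p <- stats::predict(model$fit, X)
      p$predict[, 1, model$ncomp]
    },
    svr = as.numeric(stats::predict(model$fit, X)),
    ridgecv = ridge_predict(model$fit, X),
    glmnet = as.numeric(stats::predict(model$fit, X, s = "lambda.min")),
    glmnet_fixed = as.numeric(stats::predict(model$fit, X,
                                             s = model$lambda)),
    xgb = as.numeric(stats::predict(model$fit, X)),
    stop("unknown model kind"))
  as.numeric(out)
}

# --- tuning -----------------------------------------------------------------

theta_to_params <- function(spec, theta) {
  sp <- spec$search
  out <- as.list(theta)
  names(out) <- sp$params
  if (!is.null(sp$integer)) {
    ints <- if (length(sp$integer) == 1) rep(sp$integer, length(out))
            else sp$integer
    out[ints] <- lapply(out[ints], function(v) as.integer(round(v)))
  }
  out
}

#' Tune a stage-2 model on the pipeline-transformed training data
#'
#' Models with a search space are tuned by the same GP Bayesian optimizer
#' used for stage 1, maximizing negative CV RMSE over group-aware folds;
#' `ridgecv` and `lassolarscv` skip Bayesian optimization entirely and
#' rely on their internal regularization search (no trace is emitted for
#' them).
#'
#' @param spec a [model_spec()].
#' @param pipeline a `pipeline_config` (or `NULL` for no preprocessing).
#' @param train training `spectra_set` with targets.
#' @param target target component name.
#' @param cv a [cv_strategy()].
#' @param seed integer seed.
#' @return List with `params` (best hyperparameters, possibly empty) and
#'   `trace` (a `bo_trace`, or `NULL` for the self-tuning models).
#' @export
tune_model <- function(spec, pipeline, train, target, cv = cv_strategy(),
                       seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$search))
    return(list(params = list(), trace = NULL))
  sp <- spec$search
  upper <- sp$upper
  if (spec$name == "pls")
    upper <- min(sp$upper, ncol(train$absorbance))
  folds <- cv_folds(train, cv)
  obj <- function(theta) {
    params <- theta_to_params(spec, theta)
    # any numerical failure of a candidate (e.g. a singular PLS solve at
    # too many components on low-rank data) is penalized, not fatal
    errs <- tryCatch(vapply(folds, function(fd) {
      tr <- subset_rows(train, fd$train)
      va <- subset_rows(train, fd$validation)
      if (!is.null(pipeline)) {
        fp <- fit_pipeline(pipeline, tr, seed = seed)
        Xtr <- fp$train_out$absorbance
        Xva <- transform_pipeline(fp, va)$absorbance
      } else {
        Xtr <- tr$absorbance; Xva <- va$absorbance
      }
      m <- fit_regressor(spec, Xtr, tr$targets[[target]], params, seed)
      rmse(va$targets[[target]], predict_regressor(m, Xva))
    }, numeric(1)),
    specopt_illcond = function(e) stop(e),
    error = function(e) illcond(conditionMessage(e)))
    -mean(errs)
  }
  trace <- bo_optimize(obj, sp$lower, upper, ninit = spec$ninit,
                       niter = spec$niter, seed = seed)
  list(params = theta_to_params(spec, trace$best_theta), trace = trace)
}

#' Final fit and single-shot test evaluation of one model
#'
#' Fits the frozen pipeline on the training rows only, fits the model on
#' the transformed training data, and computes test-set RMSEP and R^2
#' exactly once.  Errors out if any group appears on both sides (leakage
#' guard).
#'
#' @param spec a [model_spec()].
#' @param pipeline a `pipeline_config` or `NULL`.
#' @param params hyperparameters from [tune_model()].
#' @param train,test disjoint-group `spectra_set`s with targets.
#' @param target target component name.
#' @param seed integer seed.
#' @return One-row data frame: component, model, train RMSE/R2, test
#'   RMSEP/R2, pipeline label.
#' @export
evaluate_final <- function(spec, pipeline, params, train, test, target,
                           seed = 0L) {
  overlap <- intersect(unique(train$group_ids), unique(test$group_ids))
  if (length(overlap))
    stop("leakage: group(s) on both sides: ",
         paste(utils::head(overlap, 3), collapse = ", "))
  if (!is.null(pipeline)) {
    fp <- fit_pipeline(pipeline, train, seed = seed)
    Xtr <- fp$train_out$absorbance
    Xte <- transform_pipeline(fp, test)$absorbance
  } else {
    Xtr <- train$absorbance; Xte <- test$absorbance
  }
  ytr <- train$targets[[target]]; yte <- test$targets[[target]]
  m <- fit_regressor(spec, Xtr, ytr, params, seed)
  ptr <- predict_regressor(m, Xtr)
  pte <- predict_regressor(m, Xte)
  data.frame(component = target, model = spec$name,
             train_rmse = rmse(ytr, ptr), train_r2 = r_squared(ytr, ptr),
             rmsep = rmse(yte, pte), r2 = r_squared(yte, pte),
             pipeline = if (is.null(pipeline)) "none"
                        else pipeline_label(pipeline),
             params = paste(names(params),
                            vapply(params, function(v)
                              paste(format(v), collapse = ":"),
                              character(1)),
                            sep = "=", collapse = ", "),
             stringsAsFactors = FALSE)
}

#' Tune and evaluate all six models on a fixed pipeline
#'
#' @param pipeline a `pipeline_config` or `NULL` for no preprocessing.
#' @param train,test disjoint-group `spectra_set`s with targets.
#' @param target target component name.
#' @param specs list of [model_spec()]s (default all six).
#' @param cv a [cv_strategy()].
#' @param seed integer seed.
#' @return A `final_report` data frame, one row per model.
#' @export
final_report <- function(pipeline, train, test, target,
                         specs = model_specs(), cv = cv_strategy(),
                         seed = 0L) {
  rows <- lapply(specs, function(sp) {
    tuned <- tune_model(sp, pipeline, train, target, cv, seed)
    evaluate_final(sp, pipeline, tuned$params, train, test, target, seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("final_report", class(out))
  out
}
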