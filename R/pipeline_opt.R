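#' Optimize a spectral preprocessing pipeline
#'
#' The main fitting function of the package.  Enumerates all valid
#' ordered preprocessing pipelines from the candidate steps (under the
#' incompatibility rules), then searches the (pipeline index, log10
#' ridge strength) box by Gaussian-process Bayesian optimization with
#' Expected Improvement, scoring each decoded configuration by negative
#' RMSE under group-aware cross-validation with a ridge estimator.  The
#' winning pipeline and its ridge model are refitted on all training
#' rows, so the returned object predicts directly on new spectra.
#'
#' @param train a [spectra_set()] with targets.
#' @param target name of the target component to model.
#' @param candidates character vector of candidate step names (default:
#'   a standard twelve-step chemometric set).
#' @param allowed_lengths allowed pipeline lengths (default `c(1, 2)`).
#' @param rules an [incompatibility_rules()] object.
#' @param param_grids,unit_grids forwarded to [enumerate_pipelines()].
#' @param cv a [cv_strategy()] used for every objective evaluation.
#' @param ninit,niter Bayesian-optimization budgets (defaults 50 / 200).
#' @param seed integer seed for all randomness.
#' @param alpha_log10_bounds ridge exponent bounds (default `c(-6, 6)`).
#' @param xi EI exploration offset.
#' @param log_file optional JSON-lines evaluation log.
#' @return An object of class `pipeline_opt` with the optimization trace,
#'   the winning configuration and the refitted pipeline + ridge model.
#' @seealso [predict.pipeline_opt()], [summary.pipeline_opt()]
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_groups = 30, n_points = 120,
#'                                    seed = 7))
#' fit <- pipeline_opt(sim$spectra, "fat",
#'                     candidates = c("snv", "savgol", "scaler"),
#'                     unit_grids = TRUE, ninit = 5, niter = 10, seed = 1)
#' print(fit)
#' }
#' @export
pipeline_opt <- function(train, target,
                         candidates = c("msc", "savgol", "detrend",
                                        "scaler", "snv", "robust_scaler",
                                        "emsc", "pca", "normalization",
                                        "autoscale", "globalscaler",
                                        "meancn"),
                         allowed_lengths = c(1, 2),
                         rules = default_rules(),
                         param_grids = NULL, unit_grids = FALSE,
                         cv = cv_strategy(), ninit = 50, niter = 200,
                         seed = 0L, alpha_log10_bounds = c(-6, 6),
                         xi = 0.01, log_file = NULL) {
  stopifnot(inherits(train, "spectra_set"))
  if (is.null(train$targets) || !target %in% names(train$targets))
    stop("target '", target, "' not present in the training set")
  space <- enumerate_pipelines(candidates, allowed_lengths, rules,
                               param_grids, unit_grids,
                               alpha_log10_bounds)
  bounds <- space_bounds(space)
  obj <- function(theta)
    objective_evaluate(theta, space, train, target, cv = cv, seed = seed,
                       log_file = log_file)
  trace <- bo_optimize(obj, bounds$lower, bounds$upper, ninit = ninit,
                       niter = niter, seed = seed, xi = xi,
                       label_fn = function(th)
                         pipeline_label(decode_theta(th, space)$config))
  dec <- decode_theta(trace$best_theta, space)
  final_cv <- evaluate_pipeline_cv(dec$config, dec$alpha, train, target,
                                   cv, seed = seed)
  fp <- fit_pipeline(dec$config, train, seed = seed)
  rf <- ridge_fit(fp$train_out$absorbance, train$targets[[target]],
                  dec$alpha)
  structure(list(target = target, space = space, trace = trace,
                 best_config = dec$config, best_alpha = dec$alpha,
                 best_score = trace$best_score, cv = cv, cv_result = final_cv,
                 fitted_pipeline = fp, ridge = rf, train = train,
                 seed = seed),
            class = "pipeline_opt")
}

#' @export
print.pipeline_opt <- function(x, ...) {
  cat("Spectral preprocessing pipeline optimization\n")
  cat(sprintf("  target:      %s\n", x$target))
  cat(sprintf("  space:       %d configurations x ridge 10^[%g, %g]\n",
              length(x$space$configs), x$space$alpha_log10_bounds[1],
              x$space$alpha_log10_bounds[2]))
  cat(sprintf("  evaluations: %d (ninit %d + niter %d)\n",
              nrow(x$trace$iterations), x$trace$ninit, x$trace$niter))
  cat(sprintf("  best:        %s\n", pipeline_label(x$best_config)))
  cat(sprintf("  ridge alpha: %.4g\n", x$best_alpha))
  cat(sprintf("  CV RMSE:     %.6g\n", -x$best_score))
  invisible(x)
}

#' @export
summary.pipeline_opt <- function(object, ...) {
  it <- object$trace$iterations
  ok <- it$status == "ok"
  out <- list(target = object$target,
              best_pipeline = pipeline_label(object$best_config),
              best_alpha = object$best_alpha,
              cv_rmse = -object$best_score,
              cv_r2 = object$cv_result$r2,
              per_fold_rmse = object$cv_result$per_fold_rmse,
              n_evaluations = nrow(it), n_failed = sum(!ok),
              n_configs = length(object$space$configs))
  class(out) <- "summary.pipeline_opt"
  out
}

#' @export
print.summary.pipeline_opt <- function(x, ...) {
  cat(sprintf("Best pipeline for %s: %s (alpha %.4g)\n", x$target,
              x$best_pipeline, x$best_alpha))
  cat(sprintf("CV RMSE %.6g, CV R^2 %.4f over %d folds\n", x$cv_rmse,
              x$cv_r2, length(x$per_fold_rmse)))
  cat(sprintf("%d objective evaluations (%d penalized) over %d configurations\n",
              x$n_evaluations, x$n_failed, x$n_configs))
  invisible(x)
}

#' Predict from an optimized pipeline
#'
#' Applies the winning preprocessing pipeline (state fitted on the
#' training rows) and its ridge model to new spectra.
#'
#' @param object a `pipeline_opt` fit.
#' @param newdata a `spectra_set` on the same wavenumber axis.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations.
#' @export
predict.pipeline_opt <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectra_set"))
  tr <- transform_pipeline(object$fitted_pipeline, newdata)
  ridge_predict(object$ridge, tr$absorbance)
}

#' Residuals of the optimized pipeline on its training data
#' @param object a `pipeline_opt` fit.
#' @param ... unused.
#' @return Numeric vector of training residuals.
#' @export
residuals.pipeline_opt <- function(object, ...) {
  object$train$targets[[object$target]] -
    predict(object, object$train)
}

#' Plot the optimization trace
#'
#' Score per evaluation with the running best overlaid; penalized
#' evaluations are drawn at the bottom margin.
#'
#' @param x a `pipeline_opt` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pipeline_opt <- function(x, ...) {
  it <- x$trace$iterations
  sc <- it$score
  ok <- is.finite(sc) & sc > PENALTY_SCORE / 2
  ylim <- range(sc[ok])
  disp <- ifelse(ok, sc, ylim[1] - 0.05 * diff(ylim))
  graphics::plot(seq_along(disp), disp, pch = ifelse(ok, 16, 4),
                 col = ifelse(it$phase == "init", "grey50", "steelblue"),
                 xlab = "evaluation", ylab = "score (-RMSE)",
                 main = paste("Pipeline optimization:", x$target), ...)
  graphics::lines(cummax(ifelse(ok, sc, -Inf)), col = "firebrick", lwd = 2)
  graphics::abline(v = x$trace$ninit + 0.5, lty = 3)
  invisible(x)
}
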