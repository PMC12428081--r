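# Bayesian optimization driver: random initial design, then GP posterior
# fitting and Expected Improvement maximization over a continuous box.
# Discrete dimensions (the pipeline index) are handled by continuous
# relaxation and flooring at decode time.

#' Maximize an objective by GP Bayesian optimization
#'
#' Draws `ninit` uniform points in the box, then for `niter` rounds fits
#' a Gaussian-process posterior to all observations and evaluates the
#' objective at the Expected Improvement maximizer (located by random
#' multistart: `n_candidates` uniform draws plus local refinement from
#' the best few).  Objectives that raise errors score `-Inf` in the
#' trace; if every initial point fails the run aborts with a diagnostic
#' trace attached.
#'
#' @param objective function of a numeric vector `theta` returning a
#'   scalar score to maximize.
#' @param lower,upper numeric vectors delimiting the box.
#' @param ninit number of random initial evaluations (>= 1).
#' @param niter number of model-guided evaluations (>= 0).
#' @param seed integer seed controlling all randomness.
#' @param xi EI exploration offset.
#' @param n_candidates random acquisition candidates per round.
#' @param label_fn optional function of theta returning a display label
#'   recorded in the trace.
#' @return An object of class `bo_trace`: data frame `iterations`
#'   (theta coordinates, score, status, phase), `best_theta`,
#'   `best_score`, plus the budgets and seed.
#' @export
bo_optimize <- function(objective, lower, upper, ninit = 50, niter = 200,
                        seed = 0L, xi = 0.01, n_candidates = 1000,
                        label_fn = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            ninit >= 1, niter >= 0)
  d <- length(lower)
  evals <- list()
  score_one <- function(theta) {
    val <- tryCatch(objective(theta), error = function(e) {
      if (is_illcond(e)) -Inf else stop(e)
    })
    if (!is.finite(val)) val <- -Inf
    val
  }

  with_seed(seed, {
    X <- matrix(stats::runif(ninit * d, rep(lower, each = ninit),
                             rep(upper, each = ninit)), ninit, d)
    y <- apply(X, 1, score_one)
    if (all(!is.finite(y)))
      stop(structure(class = c("specopt_bo_abort", "error", "condition"),
                     list(message = "objective failed on every initial point",
                          call = NULL, trace = list(X = X, y = y))))

    for (it in seq_len(niter)) {
      ok <- is.finite(y)
      # failed points enter the GP at a pessimistic floor so the surrogate
      # learns to avoid them without destabilizing the fit
      yfit <- y
      if (any(!ok)) yfit[!ok] <- min(y[ok]) - 2 * max(stats::sd(y[ok]), 1e-3)
      fit <- gp_fit(X, yfit)
      best <- max(y[ok])
      cand <- matrix(stats::runif(n_candidates * d,
                                  rep(lower, each = n_candidates),
                                  rep(upper, each = n_candidates)),
                     n_candidates, d)
      # stratify the first coordinate: when it is a discrete pipeline
      # index (an integer-spanned axis), guarantee every cell midpoint
      # appears among the candidates at a few spreads of the others
      span1 <- upper[1] - lower[1]
      if (span1 <= 512 && abs(span1 - round(span1)) < 1e-9) {
        mids <- lower[1] + seq_len(span1) - 0.5
        extra <- matrix(stats::runif(4 * length(mids) * d,
                                     rep(lower, each = 4 * length(mids)),
                                     rep(upper, each = 4 * length(mids))),
                        ncol = d)
        extra[, 1] <- rep(mids, 4)
        cand <- rbind(cand, extra)
      }
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mean, pr$sd, best, xi)
      top <- order(ei, decreasing = TRUE)[seq_len(min(5, n_candidates))]
      prop <- cand[top[1], ]
      prop_ei <- ei[top[1]]
      for (t0 in top) {
        op <- tryCatch(stats::optim(
          cand[t0, ],
          function(th) {
            p <- gp_predict(fit, matrix(th, 1))
            -expected_improvement(p$mean, p$sd, best, xi)
          },
          method = "L-BFGS-B", lower = lower,
          upper = upper - 1e-9 * (upper - lower)),
          error = function(e) NULL)
        if (!is.null(op) && -op$value > prop_ei) {
          prop_ei <- -op$value; prop <- op$par
        }
      }
      X <- rbind(X, prop)
      y <- c(y, score_one(prop))
    }
  })

  status <- ifelse(is.finite(y), "ok", "failed")
  labels <- if (is.null(label_fn)) rep(NA_character_, nrow(X))
            else apply(X, 1, label_fn)
  iters <- data.frame(X, score = y, status = status, label = labels,
                      phase = rep(c("init", "bo"), c(ninit, nrow(X) - ninit)),
                      stringsAsFactors = FALSE)
  names(iters)[seq_len(d)] <- paste0("theta", seq_len(d))
  best_i <- which.max(y)
  structure(list(iterations = iters, best_theta = X[best_i, ],
                 best_score = y[best_i], ninit = ninit, niter = niter,
                 seed = seed),
            class = "bo_trace")
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf("<bo_trace> %d evaluations (ninit %d + niter %d), best score %.6g\n",
              nrow(x$iterations), x$ninit, x$niter, x$best_score))
  if (!all(is.na(x$iterations$label))) {
    bl <- x$iterations$label[which.max(x$iterations$score)]
    cat("  best:", bl, "\n")
  }
  invisible(x)
}
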