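# Gaussian-process regression surrogate for Bayesian optimization.
# Matern 5/2 kernel with per-dimension length-scales; amplitude, scales
# and observation noise estimated by marginal-likelihood maximization,
# with a hard noise floor so the Cholesky stays stable near duplicated
# design points.

matern52 <- function(X1, X2, ls, amp) {
  # X scaled by length-scales; r = Euclidean distance in scaled space
  S1 <- sweep(X1, 2, ls, "/")
  S2 <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * S1 %*% t(S2)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  amp * (1 + sqrt(5) * r + 5 / 3 * d2) * exp(-sqrt(5) * r)
}

gp_nll <- function(log_par, X, y, noise_floor) {
  d <- ncol(X)
  ls <- exp(log_par[seq_len(d)])
  amp <- exp(log_par[d + 1])
  noise <- exp(log_par[d + 2]) + noise_floor
  K <- matern52(X, X, ls, amp) + diag(noise, nrow(X))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

#' Fit a Gaussian-process surrogate
#'
#' @param X design matrix (n x d), coordinates on the optimizer box.
#' @param y observed objective values.
#' @param noise_floor minimum observation noise variance (default 1e-6).
#' @param n_restarts hyperparameter optimization restarts.
#' @return A `gp_fit` object used by [gp_predict()].
#' @export
gp_fit <- function(X, y, noise_floor = 1e-6, n_restarts = 2) {
  X <- as.matrix(X)
  d <- ncol(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  span <- apply(X, 2, function(v) max(diff(range(v)), 1e-3))

  starts <- list(c(log(span / 3), 0, log(1e-4)))
  if (n_restarts > 1)
    starts <- c(starts, lapply(seq_len(n_restarts - 1), function(i)
      c(log(span / 3) + (i - 1.5), 0.5 * (i - 1.5), log(1e-3))))
  best <- NULL; bestval <- Inf
  for (s0 in starts) {
    op <- tryCatch(
      stats::optim(s0, gp_nll, X = X, y = ys, noise_floor = noise_floor,
                   method = "L-BFGS-B",
                   lower = c(log(span) - 6, -6, log(1e-8)),
                   upper = c(log(span) + 4, 6, log(1))),
      error = function(e) NULL)
    if (!is.null(op) && op$value < bestval) { bestval <- op$value; best <- op$par }
  }
  if (is.null(best)) best <- starts[[1]]
  ls <- exp(best[seq_len(d)]); amp <- exp(best[d + 1])
  noise <- exp(best[d + 2]) + noise_floor
  K <- matern52(X, X, ls, amp) + diag(noise, nrow(X))
  ch <- chol(K + diag(1e-10, nrow(X)))
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, chol = ch, alpha = alpha, ls = ls, amp = amp,
                 noise = noise, mu = mu, sdy = sdy),
            class = "gp_fit")
}

#' Posterior mean and standard deviation of a GP surrogate
#' @param fit a `gp_fit`.
#' @param Xnew matrix of query points.
#' @return List with vectors `mean` and `sd`.
#' @export
gp_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- matern52(Xnew, fit$X, fit$ls, fit$amp)
  mean_s <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(fit$amp - colSums(v^2), 0)
  list(mean = fit$mu + fit$sdy * mean_s,
       sd = fit$sdy * sqrt(var_s))
}

#' Expected improvement acquisition
#'
#' For a maximization problem: `EI = (mu - best - xi) * Phi(z) +
#' sigma * phi(z)` with `z = (mu - best - xi) / sigma`; zero when
#' `sigma = 0`.
#'
#' @param mu posterior mean (vectorized).
#' @param sigma posterior standard deviation (>= 0).
#' @param best incumbent objective value.
#' @param xi exploration offset (>= 0).
#' @return Non-negative expected improvement values.
#' @export
expected_improvement <- function(mu, sigma, best, xi = 0) {
  stopifnot(all(sigma >= 0), xi >= 0)
  imp <- mu - best - xi
  out <- numeric(length(mu))
  pos <- sigma > 0
  z <- imp[pos] / sigma[pos]
  out[pos] <- imp[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  pmax(out, 0)
}
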