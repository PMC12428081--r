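# Preprocessing operator registry.
#
# Every operator is exposed through a uniform fit/transform contract with
# strict train-only fitting: row-wise operators (SNV and relatives,
# derivatives, detrending, baseline removal) carry empty fitted state,
# while column-wise and reference-based operators (scatter correction
# references, scalers, decompositions) learn their state from the
# training rows alone and never re-estimate it at transform time.

# --- parameter plumbing -----------------------------------------------------

PARAM_ALIASES <- c(deriv_order = "deriv", filter_win = "window_length",
                   poly_order = "polyorder", win = "window_length")

resolve_aliases <- function(params) {
  nm <- names(params)
  hit <- nm %in% names(PARAM_ALIASES)
  names(params)[hit] <- PARAM_ALIASES[nm[hit]]
  params
}

#' Construct a preprocessing step
#'
#' Builds a named, parameterized preprocessing step after validating the
#' parameters against the step's declared domain.  Parameter spellings
#' used in common search-space tables (`deriv_order`, `filter_win`,
#' `poly_order`) are accepted as aliases of `deriv`, `window_length` and
#' `polyorder`.
#'
#' @param name registry name, one of [step_names()].
#' @param ... parameters, e.g. `window_length = 11`.
#' @param params alternative list form of the parameters.
#' @return An object of class `preproc_step`.
#' @examples
#' preproc_step("savgol", window_length = 11, polyorder = 2, deriv = 1)
#' @export
preproc_step <- function(name, ..., params = list()) {
  reg <- step_registry()
  if (!name %in% names(reg)) stop("unknown preprocessing step: ", name)
  def <- reg[[name]]
  p <- resolve_aliases(utils::modifyList(params, list(...)))
  unknown <- setdiff(names(p), names(def$params))
  if (length(unknown))
    stop("unknown parameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "))
  full <- utils::modifyList(lapply(def$params, `[[`, "default"), p)
  if (!is.null(def$validate)) def$validate(full)
  structure(list(name = name, params = full), class = "preproc_step")
}

#' @export
print.preproc_step <- function(x, ...) {
  cat(step_label(x), "\n"); invisible(x)
}

step_label <- function(step) {
  if (!length(step$params)) return(step$name)
  vals <- vapply(step$params, function(v) paste(format(v), collapse = ":"),
                 character(1))
  sprintf("%s(%s)", step$name,
          paste(names(vals), vals, sep = "=", collapse = ", "))
}

#' Names of all registered preprocessing steps
#' @return Character vector of registry names.
#' @export
step_names <- function() names(step_registry())

#' Is a step fitted column-wise / reference-based?
#'
#' Row-wise operators carry empty fitted state; everything else learns
#' train-derived statistics.
#' @param name registry name.
#' @return Logical.
#' @export
step_is_rowwise <- function(name) {
  isTRUE(step_registry()[[name]]$rowwise)
}

# --- shared numeric helpers -------------------------------------------------

row_sd <- function(m) {
  p <- ncol(m)
  if (p < 2) return(rep(0, nrow(m)))
  sqrt(rowSums((m - rowMeans(m))^2) / (p - 1))
}

snv_rows <- function(m, label = "snv") {
  s <- row_sd(m)
  if (any(s == 0))
    illcond(sprintf("%s: zero row standard deviation (constant spectrum)",
                    label))
  (m - rowMeans(m)) / s
}

col_quantile <- function(m, q) apply(m, 2, stats::quantile, probs = q,
                                     type = 7, names = FALSE)

# population (ddof 0) column sd, the convention of the scaler family;
# SNV and friends use the sample (n-1) definition instead
col_sd_pop <- function(m) {
  n <- nrow(m)
  sqrt(colSums(sweep(m, 2, colMeans(m))^2) / n)
}

# Index axis rescaled to [-1, 1]; used by EMSC and detrending so the
# polynomial terms stay well conditioned regardless of the cm^-1 scale.
scaled_axis <- function(p) {
  if (p == 1) return(0)
  seq(-1, 1, length.out = p)
}

# Second-difference penalty matrix (sparse) for the asymmetric least
# squares baseline.
als_penalty <- function(p, lam) {
  D <- Matrix::bandSparse(p - 2, p, k = 0:2,
                          diagonals = list(rep(1, p - 2), rep(-2, p - 2),
                                           rep(1, p - 2)))
  lam * Matrix::crossprod(D)
}

als_baseline_row <- function(x, lam, asym, niter, DtD) {
  # solve for the deviation from the row mean: the second-difference
  # penalty annihilates constants exactly, so (W + DtD) xbar = w xbar
  # and the constant component carries no solver error
  xbar <- mean(x)
  xc <- x - xbar
  w <- rep(1, length(x))
  z <- xc
  for (i in seq_len(niter)) {
    A <- Matrix::Diagonal(x = w) + DtD
    z <- as.numeric(Matrix::solve(A, w * xc))
    w <- ifelse(xc > z, asym, 1 - asym)
  }
  z + xbar
}

# Yeo-Johnson transform and per-column MLE of its exponent.
yj <- function(x, lambda) {
  y <- x
  pos <- x >= 0
  if (abs(lambda) > 1e-10) {
    y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else y[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-10) {
    y[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else y[!pos] <- -log1p(-x[!pos])
  y
}

yj_fit_lambda <- function(x) {
  ll <- function(lmb) {
    y <- yj(x, lmb)
    v <- stats::var(y) * (length(y) - 1) / length(y)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -length(x) / 2 * log(v) + (lmb - 1) * sum(sign(x) * log1p(abs(x)))
  }
  stats::optimize(ll, c(-4, 4), maximum = TRUE)$maximum
}

# --- the registry -----------------------------------------------------------

# Each entry: rowwise flag, params (default + optional grid used by the
# default enumeration), optional validate, fit(step, train, seed) -> state,
# transform(state, step, matrix, wavenumbers) -> list(m, wavenumbers).
step_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)

  pass_wn <- function(m, wn) list(m = m, wavenumbers = wn)

  reg <- list(
    snv = list(
      rowwise = TRUE, params = list(),
      transform = function(state, step, m, wn) pass_wn(snv_rows(m), wn)),

    row_standardizer = list(
      # numerically SNV; kept as a distinct registry name because the
      # compatibility rules treat it as a scaling-family member
      rowwise = TRUE, params = list(),
      transform = function(state, step, m, wn)
        pass_wn(snv_rows(m, "row_standardizer"), wn)),

    lsnv = list(
      rowwise = TRUE,
      params = list(window = list(default = 100)),
      validate = function(p) if (p$window < 2) stop("lsnv window must be >= 2"),
      transform = function(state, step, m, wn) {
        w <- step$params$window
        p <- ncol(m)
        starts <- seq(1, p, by = w)
        for (s0 in starts) {
          idx <- s0:min(s0 + w - 1, p)
          m[, idx] <- if (length(idx) > 1) snv_rows(m[, idx, drop = FALSE],
                                                    "lsnv")
                      else illcond("lsnv: window of width 1")
        }
        pass_wn(m, wn)
      }),

    rnv = list(
      rowwise = TRUE,
      params = list(q = list(default = 25)),
      validate = function(p) if (p$q <= 0 || p$q >= 100)
        stop("rnv percentile q must be in (0, 100)"),
      transform = function(state, step, m, wn) {
        q <- step$params$q / 100
        out <- t(apply(m, 1, function(x) {
          pq <- stats::quantile(x, q, type = 7, names = FALSE)
          lo <- x[x <= pq]
          if (length(lo) < 2) illcond("rnv: too few points below percentile")
          s <- stats::sd(lo)
          if (s == 0) illcond("rnv: zero spread below percentile")
          (x - pq) / s
        }))
        pass_wn(out, wn)
      }),

    msc = list(
      rowwise = FALSE,
      params = list(reference = list(default = "mean",
                                     grid = c("mean", "median"))),
      validate = function(p) if (!p$reference %in% c("mean", "median"))
        stop("msc reference must be 'mean' or 'median'"),
      fit = function(step, m, wn, seed) {
        ref <- if (step$params$reference == "mean") colMeans(m)
               else apply(m, 2, stats::median)
        list(reference = ref)
      },
      transform = function(state, step, m, wn) {
        r <- state$reference
        vr <- stats::var(r)
        if (!is.finite(vr) || vr == 0)
          illcond("msc: zero-variance reference spectrum")
        rc <- r - mean(r)            # sum(rc) = 0, so the centered slope
        b <- as.numeric(m %*% rc) / sum(rc^2)
        a <- rowMeans(m) - b * mean(r)
        if (any(b == 0)) illcond("msc: zero slope against reference")
        pass_wn((m - a) / b, wn)
      }),

    emsc = list(
      rowwise = FALSE,
      params = list(reference = list(default = "mean",
                                     grid = c("mean", "median")),
                    order = list(default = 2)),
      validate = function(p) {
        if (!p$reference %in% c("mean", "median"))
          stop("emsc reference must be 'mean' or 'median'")
        if (!p$order %in% 0:2) stop("emsc polynomial order must be 0, 1 or 2")
      },
      fit = function(step, m, wn, seed) {
        ref <- if (step$params$reference == "mean") colMeans(m)
               else apply(m, 2, stats::median)
        # wavenumber axis rescaled to [-1,1] stabilizes the polynomial part
        lt <- if (!is.null(wn) && diff(range(wn)) > 0)
          2 * (wn - min(wn)) / diff(range(wn)) - 1 else scaled_axis(ncol(m))
        list(reference = ref, lt = lt)
      },
      transform = function(state, step, m, wn) {
        ord <- step$params$order
        lt <- state$lt
        X <- cbind(1, state$reference)
        if (ord >= 1) X <- cbind(X, lt)
        if (ord >= 2) X <- cbind(X, lt^2)
        qr_X <- qr(X)
        if (qr_X$rank < ncol(X))
          illcond("emsc: singular design (degenerate reference)")
        cf <- qr.coef(qr_X, t(m))  # (1+1+ord) x n
        b <- cf[2, ]
        if (any(b == 0)) illcond("emsc: zero multiplicative slope")
        fit_poly <- X[, -2, drop = FALSE] %*% cf[-2, , drop = FALSE]
        pass_wn(t((t(m) - fit_poly) / rep(b, each = ncol(m))), wn)
      }),

    savgol = list(
      rowwise = TRUE,
      params = list(window_length = list(default = 11, grid = c(5, 7, 11, 15)),
                    polyorder = list(default = 2, grid = c(2, 3, 4)),
                    deriv = list(default = 0, grid = c(0, 1, 2))),
      validate = function(p) {
        if (p$window_length %% 2 != 1 || p$window_length < 3)
          stop("savgol window_length must be odd and >= 3")
        if (p$polyorder >= p$window_length)
          stop("savgol polyorder must be < window_length")
        if (p$deriv > p$polyorder)
          stop("savgol deriv must be <= polyorder")
      },
      transform = function(state, step, m, wn) {
        p <- step$params
        # derivative taken w.r.t. the point index (ts = 1); downstream
        # scalers absorb the cm^-1 step factor
        out <- t(apply(m, 1, signal::sgolayfilt, p = p$polyorder,
                       n = p$window_length, m = p$deriv, ts = 1))
        pass_wn(out, wn)
      }),

    detrend = list(
      rowwise = TRUE,
      params = list(method = list(default = "simple",
                                  grid = c("simple", "polynomial", "spline")),
                    order = list(default = 2),
                    dspline = list(default = 100)),
      validate = function(p) {
        if (!p$method %in% c("simple", "polynomial", "spline"))
          stop("detrend method must be simple, polynomial or spline")
        if (p$order < 1) stop("detrend order must be >= 1")
        if (p$dspline < 4) stop("detrend dspline must be >= 4")
      },
      transform = function(state, step, m, wn) {
        p <- ncol(m)
        prm <- step$params
        X <- switch(prm$method,
          simple = cbind(1, scaled_axis(p)),
          polynomial = stats::poly(seq_len(p), degree = prm$order, raw = FALSE,
                                   simple = TRUE),
          spline = {
            kn <- seq(prm$dspline, p - 1, by = prm$dspline)
            splines::bs(seq_len(p), knots = kn, degree = 3, intercept = TRUE)
          })
        if (prm$method == "polynomial") X <- cbind(1, X)
        qr_X <- qr(X)
        fitted <- t(qr.fitted(qr_X, t(m)))
        pass_wn(m - fitted, wn)
      }),

    als_baseline = list(
      rowwise = TRUE,
      params = list(lam = list(default = 1e5),
                    p = list(default = 0.01),
                    niter = list(default = 10)),
      validate = function(p) {
        if (p$lam <= 0) stop("als lam must be > 0")
        if (p$p <= 0 || p$p >= 1) stop("als p must be in (0,1)")
      },
      transform = function(state, step, m, wn) {
        prm <- step$params
        DtD <- als_penalty(ncol(m), prm$lam)
        out <- t(apply(m, 1, function(x)
          x - als_baseline_row(x, prm$lam, prm$p, prm$niter, DtD)))
        pass_wn(out, wn)
      }),

    meancn = list(
      rowwise = FALSE, params = list(),
      fit = function(step, m, wn, seed) list(center = colMeans(m)),
      transform = function(state, step, m, wn)
        pass_wn(sweep(m, 2, state$center), wn)),

    scaler = list(
      rowwise = FALSE,
      params = list(with_mean = list(default = TRUE, grid = c(TRUE, FALSE)),
                    with_std = list(default = TRUE, grid = c(TRUE, FALSE))),
      fit = function(step, m, wn, seed) {
        s <- col_sd_pop(m)
        s[s == 0] <- 1  # constant columns pass through unscaled
        list(center = colMeans(m), scale = s)
      },
      transform = function(state, step, m, wn) {
        if (step$params$with_mean) m <- sweep(m, 2, state$center)
        if (step$params$with_std) m <- sweep(m, 2, state$scale, "/")
        pass_wn(m, wn)
      }),

    autoscale = list(
      rowwise = FALSE, params = list(),
      fit = function(step, m, wn, seed) {
        s <- col_sd_pop(m); s[s == 0] <- 1
        list(center = colMeans(m), scale = s)
      },
      transform = function(state, step, m, wn)
        pass_wn(sweep(sweep(m, 2, state$center), 2, state$scale, "/"), wn)),

    globalscaler = list(
      rowwise = FALSE, params = list(),
      fit = function(step, m, wn, seed) {
        v <- as.numeric(m)
        s <- sqrt(mean((v - mean(v))^2))
        if (s == 0) illcond("globalscaler: constant training matrix")
        list(center = mean(v), scale = s)
      },
      transform = function(state, step, m, wn)
        pass_wn((m - state$center) / state$scale, wn)),

    robust_scaler = list(
      rowwise = FALSE,
      params = list(
        quantile_range = list(default = c(25, 75),
                              grid = list(c(5, 80), c(10, 90), c(25, 75))),
        with_centering = list(default = TRUE, grid = c(TRUE, FALSE)),
        with_scaling = list(default = TRUE, grid = c(TRUE, FALSE)),
        unit_variance = list(default = FALSE, grid = c(TRUE, FALSE))),
      validate = function(p) {
        qr <- p$quantile_range
        if (length(qr) != 2 || qr[1] >= qr[2] || qr[1] < 0 || qr[2] > 100)
          stop("robust_scaler quantile_range must be increasing within [0,100]")
      },
      fit = function(step, m, wn, seed) {
        p <- step$params
        qr <- p$quantile_range / 100
        sc <- col_quantile(m, qr[2]) - col_quantile(m, qr[1])
        if (p$unit_variance)
          sc <- sc / (stats::qnorm(qr[2]) - stats::qnorm(qr[1]))
        sc[sc == 0] <- 1
        list(center = apply(m, 2, stats::median), scale = sc)
      },
      transform = function(state, step, m, wn) {
        if (step$params$with_centering) m <- sweep(m, 2, state$center)
        if (step$params$with_scaling) m <- sweep(m, 2, state$scale, "/")
        pass_wn(m, wn)
      }),

    minmax_scaler = list(
      rowwise = FALSE, params = list(),
      fit = function(step, m, wn, seed) {
        lo <- apply(m, 2, min); hi <- apply(m, 2, max)
        rg <- hi - lo; rg[rg == 0] <- 1
        list(min = lo, range = rg)
      },
      transform = function(state, step, m, wn)
        pass_wn(sweep(sweep(m, 2, state$min), 2, state$range, "/"), wn)),

    normalization = list(
      rowwise = TRUE, params = list(),
      transform = function(state, step, m, wn) {
        nrm <- sqrt(rowSums(m^2))
        if (any(nrm == 0)) illcond("normalization: zero-norm spectrum")
        pass_wn(m / nrm, wn)
      }),

    power_transformer = list(
      rowwise = FALSE, params = list(),
      fit = function(step, m, wn, seed) {
        lambdas <- apply(m, 2, yj_fit_lambda)
        tr <- vapply(seq_len(ncol(m)),
                     function(j) yj(m[, j], lambdas[j]), numeric(nrow(m)))
        tr <- matrix(tr, nrow = nrow(m))
        s <- col_sd_pop(tr); s[s == 0] <- 1
        list(lambdas = lambdas, center = colMeans(tr), scale = s)
      },
      transform = function(state, step, m, wn) {
        out <- vapply(seq_len(ncol(m)),
                      function(j) yj(m[, j], state$lambdas[j]),
                      numeric(nrow(m)))
        out <- matrix(out, nrow = nrow(m))
        pass_wn(sweep(sweep(out, 2, state$center), 2, state$scale, "/"), wn)
      }),

    quantile_transformer = list(
      rowwise = FALSE,
      params = list(n_quantiles = list(default = 1000)),
      fit = function(step, m, wn, seed) {
        nq <- min(step$params$n_quantiles, nrow(m))
        probs <- seq(0, 1, length.out = max(nq, 2))
        list(probs = probs,
             quantiles = apply(m, 2, stats::quantile, probs = probs,
                               type = 7, names = FALSE))
      },
      transform = function(state, step, m, wn) {
        out <- vapply(seq_len(ncol(m)), function(j) {
          q <- state$quantiles[, j]
          if (q[length(q)] == q[1]) return(rep(0.5, nrow(m)))
          stats::approx(q, state$probs, xout = m[, j], rule = 2,
                        ties = "ordered")$y
        }, numeric(nrow(m)))
        pass_wn(matrix(out, nrow = nrow(m)), wn)
      }),

    pca = list(
      rowwise = FALSE,
      params = list(n_components = list(default = 10)),
      fit = function(step, m, wn, seed) {
        nc <- min(step$params$n_components, nrow(m) - 1, ncol(m))
        if (nc < 1) illcond("pca: not enough rows for one component")
        pr <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = nc)
        list(center = pr$center, rotation = pr$rotation)
      },
      transform = function(state, step, m, wn)
        list(m = sweep(m, 2, state$center) %*% state$rotation,
             wavenumbers = NULL)),

    kernel_pca = list(
      rowwise = FALSE,
      params = list(n_components = list(default = 10)),
      fit = function(step, m, wn, seed) {
        nc <- min(step$params$n_components, nrow(m) - 1)
        if (nc < 1) illcond("kernel_pca: not enough rows")
        kp <- tryCatch(
          kernlab::kpca(m, kernel = "rbfdot",
                        kpar = list(sigma = 1 / ncol(m)), features = nc),
          error = function(e) illcond(paste("kernel_pca:", conditionMessage(e))))
        list(kp = kp)
      },
      transform = function(state, step, m, wn)
        list(m = kernlab::predict(state$kp, m), wavenumbers = NULL)),

    fast_ica = list(
      rowwise = FALSE,
      params = list(n_components = list(default = 10)),
      fit = function(step, m, wn, seed) {
        nc <- min(step$params$n_components, nrow(m) - 1, ncol(m))
        if (nc < 1) illcond("fast_ica: not enough rows")
        fastica_fit(m, nc, seed)
      },
      transform = function(state, step, m, wn)
        list(m = sweep(m, 2, state$center) %*% state$proj,
             wavenumbers = NULL)),

    lle = list(
      rowwise = FALSE,
      params = list(n_components = list(default = 10),
                    n_neighbors = list(default = 5)),
      fit = function(step, m, wn, seed) {
        nc <- min(step$params$n_components, nrow(m) - 2)
        k <- min(step$params$n_neighbors, nrow(m) - 1)
        if (nc < 1 || k < 1) illcond("lle: not enough rows")
        lle_fit(m, nc, k)
      },
      transform = function(state, step, m, wn)
        list(m = lle_transform(state, m), wavenumbers = NULL))
  )
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

# --- fit / transform surface ------------------------------------------------

#' Fit a preprocessing step on training spectra
#'
#' Row-wise steps return empty state; fitted steps learn their statistics
#' (scatter reference, column means/scales, projection bases) from the
#' training rows only.
#'
#' @param step a [preproc_step()].
#' @param train a `spectra_set` of training rows.
#' @param seed integer seed for randomized decompositions.
#' @return An object of class `fitted_step`.
#' @export
fit_step <- function(step, train, seed = 0L) {
  stopifnot(inherits(step, "preproc_step"))
  if (n_spectra(train) < 1) stop("cannot fit a step on an empty training set")
  def <- step_registry()[[step$name]]
  state <- if (is.null(def$fit)) list()
           else def$fit(step, train$absorbance, train$wavenumbers, seed)
  structure(list(step = step, state = state,
                 n_features = ncol(train$absorbance)),
            class = "fitted_step")
}

#' Apply a fitted preprocessing step
#'
#' Applies the step using only the state learned at fit time; the input
#' is never used to re-estimate state.  Dimensionality reductions change
#' the number of columns and blank the wavenumber axis.
#'
#' @param f a `fitted_step` from [fit_step()].
#' @param s a `spectra_set` with the same feature axis the step was
#'   fitted on.
#' @return The transformed `spectra_set`.
#' @export
transform_step <- function(f, s) {
  stopifnot(inherits(f, "fitted_step"))
  if (ncol(s$absorbance) != f$n_features)
    stop("feature axis mismatch between fitted step and input")
  def <- step_registry()[[f$step$name]]
  out <- def$transform(f$state, f$step, s$absorbance, s$wavenumbers)
  if (!all(is.finite(out$m)))
    illcond(paste0(f$step$name, ": non-finite transform output"))
  replace_matrix(s, out$m, out$wavenumbers)
}

# --- FastICA (logcosh, symmetric decorrelation) -----------------------------

fastica_fit <- function(m, nc, seed, max_iter = 200, tol = 1e-6) {
  center <- colMeans(m)
  xc <- sweep(m, 2, center)
  cv <- stats::cov(xc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (sum(pos) < nc) illcond("fast_ica: rank-deficient whitening")
  K <- eg$vectors[, seq_len(nc), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(nc)]), nc)
  z <- xc %*% K                      # whitened, n x nc
  W <- with_seed(seed, matrix(stats::rnorm(nc * nc), nc))
  sym_decor <- function(W) {
    sv <- La.svd(W)
    sv$u %*% sv$vt
  }
  W <- sym_decor(W)
  n <- nrow(z)
  for (it in seq_len(max_iter)) {
    wz <- z %*% t(W)
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- t(g) %*% z / n - diag(colMeans(gp), nc) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(center = center, proj = K %*% t(W))
}

# --- Locally linear embedding ----------------------------------------------

lle_weights <- function(x, nb, reg = 1e-3) {
  Z <- sweep(nb, 2, x)
  G <- Z %*% t(Z)
  G <- G + diag(nrow(G)) * reg * sum(diag(G)) / nrow(G)
  w <- solve(G, rep(1, nrow(G)))
  w / sum(w)
}

lle_fit <- function(m, nc, k) {
  n <- nrow(m)
  d2 <- as.matrix(stats::dist(m))^2
  W <- matrix(0, n, n)
  nbrs <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    nbrs[i, ] <- nb
    W[i, nb] <- lle_weights(m[i, ], m[nb, , drop = FALSE])
  }
  M <- crossprod(diag(n) - W)
  eg <- eigen(M, symmetric = TRUE)
  idx <- order(eg$values)[2:(nc + 1)]
  list(train = m, embedding = eg$vectors[, idx, drop = FALSE] * sqrt(n),
       k = k)
}

lle_transform <- function(state, m) {
  out <- matrix(0, nrow(m), ncol(state$embedding))
  for (i in seq_len(nrow(m))) {
    d2 <- colSums((t(state$train) - m[i, ])^2)
    nb <- order(d2)[seq_len(state$k)]
    w <- lle_weights(m[i, ], state$train[nb, , drop = FALSE])
    out[i, ] <- as.numeric(w %*% state$embedding[nb, , drop = FALSE])
  }
  out
}

# --- pipelines --------------------------------------------------------------

#' Fit an ordered preprocessing pipeline
#'
#' Fits each step on the (progressively transformed) training rows, in
#' order, so every step's state derives from training data only.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]) or list of
#'   [preproc_step()]s.
#' @param train training `spectra_set`.
#' @param seed integer seed for randomized steps.
#' @return An object of class `fitted_pipeline`.
#' @export
fit_pipeline <- function(config, train, seed = 0L) {
  steps <- if (inherits(config, "pipeline_config")) config$steps else config
  fitted <- vector("list", length(steps))
  cur <- train
  for (i in seq_along(steps)) {
    fitted[[i]] <- fit_step(steps[[i]], cur, seed = seed + i)
    cur <- transform_step(fitted[[i]], cur)
  }
  structure(list(fitted = fitted, train_out = cur),
            class = "fitted_pipeline")
}

#' Apply a fitted preprocessing pipeline
#' @param fp a `fitted_pipeline`.
#' @param s a `spectra_set`.
#' @return The transformed `spectra_set`.
#' @export
transform_pipeline <- function(fp, s) {
  for (f in fp$fitted) s <- transform_step(f, s)
  s
}
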