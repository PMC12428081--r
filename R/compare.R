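# Fold-level paired statistical comparison of preprocessing conditions:
# Shapiro-Wilk normality gate choosing between a paired t-test and the
# Wilcoxon signed-rank test, Bonferroni family-wise control, Cohen's d
# for paired differences, and a 95% t-interval on the mean difference.

#' Paired Cohen's d
#'
#' `mean(diff) / sd(diff)` with the sample (n-1) standard deviation.
#' Negative values mean the first (optimized) condition had the lower
#' RMSE.
#'
#' @param diff vector of paired differences (length >= 2).
#' @return Scalar effect size.
#' @export
cohens_d_paired <- function(diff) {
  if (length(diff) < 2) stop("need at least 2 paired differences")
  s <- stats::sd(diff)
  if (s == 0) stop("zero-variance differences: effect size undefined")
  mean(diff) / s
}

#' Paired comparison of two fold-level RMSE vectors
#'
#' Computes `diff = a - b`, gates on Shapiro-Wilk normality of the
#' differences (p > 0.05 selects the paired t-test, otherwise the
#' Wilcoxon signed-rank test; the exact Wilcoxon null is used for
#' n <= 25 without ties, the continuity-corrected normal approximation
#' above), and reports the two-sided p-value, paired Cohen's d and the
#' 95% t confidence interval for the mean difference.
#'
#' @param a fold RMSEs of the optimized condition.
#' @param b fold RMSEs of the baseline condition, paired by fold.
#' @param alpha significance level (default 0.05).
#' @return An object of class `comparison_result` (uncorrected fields).
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("fold vectors must have equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 paired folds")
  diff <- a - b
  constant <- stats::sd(diff) == 0
  if (constant) {
    # identical conditions: no evidence against H0 by construction
    shapiro_p <- NA_real_
    test_used <- "paired_t"
    p_raw <- 1
    d <- 0
    ci <- c(mean(diff), mean(diff))
  } else {
    shapiro_p <- stats::shapiro.test(diff)$p.value
    if (shapiro_p > 0.05) {
      test_used <- "paired_t"
      p_raw <- stats::t.test(diff)$p.value
    } else {
      test_used <- "wilcoxon"
      has_ties <- anyDuplicated(abs(diff)) > 0 || any(diff == 0)
      p_raw <- if (n <= 25 && !has_ties)
        stats::wilcox.test(diff, exact = TRUE)$p.value
      else suppressWarnings(
        stats::wilcox.test(diff, exact = FALSE, correct = TRUE)$p.value)
    }
    d <- cohens_d_paired(diff)
    half <- stats::qt(0.975, n - 1) * stats::sd(diff) / sqrt(n)
    ci <- mean(diff) + c(-half, half)
  }
  structure(list(n = n, mean_diff = mean(diff), cohen_d = d,
                 test_used = test_used, shapiro_p = shapiro_p,
                 p_raw = p_raw, ci95 = ci, alpha = alpha,
                 sig_raw = p_raw < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired %s over %d folds: mean diff %.4g, d = %.3g, p = %.4g%s\n",
              x$test_used, x$n, x$mean_diff, x$cohen_d, x$p_raw,
              if (!is.null(x$p_corrected))
                sprintf(" (corrected %.4g)", x$p_corrected) else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * K)` elementwise, with `K` the family size.
#'
#' @param p_raw vector of raw p-values.
#' @param K family size (>= `length(p_raw)`).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_raw, K) {
  if (K < 1) stop("family size K must be >= 1")
  if (K < length(p_raw)) stop("K must be at least the number of p-values")
  pmin(1, p_raw * K)
}

#' Comparison matrix over models x components x baselines
#'
#' One paired comparison per (model, component, baseline), corrected
#' with the Bonferroni family size equal to the number of comparisons
#' run (unless overridden).
#'
#' @param fold_rmse data frame with columns `model`, `component`,
#'   `condition`, `fold`, `rmse`; the optimized condition is named in
#'   `optimized_label`.
#' @param models,components,baselines character vectors defining the
#'   comparison family.
#' @param optimized_label condition label of the optimized pipeline
#'   (default `"optimized"`).
#' @param alpha corrected significance level (default 0.05).
#' @param family_size override for the Bonferroni K (default: number of
#'   comparisons).
#' @return Data frame of class `comparison_matrix`, one row per
#'   comparison with effect size, raw/corrected p-values, confidence
#'   interval and significance flags.
#' @export
comparison_matrix <- function(fold_rmse, models, components, baselines,
                              optimized_label = "optimized", alpha = 0.05,
                              family_size = NULL) {
  if (!length(baselines))
    return(structure(data.frame(), class = c("comparison_matrix",
                                             "data.frame")))
  need <- c("model", "component", "condition", "fold", "rmse")
  miss <- setdiff(need, names(fold_rmse))
  if (length(miss))
    stop("fold_rmse lacks column(s): ", paste(miss, collapse = ", "))
  get_cell <- function(m, comp, cond) {
    v <- fold_rmse[fold_rmse$model == m & fold_rmse$component == comp &
                     fold_rmse$condition == cond, ]
    if (!nrow(v))
      stop(sprintf("missing fold RMSEs for (%s, %s, %s)", m, comp, cond))
    v$rmse[order(v$fold)]
  }
  rows <- list()
  for (m in models) for (comp in components) for (bl in baselines) {
    a <- get_cell(m, comp, optimized_label)
    b <- get_cell(m, comp, bl)
    cr <- paired_compare(a, b, alpha)
    rows[[length(rows) + 1]] <-
      data.frame(model = m, component = comp, baseline = bl, n = cr$n,
                 mean_diff = cr$mean_diff, cohen_d = cr$cohen_d,
                 test_used = cr$test_used, shapiro_p = cr$shapiro_p,
                 p_raw = cr$p_raw, ci_lo = cr$ci95[1], ci_hi = cr$ci95[2],
                 sig_raw = cr$sig_raw, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  K <- family_size %||% nrow(out)
  out$p_corrected <- bonferroni(out$p_raw, K)
  out$sig_corrected <- out$p_corrected < alpha
  rownames(out) <- NULL
  class(out) <- c("comparison_matrix", "data.frame")
  out
}

#' Boxplot of fold RMSE distributions per condition
#'
#' @param fold_rmse data frame as in [comparison_matrix()].
#' @param component component to plot.
#' @param model model to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_fold_rmse <- function(fold_rmse, component, model, ...) {
  sub <- fold_rmse[fold_rmse$component == component &
                     fold_rmse$model == model, ]
  graphics::boxplot(rmse ~ condition, data = sub,
                    main = sprintf("%s (%s)", component, model),
                    ylab = "fold RMSE", xlab = "", ...)
  invisible(NULL)
}
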