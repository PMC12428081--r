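# Replicate-aware sample partitioning and group-aware cross-validation.
# Replicate measurements share a group id; every splitter here keeps all
# rows of a group on one side, which is what prevents the silent leakage
# that inflates apparent accuracy when replicates straddle the divide.

#' Group centroids of a spectra set
#'
#' One centroid per unique group (mean of its rows), in first-appearance
#' order.
#'
#' @param s a `spectra_set`.
#' @return List with `groups` (character) and `centroids` (matrix, one
#'   row per group).
#' @export
aggregate_group_centroids <- function(s) {
  groups <- unique(s$group_ids)
  idx <- split(seq_along(s$group_ids),
               factor(s$group_ids, levels = groups))
  p <- ncol(s$absorbance)
  centroids <- matrix(vapply(idx, function(i)
    colMeans(s$absorbance[i, , drop = FALSE]), numeric(p)),
    ncol = p, byrow = TRUE)
  list(groups = groups, centroids = centroids)
}

#' Replicate-aware Kennard-Stone partitioning
#'
#' Classical Kennard-Stone run on group centroids: replicates of each
#' group are averaged to a centroid, the training side is seeded with the
#' centroid pair at maximum Euclidean distance, then grown greedily by
#' max-min distance until it holds `round((1 - p) * n_groups)` groups
#' (rounding half away from zero); finally all replicate rows are mapped
#' back to their group's side.  Fully deterministic; distance ties are
#' broken towards the smallest group index in first-appearance order.
#'
#' @param s a `spectra_set`.
#' @param p test proportion in (0, 1).
#' @return An object of class `split_result` with row indices and group
#'   sets for both sides.
#' @export
kennard_stone_r <- function(s, p) {
  if (!(p > 0 && p < 1)) stop("test proportion p must be in (0, 1)")
  agg <- aggregate_group_centroids(s)
  ng <- length(agg$groups)
  if (ng < 2) stop("need at least 2 unique groups to split")
  m <- round_half_up((1 - p) * ng)
  if (m < 2)
    stop("fewer than 2 training groups after rounding; ",
         "use a smaller p or more groups")
  if (m >= ng)
    stop("no groups left for testing; use a larger p")

  D <- as.matrix(stats::dist(agg$centroids))
  # seed: pair at maximum distance, ties to smallest (i, j)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  selected <- best
  dmin <- pmin(D[, best[1]], D[, best[2]])
  dmin[selected] <- -Inf
  while (length(selected) < m) {
    nxt <- which.max(dmin)          # ties -> smallest index
    selected <- c(selected, nxt)
    dmin <- pmin(dmin, D[, nxt])
    dmin[nxt] <- -Inf
  }
  train_groups <- agg$groups[sort(selected)]
  test_groups <- setdiff(agg$groups, train_groups)
  train_rows <- which(s$group_ids %in% train_groups)
  test_rows <- which(s$group_ids %in% test_groups)
  structure(list(train_row_indices = train_rows,
                 test_row_indices = test_rows,
                 train_groups = train_groups, test_groups = test_groups,
                 p = p),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> p = %g: %d train groups (%d rows), %d test groups (%d rows)\n",
              x$p, length(x$train_groups), length(x$train_row_indices),
              length(x$test_groups), length(x$test_row_indices)))
  invisible(x)
}

#' Group-shuffle-split cross-validation folds
#'
#' Randomly assigns whole groups to a validation side of size
#' `round(test_frac * n_groups)` (at least one group each side),
#' `n_splits` times.  Reproducible under a fixed seed.
#'
#' @param s a `spectra_set`.
#' @param n_splits number of random splits.
#' @param test_frac fraction of groups per validation side.
#' @param seed integer seed.
#' @return List of `list(train = row indices, validation = row indices)`.
#' @export
group_shuffle_split <- function(s, n_splits = 5, test_frac = 0.25,
                                seed = 0L) {
  groups <- unique(s$group_ids)
  ng <- length(groups)
  if (ng < 2) stop("need at least 2 groups")
  n_test <- round_half_up(test_frac * ng)
  if (n_test < 1 || n_test >= ng)
    stop("test_frac leaves an empty side")
  with_seed(seed, lapply(seq_len(n_splits), function(k) {
    test_g <- sample(groups, n_test)
    list(train = which(!s$group_ids %in% test_g),
         validation = which(s$group_ids %in% test_g))
  }))
}

#' Leave-P-groups-out cross-validation folds
#'
#' Enumerates all `choose(n_groups, p_groups)` combinations of held-out
#' groups.
#'
#' @param s a `spectra_set`.
#' @param p_groups number of groups per validation fold.
#' @param max_folds refuse to enumerate more than this many combinations
#'   (default 10000); use [group_shuffle_split()] beyond that.
#' @return List of `list(train, validation)` row-index pairs.
#' @export
leave_p_groups_out <- function(s, p_groups = 1, max_folds = 10000) {
  groups <- unique(s$group_ids)
  ng <- length(groups)
  if (p_groups < 1 || p_groups >= ng)
    stop("p_groups must be in [1, n_groups)")
  nf <- choose(ng, p_groups)
  if (nf > max_folds)
    stop(sprintf("%d folds exceed the cap (%d); use group_shuffle_split",
                 nf, max_folds))
  combos <- utils::combn(groups, p_groups, simplify = FALSE)
  lapply(combos, function(test_g)
    list(train = which(!s$group_ids %in% test_g),
         validation = which(s$group_ids %in% test_g)))
}
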