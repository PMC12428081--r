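test_that("group centroids are means in first-appearance order", {
  s <- spectra_set(rbind(c(0, 2), c(2, 0), c(5, 5)), c(2, 1),
                   c("A_1", "A_2", "B_1"))
  agg <- aggregate_group_centroids(s)
  expect_equal(agg$groups, c("A", "B"))
  expect_equal(unname(agg$centroids[1, ]), c(1, 1))

  # singleton groups: centroids equal the rows
  s2 <- singleton_spectra(5, 4)
  agg2 <- aggregate_group_centroids(s2)
  expect_equal(unname(agg2$centroids), unname(s2$absorbance))
})

test_that("Kennard-StoneR seeds with the extreme pair and grows by max-min distance", {
  # 1-D centroids {0, 1, 10}: max-distance pair is (0, 10)
  s <- spectra_set(matrix(c(0, 1, 10)), NULL, c("a", "b", "c"))
  sr <- kennard_stone_r(s, 0.34)   # m = round(0.66 * 3) = 2
  expect_setequal(sr$train_groups, c("a", "c"))
  expect_equal(sr$test_groups, "b")

  # square corners: all diagonals tie; smallest-index pair wins
  sq <- spectra_set(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), NULL,
                    c("g1", "g2", "g3", "g4"))
  sr2 <- kennard_stone_r(sq, 0.5)
  expect_setequal(sr2$train_groups, c("g1", "g3"))

  # all replicate rows land on their group's side
  s3 <- toy_spectra(8, 3, 10, seed = 2)
  sr3 <- kennard_stone_r(s3, 0.25)
  expect_length(intersect(sr3$train_groups, sr3$test_groups), 0)
  expect_setequal(c(sr3$train_row_indices, sr3$test_row_indices),
                  seq_len(n_spectra(s3)))
  expect_setequal(unique(s3$group_ids[sr3$train_row_indices]),
                  sr3$train_groups)

  # deterministic: no RNG involved
  expect_identical(kennard_stone_r(s3, 0.25), sr3)

  expect_error(kennard_stone_r(s, 0), "in \\(0, 1\\)")
  expect_error(kennard_stone_r(s, 0.99), "smaller p|fewer than 2")
})

test_that("Kennard-StoneR on singleton groups equals classical Kennard-Stone", {
  # direct sample-level implementation as the oracle
  classical_ks <- function(m, n_train) {
    D <- as.matrix(dist(m))
    sel <- as.integer(arrayInd(which.max(D), dim(D)))
    sel <- sort(sel)[1:2]
    pair <- which(D == max(D), arr.ind = TRUE)
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    sel <- sort(unname(pair[1, ]))
    while (length(sel) < n_train) {
      dmin <- apply(D[, sel, drop = FALSE], 1, min)
      dmin[sel] <- -Inf
      sel <- c(sel, which.max(dmin))
    }
    sort(sel)
  }
  set.seed(21)
  for (i in 1:5) {
    s <- singleton_spectra(12, 6, seed = i)
    sr <- kennard_stone_r(s, 0.3)
    m <- round(0.7 * 12)
    oracle <- unname(classical_ks(s$absorbance, m))
    expect_equal(sort(match(sr$train_groups, s$group_ids)), oracle)
  }
})

test_that("training group count grows monotonically as p shrinks", {
  s <- singleton_spectra(20, 5, seed = 3)
  ps <- c(0.8, 0.6, 0.4, 0.2, 0.1)
  ms <- vapply(ps, function(p)
    length(kennard_stone_r(s, p)$train_groups), numeric(1))
  expect_true(all(diff(ms) >= 0))
})

test_that("group-shuffle-split keeps groups disjoint and is seed-reproducible", {
  s <- singleton_spectra(10, 4, seed = 4)
  folds <- group_shuffle_split(s, n_splits = 5, test_frac = 0.3, seed = 7)
  expect_length(folds, 5)
  for (fd in folds) {
    expect_length(fd$validation, 3)         # round(10 * 0.3)
    expect_length(intersect(s$group_ids[fd$train],
                            s$group_ids[fd$validation]), 0)
    expect_setequal(c(fd$train, fd$validation), seq_len(10))
  }
  expect_identical(folds, group_shuffle_split(s, 5, 0.3, seed = 7))
  expect_false(identical(folds, group_shuffle_split(s, 5, 0.3, seed = 8)))
  expect_error(group_shuffle_split(s, 5, 0.01), "empty side")
})

test_that("leave-P-groups-out enumerates all combinations", {
  s <- toy_spectra(4, 2, 6, seed = 5)
  expect_length(leave_p_groups_out(s, 1), 4)   # C(4,1)
  folds <- leave_p_groups_out(s, 2)
  expect_length(folds, 6)                       # C(4,2)
  for (fd in folds)
    expect_length(intersect(s$group_ids[fd$train],
                            s$group_ids[fd$validation]), 0)
  expect_error(leave_p_groups_out(s, 4), "n_groups")
  big <- singleton_spectra(30, 3, seed = 6)
  expect_error(leave_p_groups_out(big, 15), "group_shuffle_split")
})
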