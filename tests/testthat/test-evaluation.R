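test_that("rmse and R^2 match their definitions", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(1, 3), 2)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")

  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 0)), -1.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("the ridge solver matches penalized least squares", {
  set.seed(31)
  X <- matrix(rnorm(200), 20, 10)
  y <- X %*% rnorm(10) + rnorm(20, 0, 0.1)
  a <- 2.5
  fit <- specopt:::ridge_fit(X, y, a)
  # oracle: centered closed form
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc) + diag(a, 10), crossprod(Xc, y - mean(y)))
  expect_equal(fit$beta, as.numeric(beta), tolerance = 1e-10)
  expect_equal(specopt:::ridge_predict(fit, X),
               as.numeric(Xc %*% beta + mean(y)), tolerance = 1e-10)
})

test_that("a realizable linear target scores near zero and the score is exactly -RMSE", {
  cfg <- sim_config(n_groups = 24, n_points = 80, seed = 11)
  cfg <- apply_corruption_preset(cfg, "none")
  sim <- simulate_dataset(cfg)
  sp <- enumerate_pipelines("meancn", 1, unit_grids = TRUE)
  cv <- cv_strategy(seed = 5)
  score <- objective_evaluate(c(0, -6), sp, sim$spectra, "fat", cv = cv)
  expect_gt(score, -1e-3)

  res <- evaluate_pipeline_cv(sp$configs[[1]], 1e-6, sim$spectra, "fat", cv)
  expect_equal(score, -res$rmse)
  expect_equal(res$status, "ok")
  expect_length(res$per_fold_rmse, 5)
  expect_true(all(res$per_fold_rmse >= 0))
})

test_that("ill-conditioned configurations earn the penalty, not an error", {
  s <- toy_spectra(6, 2, 15, seed = 12)
  s$absorbance[1, ] <- 2            # one constant spectrum breaks SNV
  sp <- enumerate_pipelines("snv", 1, unit_grids = TRUE)
  score <- objective_evaluate(c(0, 0), sp, s, "y",
                              cv = cv_strategy(n_splits = 3, seed = 2))
  expect_equal(score, PENALTY_SCORE)
  expect_lt(PENALTY_SCORE, -1e5)    # dominates any achievable -RMSE
})

test_that("the external-test branch is gated and ignores the CV argument when enabled", {
  sim <- simulate_dataset(sim_config(n_groups = 16, n_points = 60, seed = 13))
  sr <- kennard_stone_r(sim$spectra, 0.3)
  train <- specopt:::subset_rows(sim$spectra, sr$train_row_indices)
  test <- specopt:::subset_rows(sim$spectra, sr$test_row_indices)
  sp <- enumerate_pipelines("meancn", 1, unit_grids = TRUE)

  expect_warning(
    s_cv <- objective_evaluate(c(0, 0), sp, train, "fat",
                               cv = cv_strategy(seed = 3), test = test),
    "allow_test")

  s_test1 <- objective_evaluate(c(0, 0), sp, train, "fat",
                                cv = cv_strategy(seed = 3), test = test,
                                allow_test = TRUE)
  s_test2 <- objective_evaluate(c(0, 0), sp, train, "fat",
                                cv = cv_strategy(seed = 99), test = test,
                                allow_test = TRUE)
  expect_identical(s_test1, s_test2)   # cv argument irrelevant on this branch
  expect_true(is.finite(s_cv) && is.finite(s_test1))
  expect_false(identical(s_cv, s_test1))
})

test_that("fold fitting never reads the validation side", {
  s <- toy_spectra(8, 2, 12, seed = 14)
  folds <- group_shuffle_split(s, 2, 0.25, seed = 4)
  fd <- folds[[1]]
  tr <- specopt:::subset_rows(s, fd$train)
  cfg <- pipeline_config(list(preproc_step("scaler")))
  f1 <- fit_pipeline(cfg, tr)

  # perturb the validation rows wildly; fitted state must be unchanged
  s2 <- s
  s2$absorbance[fd$validation, ] <- s2$absorbance[fd$validation, ] * 100 + 7
  f2 <- fit_pipeline(cfg, specopt:::subset_rows(s2, fd$train))
  expect_identical(f1$fitted[[1]]$state, f2$fitted[[1]]$state)

  per_fold_logged <- tempfile()
  sp <- enumerate_pipelines("scaler", 1, unit_grids = TRUE)
  objective_evaluate(c(0, 0), sp, s, "y", cv = cv_strategy(seed = 4),
                     log_file = per_fold_logged)
  log_line <- jsonlite::fromJSON(readLines(per_fold_logged)[1])
  expect_equal(log_line$status, "ok")
  expect_length(log_line$per_fold_rmse, 5)
})
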