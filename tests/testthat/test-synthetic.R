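test_that("the default wavenumber grid matches the MIR acquisition geometry", {
  cfg <- sim_config(seed = 1)
  grid <- specopt:::sim_grid(cfg)
  expect_length(grid, 1060)
  expect_equal(grid[1], 4999.99)
  expect_equal(grid[1060], 925.07)
  expect_equal(abs(mean(diff(grid))), (4999.99 - 925.07) / 1059)
})

test_that("sampled concentrations reproduce the component statistics", {
  cfg <- sim_config(seed = 2)
  conc <- sample_concentrations(cfg, 1e4)
  tab <- component_table()
  # fat and total solids sit close to their upper table bound, so range
  # truncation biases their means slightly low; protein and lactose are
  # far from their bounds and must match to Monte Carlo error
  tol <- 3 * tab$sd / sqrt(1e4) + c(0.03, 0, 0, 0.06)
  for (i in seq_len(4)) {
    expect_lt(abs(mean(conc[[i]]) - tab$mean[i]), tol[i])
    expect_true(all(conc[[i]] >= tab$min[i] & conc[[i]] <= tab$max[i]))
  }
  # residual-solids offset: total solids mean minus the three components
  expect_equal(cfg$ts_offset,
               round(16.1490 - (5.5679 + 4.7644 + 4.5607), 4))

  # correlation structure: fat/TS strong positive, protein/lactose negative
  expect_lt(abs(cor(conc$fat, conc$total_solids) - 0.88), 0.05)
  expect_lt(cor(conc$protein, conc$lactose), -0.4)

  expect_error(
    sim_config(correlations = c(fat_protein = 0.9,
                                protein_lactose = 0.9,
                                fat_lactose = -0.9)),
    "positive semi-definite")
})

test_that("pure component spectra peak at their assigned bands", {
  grid <- specopt:::sim_grid(sim_config())
  fat <- component_spectrum("fat", grid)
  step <- abs(grid[2] - grid[1])
  expect_lt(abs(grid[which.max(fat)] - 2922), step + 1e-9)
  expect_equal(max(fat), 1)

  lactose <- component_spectrum("lactose", grid)
  expect_lt(max(lactose[grid > 2000]), 1e-6)

  expect_identical(component_spectrum("protein", grid),
                   component_spectrum("protein", grid))
  expect_error(component_spectrum("caffeine", grid), "unknown")
})

test_that("simulation is bit-stable under a fixed seed and replicates differ only by corruption", {
  cfg <- sim_config(n_groups = 10, n_points = 80, seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$spectra$absorbance, s2$spectra$absorbance)
  expect_identical(s1$concentrations, s2$concentrations)

  clean_cfg <- apply_corruption_preset(cfg, "none")
  s3 <- simulate_dataset(clean_cfg)
  reps <- which(s3$spectra$group_ids == s3$spectra$group_ids[1])
  if (length(reps) > 1)
    expect_equal(s3$spectra$absorbance[reps[1], ],
                 s3$spectra$absorbance[reps[2], ])
})

test_that("clean mixtures are an exactly realizable linear system", {
  cfg <- apply_corruption_preset(
    sim_config(n_groups = 30, n_points = 100, seed = 7), "none")
  sim <- simulate_dataset(cfg)
  # group rows equal the clean mixture matrix
  first_rows <- match(unique(sim$spectra$group_ids), sim$spectra$group_ids)
  expect_equal(unname(sim$spectra$absorbance[first_rows, ]),
               unname(sim$clean), tolerance = 1e-12)

  # ridge on raw spectra recovers the targets essentially exactly
  fit <- specopt:::ridge_fit(sim$spectra$absorbance,
                             sim$spectra$targets$fat, 1e-10)
  pred <- specopt:::ridge_predict(fit, sim$spectra$absorbance)
  rng <- diff(range(sim$spectra$targets$fat))
  expect_lt(rmse(sim$spectra$targets$fat, pred), 1e-6 * rng)
})

test_that("the planted-scatter benchmark is won by a scatter-correcting pipeline", {
  bench <- planted_scatter_benchmark(n_groups = 30, n_points = 100,
                                     seed = 19)
  sp <- enumerate_pipelines(c("snv", "msc", "scaler", "meancn"),
                            c(1, 2), unit_grids = TRUE)
  cv <- cv_strategy(n_splits = 3, seed = 11)
  scores <- vapply(seq_along(sp$configs) - 1, function(i)
    objective_evaluate(c(i + 0.5, -4), sp, bench$spectra, "fat", cv = cv),
    numeric(1))
  winner <- sp$configs[[which.max(scores)]]
  nms <- vapply(winner$steps, `[[`, character(1), "name")
  expect_true(any(nms %in% c("snv", "msc", "emsc", "lsnv", "rnv")))
})
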