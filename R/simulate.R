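# Synthetic milk MIR spectra with known ground truth.  Beer-Lambert
# linear mixing of Gaussian component bands at the canonical milk band
# positions, a broad shared water/background continuum, and per-replicate
# corruption (multiplicative scatter, additive polynomial baseline,
# i.i.d. noise) so that scatter-correction and baseline operators have
# something real to remove.

#' Default milk component statistics
#'
#' Means, standard deviations and ranges (% w/w) of fat, protein,
#' lactose and total solids used by the concentration sampler.
#'
#' @return Data frame with columns `component`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
component_table <- function() {
  data.frame(
    component = c("fat", "protein", "lactose", "total_solids"),
    mean = c(5.5679, 4.7644, 4.5607, 16.1490),
    sd = c(0.8178, 0.5065, 0.1152, 1.1442),
    min = c(3.0700, 3.1900, 4.0900, 12.1100),
    max = c(6.7750, 6.5960, 4.9517, 17.5600),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_groups number of unique sample groups.
#' @param replicates_per_group integer range `c(lo, hi)`; each group
#'   draws its replicate count uniformly from it.
#' @param wn_start,wn_end,n_points wavenumber grid (defaults: 1060 points
#'   from 4999.99 down to 925.07 cm^-1, ~4 cm^-1 steps).
#' @param correlations correlations among (fat, protein), (protein,
#'   lactose), (fat, lactose).  Defaults 0.38, -0.58 and 0 (the last is
#'   an undocumented assumption of the generator).
#' @param ts_offset residual-solids offset added to fat + protein +
#'   lactose so total solids has the right mean (default 1.2560).
#' @param ts_noise_sd sd of the total-solids residual term; the default
#'   0.36 reproduces both the total-solids spread (~1.14) and the
#'   fat/total-solids correlation (~0.88).
#' @param scatter_slope_sd,scatter_offset_sd per-replicate multiplicative
#'   scatter: gain ~ N(1, slope_sd), offset ~ N(0, offset_sd).
#' @param baseline_order,baseline_amp per-replicate additive polynomial
#'   baseline (order and coefficient scale, absorbance units).
#' @param noise_sd i.i.d. absorbance noise.
#' @param band_scale absorbance per % w/w at unit band height.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_groups = 40, replicates_per_group = c(1, 3),
                       wn_start = 4999.99, wn_end = 925.07,
                       n_points = 1060,
                       correlations = c(fat_protein = 0.38,
                                        protein_lactose = -0.58,
                                        fat_lactose = 0),
                       ts_offset = 1.2560, ts_noise_sd = 0.36,
                       scatter_slope_sd = 0.05, scatter_offset_sd = 0.02,
                       baseline_order = 2, baseline_amp = 0.01,
                       noise_sd = 0.002, band_scale = 0.05, seed = 1L) {
  stopifnot(n_groups >= 2, n_points >= 2,
            scatter_slope_sd >= 0, scatter_offset_sd >= 0,
            baseline_amp >= 0, noise_sd >= 0, ts_noise_sd >= 0)
  cfg <- list(n_groups = n_groups,
              replicates_per_group = as.integer(replicates_per_group),
              wn_start = wn_start, wn_end = wn_end, n_points = n_points,
              correlations = correlations, ts_offset = ts_offset,
              ts_noise_sd = ts_noise_sd,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              baseline_order = baseline_order, baseline_amp = baseline_amp,
              noise_sd = noise_sd, band_scale = band_scale,
              seed = as.integer(seed))
  # validate the implied concentration correlation matrix once
  conc_cov(cfg)
  structure(cfg, class = "sim_config")
}

#' Corruption presets for the simulator
#'
#' `"none"` — clean mixtures; `"scatter"` — strong multiplicative
#' scatter only (the planted benchmark where scatter correction must
#' win); `"baseline"` — additive polynomial drift only; `"full"` — the
#' default mixture of both plus noise.
#'
#' @param cfg a [sim_config()].
#' @param preset one of `"none"`, `"scatter"`, `"baseline"`, `"full"`.
#' @return The modified `sim_config`.
#' @export
apply_corruption_preset <- function(cfg, preset = c("full", "none",
                                                    "scatter", "baseline")) {
  preset <- match.arg(preset)
  vals <- switch(preset,
    none = list(scatter_slope_sd = 0, scatter_offset_sd = 0,
                baseline_amp = 0, noise_sd = 0),
    scatter = list(scatter_slope_sd = 0.2, scatter_offset_sd = 0.1,
                   baseline_amp = 0, noise_sd = 0.002),
    baseline = list(scatter_slope_sd = 0, scatter_offset_sd = 0,
                    baseline_amp = 0.05, noise_sd = 0.002),
    full = list())
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  cfg
}

conc_cov <- function(cfg) {
  tab <- component_table()
  sds <- stats::setNames(tab$sd, tab$component)[1:3]
  r <- cfg$correlations
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- r[["fat_protein"]]
  C[2, 3] <- C[3, 2] <- r[["protein_lactose"]]
  C[1, 3] <- C[3, 1] <- r[["fat_lactose"]]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation matrix is not positive semi-definite")
  diag(sds) %*% C %*% diag(sds)
}

#' Sample milk component concentrations
#'
#' Fat, protein and lactose are drawn from a trivariate normal with the
#' [component_table()] means/sds and the configured correlations; total
#' solids = fat + protein + lactose + offset + noise.  All values are
#' clipped to the table's min/max range.
#'
#' @param cfg a [sim_config()].
#' @param n number of samples.
#' @param seed optional seed override.
#' @return Data frame with columns `fat`, `protein`, `lactose`,
#'   `total_solids`.
#' @export
sample_concentrations <- function(cfg, n, seed = cfg$seed) {
  tab <- component_table()
  mu <- stats::setNames(tab$mean, tab$component)
  Sigma <- conc_cov(cfg)
  with_seed(seed, {
    X <- MASS::mvrnorm(n, mu[1:3], Sigma)
    X <- matrix(X, nrow = n)
    ts <- rowSums(X) + cfg$ts_offset + stats::rnorm(n, 0, cfg$ts_noise_sd)
    out <- data.frame(fat = X[, 1], protein = X[, 2], lactose = X[, 3],
                      total_solids = ts)
    for (i in seq_len(4))
      out[[i]] <- pmin(pmax(out[[i]], tab$min[i]), tab$max[i])
    out
  })
}

# Band positions (cm^-1), relative heights and widths (sd, cm^-1) per
# component: methylene stretches and the ester carbonyl for fat, amide
# I/II for protein, the C-O carbohydrate band for lactose.
component_bands <- function(component) {
  switch(component,
    fat = list(center = c(2922, 2852, 1743),
               height = c(1.0, 0.72, 0.85), width = c(22, 22, 18)),
    protein = list(center = c(1635, 1548),
                   height = c(1.0, 0.78), width = c(28, 30)),
    lactose = list(center = 1077, height = 1.0, width = 30),
    stop("unknown component: ", component))
}

#' Pure component spectrum on a wavenumber grid
#'
#' Sum of Gaussian bands at the component's characteristic positions,
#' peak-height normalized to 1.  Deterministic.
#'
#' @param component `"fat"`, `"protein"` or `"lactose"`.
#' @param grid numeric wavenumber vector (cm^-1).
#' @return Numeric vector of the same length as `grid`.
#' @export
component_spectrum <- function(component, grid) {
  b <- component_bands(component)
  s <- numeric(length(grid))
  for (i in seq_along(b$center))
    s <- s + b$height[i] * exp(-0.5 * ((grid - b$center[i]) / b$width[i])^2)
  s / max(s)
}

sim_grid <- function(cfg) seq(cfg$wn_start, cfg$wn_end,
                              length.out = cfg$n_points)

# Broad shared water/background continuum: a gentle quadratic in the
# scaled axis, always positive.
background_spectrum <- function(grid) {
  u <- scaled_axis(length(grid))
  0.15 + 0.05 * u + 0.04 * u^2
}

#' Simulate a milk MIR dataset with known ground truth
#'
#' Each group draws component concentrations and a clean Beer-Lambert
#' mixture spectrum; each replicate then receives its own multiplicative
#' scatter, polynomial baseline and noise draws.  Bit-identical under a
#' fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `spectra` (a [spectra_set()] with targets), `clean`
#'   (group-level clean matrix), `concentrations` (group-level data
#'   frame), and `grid`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- sim_grid(cfg)
  pure <- sapply(c("fat", "protein", "lactose"), component_spectrum,
                 grid = grid)
  bg <- background_spectrum(grid)
  conc <- sample_concentrations(cfg, cfg$n_groups, seed = cfg$seed)

  with_seed(cfg$seed + 1L, {
    rep_range <- seq(cfg$replicates_per_group[1],
                     cfg$replicates_per_group[2])
    reps <- if (length(rep_range) == 1) rep(rep_range, cfg$n_groups)
            else sample(rep_range, cfg$n_groups, replace = TRUE)
    clean <- cfg$band_scale *
      (as.matrix(conc[, c("fat", "protein", "lactose")]) %*% t(pure))
    clean <- sweep(clean, 2, bg, "+")
    rows <- vector("list", sum(reps))
    ids <- character(sum(reps)); groups <- character(sum(reps))
    k <- 0
    u <- scaled_axis(length(grid))
    for (g in seq_len(cfg$n_groups)) {
      for (r in seq_len(reps[g])) {
        k <- k + 1
        slope <- stats::rnorm(1, 1, cfg$scatter_slope_sd)
        offset <- stats::rnorm(1, 0, cfg$scatter_offset_sd)
        base <- numeric(length(grid))
        if (cfg$baseline_amp > 0) {
          cf <- stats::rnorm(cfg$baseline_order + 1, 0, cfg$baseline_amp)
          base <- as.numeric(stats::poly(u, cfg$baseline_order,
                                         raw = TRUE, simple = TRUE) %*%
                               cf[-1]) + cf[1]
        }
        noise <- if (cfg$noise_sd > 0)
          stats::rnorm(length(grid), 0, cfg$noise_sd) else 0
        rows[[k]] <- offset + slope * clean[g, ] + base + noise
        groups[k] <- sprintf("G%03d", g)
        ids[k] <- sprintf("G%03d_%d", g, r)
      }
    }
    m <- do.call(rbind, rows)
    targets <- lapply(conc, function(v) rep(v, reps))
    sp <- spectra_set(m, grid, ids, groups, targets)
    list(spectra = sp, clean = clean, concentrations = conc, grid = grid)
  })
}

#' Planted-scatter benchmark dataset
#'
#' A small strongly scatter-corrupted dataset (no baseline) on which the
#' best cross-validated pipeline must contain a scatter-correction step;
#' used to validate optimizer recovery against exhaustive search.
#'
#' @param n_groups,n_points,seed size and seed controls.
#' @return As [simulate_dataset()].
#' @export
planted_scatter_benchmark <- function(n_groups = 40, n_points = 200,
                                      seed = 42L) {
  cfg <- sim_config(n_groups = n_groups, replicates_per_group = c(2, 2),
                    n_points = n_points, seed = seed)
  cfg <- apply_corruption_preset(cfg, "scatter")
  simulate_dataset(cfg)
}
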