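# Pipeline search space: ordered sequences of preprocessing steps under
# incompatibility constraints, crossed with discretized per-step parameter
# grids, plus the continuous ridge-regularization dimension explored by
# the optimizer.

#' Default incompatibility rules
#'
#' Three exclusive families — scatter correction (SNV, MSC, EMSC, LSNV,
#' RNV: applying more than one overcorrects), scaling/normalization, and
#' dimensionality reduction — plus two explicit pair bans (snv with
#' row_standardizer, autoscale with scaler) retained verbatim even though
#' the families already imply them.
#'
#' @return An object of class `incompatibility_rules`.
#' @export
default_rules <- function() {
  incompatibility_rules(
    exclusive_sets = list(
      scatter = c("snv", "msc", "emsc", "lsnv", "rnv"),
      scaling = c("scaler", "autoscale", "globalscaler", "normalization",
                  "robust_scaler", "minmax_scaler", "power_transformer",
                  "quantile_transformer", "row_standardizer"),
      dimred  = c("pca", "fast_ica", "kernel_pca", "lle")),
    pair_bans = list(c("snv", "row_standardizer"),
                     c("autoscale", "scaler")))
}

#' Construct incompatibility rules
#' @param exclusive_sets list of character vectors; at most one member of
#'   each set may appear in a pipeline.
#' @param pair_bans list of length-2 character vectors banned together.
#' @return An object of class `incompatibility_rules`.
#' @export
incompatibility_rules <- function(exclusive_sets = list(),
                                  pair_bans = list()) {
  known <- step_names()
  ref <- unique(c(unlist(exclusive_sets), unlist(pair_bans)))
  bad <- setdiff(ref, known)
  if (length(bad))
    stop("rules reference unknown step(s): ", paste(bad, collapse = ", "))
  structure(list(exclusive_sets = exclusive_sets, pair_bans = pair_bans),
            class = "incompatibility_rules")
}

#' Check step-name compatibility
#'
#' `TRUE` iff no exclusive set contributes two or more of the names and
#' no banned pair occurs.
#'
#' @param steps character vector of step names (order irrelevant here).
#' @param rules an `incompatibility_rules` (default [default_rules()]).
#' @return Logical scalar.
#' @export
is_compatible <- function(steps, rules = default_rules()) {
  unknown <- setdiff(steps, step_names())
  if (length(unknown))
    stop("unknown step name(s): ", paste(unknown, collapse = ", "))
  for (set in rules$exclusive_sets)
    if (sum(steps %in% set) >= 2) return(FALSE)
  for (ban in rules$pair_bans)
    if (all(ban %in% steps)) return(FALSE)
  TRUE
}

#' Construct a pipeline configuration
#' @param steps list of [preproc_step()]s, applied in order.
#' @param rules rules to validate against (default [default_rules()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(steps, rules = default_rules()) {
  if (inherits(steps, "preproc_step")) steps <- list(steps)
  nm <- vapply(steps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("pipeline repeats a step name")
  if (!is_compatible(nm, rules))
    stop("incompatible step combination: ", paste(nm, collapse = " -> "))
  structure(list(steps = steps), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(pipeline_label(x), "\n"); invisible(x)
}

#' Human-readable pipeline label
#' @param config a `pipeline_config`.
#' @return A string such as `"savgol(...) -> scaler(...)"`.
#' @export
pipeline_label <- function(config) {
  if (!length(config$steps)) return("<identity>")
  paste(vapply(config$steps, step_label, character(1)), collapse = " -> ")
}

# Default discrete parameter grid for one step: the cross product of the
# per-parameter grids the registry declares (parameters without a declared
# grid stay at their default).
step_param_grid <- function(name) {
  def <- step_registry()[[name]]
  grids <- lapply(def$params, function(p) {
    g <- p$grid
    if (is.null(g)) list(p$default) else as.list(g)
  })
  if (!length(grids)) return(list(list()))
  combos <- expand.grid(lapply(grids, seq_along))
  lapply(seq_len(nrow(combos)), function(i) {
    out <- lapply(seq_along(grids), function(j) grids[[j]][[combos[i, j]]])
    names(out) <- names(grids)
    out
  })
}

# Drop savgol combos violating deriv <= polyorder etc.
valid_param_combo <- function(name, params) {
  ok <- TRUE
  tryCatch(preproc_step(name, params = params), error = function(e) ok <<- FALSE)
  ok
}

#' Enumerate all valid preprocessing pipelines
#'
#' Generates every ordered, repetition-free sequence of candidate steps
#' whose length is in `allowed_lengths` and which passes the
#' incompatibility rules, crossed with the Cartesian product of each
#' step's discretized parameter grid.  Ordering is deterministic: by
#' length, then lexicographically in candidate order, then grid order.
#'
#' @param candidates character vector of step names.
#' @param allowed_lengths integer vector of allowed pipeline lengths,
#'   e.g. `c(1, 2)`.
#' @param rules an `incompatibility_rules`.
#' @param param_grids optional named list overriding the default per-step
#'   grids; each entry is a list of parameter lists.  `unit_grids = TRUE`
#'   is shorthand for default parameters only (one combo per step).
#' @param unit_grids if `TRUE`, ignore parameter grids and enumerate step
#'   identities only.
#' @param alpha_log10_bounds bounds of the ridge regularization exponent
#'   dimension (default `c(-6, 6)`).
#' @return An object of class `search_space` with elements `configs`
#'   (list of `pipeline_config`), `labels`, and `alpha_log10_bounds`.
#' @export
enumerate_pipelines <- function(candidates, allowed_lengths = c(1, 2),
                                rules = default_rules(),
                                param_grids = NULL, unit_grids = FALSE,
                                alpha_log10_bounds = c(-6, 6)) {
  if (!length(candidates)) stop("candidates must be non-empty")
  unknown <- setdiff(candidates, step_names())
  if (length(unknown))
    stop("unknown candidate step(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(candidates)) stop("duplicate candidate step names")
  allowed_lengths <- sort(unique(as.integer(allowed_lengths)))
  if (any(allowed_lengths < 1)) stop("allowed_lengths must be >= 1")

  grids <- lapply(stats::setNames(candidates, candidates), function(nm) {
    if (unit_grids) return(list(list()))
    g <- if (!is.null(param_grids) && !is.null(param_grids[[nm]]))
      param_grids[[nm]] else step_param_grid(nm)
    Filter(function(p) valid_param_combo(nm, p), g)
  })

  # ordered sequences, grown lexicographically in candidate order so the
  # final ordering is (length, lex by candidate index, grid order)
  sequences <- list()
  grow <- function(prefix, len) {
    if (length(prefix) == len) {
      if (is_compatible(prefix, rules))
        sequences[[length(sequences) + 1]] <<- prefix
      return(invisible())
    }
    for (nm in candidates) {
      if (nm %in% prefix) next
      # prune: violations are monotone in pipeline growth
      if (!is_compatible(c(prefix, nm), rules)) next
      grow(c(prefix, nm), len)
    }
  }
  for (len in allowed_lengths) grow(character(0), len)

  configs <- list()
  for (sq in sequences) {
    combo_grids <- grids[sq]
    if (any(vapply(combo_grids, length, integer(1)) == 0)) next
    idx <- expand.grid(rev(lapply(combo_grids, seq_along)))
    idx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      steps <- lapply(seq_along(sq), function(j)
        preproc_step(sq[j], params = combo_grids[[j]][[idx[i, j]]]))
      configs[[length(configs) + 1]] <- pipeline_config(steps, rules)
    }
  }
  if (!length(configs))
    stop("no valid pipeline satisfies the rules for these candidates")
  labels <- vapply(configs, pipeline_label, character(1))
  if (anyDuplicated(labels))
    stop("internal error: duplicate configurations enumerated")
  structure(list(configs = configs, labels = labels,
                 alpha_log10_bounds = as.numeric(alpha_log10_bounds)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d pipeline configurations, alpha 10^[%g, %g]\n",
              length(x$configs), x$alpha_log10_bounds[1],
              x$alpha_log10_bounds[2]))
  invisible(x)
}

#' Decode an optimizer vector into a pipeline and ridge strength
#'
#' `theta[1]` is a continuous index coordinate over `[0, n_configs)`
#' (floored, clamped to the last configuration at the upper bound);
#' `theta[2]` is the base-10 exponent of the ridge regularization
#' strength.
#'
#' @param theta numeric vector of length 2.
#' @param space a `search_space`.
#' @return List with `config`, `config_index` (1-based), and `alpha`.
#' @export
decode_theta <- function(theta, space) {
  if (length(theta) != 2 || !all(is.finite(theta)))
    stop("theta must be two finite coordinates")
  n <- length(space$configs)
  i <- floor(theta[1]) + 1
  i <- max(1, min(n, i))
  list(config = space$configs[[i]], config_index = i,
       alpha = 10^theta[2])
}

#' Bounds of the optimizer box for a search space
#' @param space a `search_space`.
#' @return List with `lower` and `upper` length-2 vectors.
#' @export
space_bounds <- function(space) {
  list(lower = c(0, space$alpha_log10_bounds[1]),
       upper = c(length(space$configs), space$alpha_log10_bounds[2]))
}
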