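#' @keywords internal
"_PACKAGE"

# Round half away from zero; base round() banker's rounding would make
# group counts platform/value dependent at exact .5 boundaries.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Signal that a configuration is numerically ill-conditioned (zero row
# variance under SNV, singular scatter regression, ...).  The evaluation
# objective catches this condition class and applies its penalty score;
# nothing is silently patched with epsilon floors.
illcond <- function(msg) {
  stop(structure(class = c("specopt_illcond", "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_illcond <- function(e) inherits(e, "specopt_illcond")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so seeded helpers compose.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
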