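# Shared fixture builders; everything is generated in code at test time.

# Tiny deterministic spectra set with replicate structure.
toy_spectra <- function(n_groups = 6, reps = 2, p = 20, seed = 1) {
  set.seed(seed)
  n <- n_groups * reps
  ids <- paste0(rep(sprintf("G%02d", seq_len(n_groups)), each = reps),
                "_", rep(seq_len(reps), n_groups))
  m <- matrix(rnorm(n * p), n, p)
  tg <- list(y = rnorm(n))
  spectra_set(m, seq(2000, 1000, length.out = p), ids, targets = tg)
}

# Random spectra set with singleton groups.
singleton_spectra <- function(n = 10, p = 8, seed = 1) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p), n, p), seq_len(p),
              sprintf("S%02d", seq_len(n)))
}

# Write a small spectra CSV and return its path.
write_toy_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# Raise the package's ill-conditioning condition from test objectives.
illcond_for_test <- function() specopt:::illcond("synthetic failure")

# Brute-force generate-and-filter oracle for pipeline enumeration over
# step identities: all ordered repetition-free sequences of the allowed
# lengths that pass the rule check.
oracle_sequences <- function(candidates, lengths, rules = default_rules()) {
  out <- list()
  recurse <- function(prefix, remaining, len) {
    if (length(prefix) == len) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (nm in remaining)
      recurse(c(prefix, nm), setdiff(remaining, nm), len)
  }
  for (len in lengths[lengths <= length(candidates)])
    recurse(character(0), candidates, len)
  Filter(function(sq) is_compatible(sq, rules), out)
}

seq_key <- function(sqs) sort(vapply(sqs, paste, character(1), collapse = ">"))

space_name_key <- function(space) {
  sort(vapply(space$configs, function(cf)
    paste(vapply(cf$steps, `[[`, character(1), "name"), collapse = ">"),
    character(1)))
}
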