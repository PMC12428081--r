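#' Spectra set container
#'
#' Bundles an absorbance matrix with its wavenumber axis, per-row sample
#' and group identifiers, and optional reference concentrations.  Rows are
#' individual measurements; replicate measurements of one physical sample
#' share a group identifier (e.g. rows `VAT15_1` and `VAT15_2` both belong
#' to group `VAT15`), which every splitter in this package respects.
#'
#' @param absorbance numeric matrix, rows = measurements, columns =
#'   spectral variables (unitless absorbance).
#' @param wavenumbers numeric vector of column positions in cm^-1, strictly
#'   monotonic (descending, as acquired, is the common case and is stored
#'   as given).  May be `NULL` after dimensionality reduction.
#' @param sample_ids character vector of per-row measurement labels.
#' @param group_ids character vector of per-row group labels; if `NULL`,
#'   derived from `sample_ids` by stripping a trailing `_<digits>`
#'   replicate suffix.
#' @param targets optional named list (or data.frame) of numeric vectors,
#'   one value per row, holding component concentrations in % w/w.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(absorbance, wavenumbers = NULL, sample_ids = NULL,
                        group_ids = NULL, targets = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (!all(is.finite(absorbance)))
    stop("absorbance values must all be finite")
  if (!is.null(wavenumbers)) {
    wavenumbers <- as.numeric(wavenumbers)
    if (length(wavenumbers) != ncol(absorbance))
      stop("wavenumbers length must equal the number of spectral columns")
    if (length(wavenumbers) > 1) {
      d <- diff(wavenumbers)
      if (!(all(d > 0) || all(d < 0)))
        stop("wavenumbers must be strictly monotonic")
    }
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("sample_ids length must equal the number of rows")
  if (is.null(group_ids)) group_ids <- derive_groups(sample_ids)
  group_ids <- as.character(group_ids)
  if (length(group_ids) != n || anyNA(group_ids))
    stop("group_ids must be defined for every row")
  if (!is.null(targets)) {
    targets <- lapply(as.list(targets), as.numeric)
    bad <- vapply(targets, function(v) length(v) != n, logical(1))
    if (any(bad))
      stop("every target vector must have one value per row")
  }
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 sample_ids = sample_ids, group_ids = group_ids,
                 targets = targets),
            class = "spectra_set")
}

#' Derive group identifiers from replicate-suffixed sample labels
#'
#' The group of a measurement is its sample label with one trailing
#' `_<digits>` replicate suffix removed, so `VAT15_1` and `VAT15_2` map to
#' group `VAT15`; labels without such a suffix are their own group.
#'
#' @param sample_ids character vector of measurement labels.
#' @return Character vector of group identifiers.
#' @export
derive_groups <- function(sample_ids) {
  sub("_[0-9]+$", "", as.character(sample_ids))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d variables, %d groups\n",
              nrow(x$absorbance), ncol(x$absorbance),
              length(unique(x$group_ids))))
  if (!is.null(x$wavenumbers))
    cat(sprintf("  wavenumbers: %.2f .. %.2f cm^-1\n",
                x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  if (!is.null(x$targets))
    cat("  targets:", paste(names(x$targets), collapse = ", "), "\n")
  invisible(x)
}

#' Number of rows of a spectra set
#' @param s a `spectra_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(s) nrow(s$absorbance)

# Row-subset a spectra_set, keeping axis and targets aligned.
subset_rows <- function(s, idx) {
  spectra_set(s$absorbance[idx, , drop = FALSE], s$wavenumbers,
              s$sample_ids[idx], s$group_ids[idx],
              if (!is.null(s$targets)) lapply(s$targets, `[`, idx))
}

# Replace the absorbance matrix (after a transform); a NULL axis marks
# feature spaces that no longer map to wavenumbers.
replace_matrix <- function(s, m, wavenumbers = s$wavenumbers) {
  spectra_set(m, wavenumbers, s$sample_ids, s$group_ids, s$targets)
}

#' Read a spectra table from CSV
#'
#' Expects the dialect written by [write_spectra()]: a header row
#' `sample_id[,group_id],<wavenumber>,...` followed by one measurement per
#' row.  Wavenumber headers must parse as numbers and be strictly
#' monotonic.  When no `group_id` column is present, groups are derived by
#' stripping the trailing `_<digits>` replicate suffix of the sample id.
#'
#' @param path CSV file path.
#' @param id_col name of the sample-id column (default `"sample_id"`).
#' @param group_col name of the optional group column (default
#'   `"group_id"`; silently absent files fall back to suffix stripping).
#' @param targets optional path of a targets CSV keyed by `sample_id`.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, id_col = "sample_id", group_col = "group_id",
                         targets = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!id_col %in% names(df)) stop("missing id column '", id_col, "'")
  meta_cols <- c(id_col, if (group_col %in% names(df)) group_col)
  wn_names <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn))
    stop("non-numeric wavenumber header(s): ",
         paste(utils::head(wn_names[is.na(wn)], 3), collapse = ", "))
  if (length(wn) > 1) {
    d <- diff(wn)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumber headers are not strictly monotonic")
  }
  mat <- matrix(NA_real_, nrow(df), length(wn))
  for (j in seq_along(wn_names)) {
    v <- suppressWarnings(as.numeric(df[[wn_names[j]]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric absorbance at row %d, column '%s'",
                   bad, wn_names[j]))
    }
    mat[, j] <- v
  }
  ids <- df[[id_col]]
  groups <- if (group_col %in% names(df)) df[[group_col]] else NULL
  tg <- NULL
  if (!is.null(targets)) {
    tdf <- utils::read.csv(targets, check.names = FALSE)
    if (!"sample_id" %in% names(tdf))
      stop("targets file must have a sample_id column")
    m <- match(ids, tdf$sample_id)
    if (anyNA(m)) stop("targets missing for sample(s): ",
                       paste(utils::head(ids[is.na(m)], 3), collapse = ", "))
    tg <- lapply(tdf[setdiff(names(tdf), "sample_id")],
                 function(v) as.numeric(v)[m])
  }
  spectra_set(mat, wn, ids, groups, tg)
}

#' Write a spectra table to CSV
#'
#' Inverse of [read_spectra()]; values are printed at full precision so a
#' read/write/read cycle round-trips exactly.
#'
#' @param s a `spectra_set`.
#' @param path output CSV path.
#' @param include_group write the `group_id` column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, include_group = TRUE) {
  wn <- s$wavenumbers %||% seq_len(ncol(s$absorbance))
  df <- data.frame(sample_id = s$sample_ids, stringsAsFactors = FALSE)
  if (include_group) df$group_id <- s$group_ids
  m <- s$absorbance
  # %.17g guarantees bit-exact double round-trips
  chr <- as.data.frame(matrix(sprintf("%.17g", m), nrow(m)),
                       check.names = FALSE)
  names(chr) <- format(wn, digits = 17, trim = TRUE, scientific = FALSE)
  out <- cbind(df, chr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a targets table to CSV
#' @param s a `spectra_set` with targets.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(s, path) {
  if (is.null(s$targets)) stop("spectra set has no targets")
  df <- cbind(data.frame(sample_id = s$sample_ids),
              as.data.frame(s$targets, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate measurements
#'
#' Collapses rows sharing an identical sample id to their mean spectrum
#' (targets averaged identically); group ids are retained.  Idempotent,
#' and the identity on data with no duplicated sample ids.
#'
#' @param s a `spectra_set`.
#' @return A `spectra_set` with one row per distinct sample id, in first
#'   appearance order.
#' @export
average_replicates <- function(s) {
  ids <- s$sample_ids
  uniq <- unique(ids)
  if (length(uniq) == n_spectra(s)) return(s)
  idx <- split(seq_along(ids), factor(ids, levels = uniq))
  p <- ncol(s$absorbance)
  mat <- matrix(vapply(idx, function(i)
    colMeans(s$absorbance[i, , drop = FALSE]), numeric(p)),
    ncol = p, byrow = TRUE)
  groups <- vapply(idx, function(i) s$group_ids[i[1]], character(1))
  tg <- if (!is.null(s$targets))
    lapply(s$targets, function(v)
      vapply(idx, function(i) mean(v[i]), numeric(1)))
  spectra_set(mat, s$wavenumbers, uniq, unname(groups),
              if (!is.null(tg)) lapply(tg, unname))
}
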