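#' Read a labeled numeric matrix from TSV
#'
#' The harmonized matrix contract used throughout the package: a
#' tab-separated file whose first column holds row identifiers (drugs, genes
#' or features) and whose header row holds cell-line identifiers.  Empty
#' cells and the literal `NA` are parsed as missing, never as zero.
#' Identifiers are whitespace-trimmed and case-folded to upper case.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with unique `rownames` and `colnames`.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) abort(paste0(path, ": empty file"))
  split_tsv <- function(line) {
    # sentinel keeps trailing empty fields that strsplit would drop
    f <- strsplit(paste0(line, "\t\x01"), "\t", fixed = TRUE)[[1]]
    f[-length(f)]
  }
  header <- split_tsv(lines[1])
  col_ids <- canonical_id(header[-1])
  dup <- col_ids[duplicated(col_ids)]
  if (length(dup)) abort(paste0(path, " line 1: duplicated column id(s): ",
                                paste(unique(dup), collapse = ", ")))
  n_fields <- length(header)
  row_ids <- character(length(lines) - 1)
  values <- matrix(NA_real_, nrow = length(lines) - 1, ncol = length(col_ids))
  for (i in seq_along(row_ids)) {
    f <- split_tsv(lines[i + 1])
    if (length(f) != n_fields) {
      abort(sprintf("%s line %d: expected %d fields, found %d (ragged row)",
                    path, i + 1, n_fields, length(f)))
    }
    row_ids[i] <- canonical_id(f[1])
    cells <- trimws(f[-1])
    miss <- cells == "" | toupper(cells) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      abort(sprintf("%s line %d: non-numeric value '%s' in column '%s'",
                    path, i + 1, cells[which(bad)[1]], col_ids[which(bad)[1]]))
    }
    values[i, ] <- num
  }
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup)) abort(paste0(path, ": duplicated row id(s): ",
                                paste(unique(dup), collapse = ", ")))
  dimnames(values) <- list(row_ids, col_ids)
  values
}

#' Write a labeled matrix to TSV
#'
#' Inverse of [read_matrix()]: missing values are written as empty cells so
#' the round trip is lossless.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c(id_column, colnames(m)), collapse = "\t"), body), path)
  invisible(path)
}

#' Row-wise z-scoring
#'
#' Centers and scales every row to mean 0, SD 1 over its non-missing cells,
#' using the population (1/n) standard deviation, so e.g. `(1, 2, 3)`
#' becomes `(-1.2247, 0, 1.2247)`.  Rows without at least two distinct
#' finite values carry no usable signal and are dropped (their ids are
#' attached as attribute `"dropped"`).
#'
#' @param m Numeric matrix.
#' @return Matrix of z-scores with the surviving rows.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- sqrt(rowMeans((m - mu)^2, na.rm = TRUE))
  keep <- is.finite(sdv) & sdv > 0
  out <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

#' Canonicalize sensitivity orientation
#'
#' Source screens disagree on sign: some report viability (higher = more
#' resistant), others sensitivity (higher = more sensitive).  Everything
#' downstream assumes the viability orientation, so that a positive
#' correlation of a feature with DiffSen reads as resistance-driving.
#' Sensitivity-oriented input is negated; no rescaling is applied.
#'
#' @param m Numeric matrix.
#' @param convention Orientation of `m` as supplied.
#' @return Matrix in the viability orientation (higher = more resistant).
#' @export
orient_sensitivity <- function(m,
                               convention = c("viability_high_resistant",
                                              "sensitivity_high_sensitive")) {
  convention <- match.arg(convention)
  if (convention == "viability_high_resistant") m else -m
}
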