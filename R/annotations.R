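#' Read drug annotations
#'
#' Parses the drug annotation contract: a TSV with columns `drug_id`,
#' `name`, `targets` (semicolon-separated gene ids) and optionally `smiles`
#' and `datasets` (semicolon-separated).  Records with more than two targets
#' are retained here and removed later by [filter_by_target_count()]; a drug
#' with zero targets is a contract violation.
#'
#' @param path TSV path.
#' @return A tibble with one row per drug: `drug_id`, `name`, `targets`
#'   (list-column of gene ids), `n_targets`, `smiles`, `datasets`
#'   (list-column).
#' @export
read_drug_annotations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("drug_id", "name", "targets")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
  targets <- lapply(df$targets, function(x) {
    t <- canonical_id(strsplit(x, ";", fixed = TRUE)[[1]])
    t[nzchar(t)]
  })
  n_targets <- lengths(targets)
  if (any(n_targets == 0)) {
    abort(paste0(path, ": drug(s) with zero targets: ",
                 paste(df$drug_id[n_targets == 0], collapse = ", ")))
  }
  datasets <- if ("datasets" %in% names(df)) {
    lapply(df$datasets, function(x) {
      d <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
      d[nzchar(d)]
    })
  } else rep(list(character(0)), nrow(df))
  tibble::tibble(
    drug_id = canonical_id(df$drug_id),
    name = trimws(df$name),
    targets = targets,
    n_targets = n_targets,
    smiles = if ("smiles" %in% names(df)) trimws(df$smiles) else NA_character_,
    datasets = datasets
  )
}

#' Read a transporter catalog
#'
#' The catalog contract is a TSV with columns `gene_id` and `drug_id`.  A
#' row with an empty `drug_id` declares a generic transporter/carrier gene
#' (a member of the feature universe); a row with a `drug_id` annotates that
#' gene as a known transporter or carrier for that drug.  Every annotated
#' gene must also appear as a generic row.
#'
#' @param path TSV path.
#' @return An object of class `transporter_catalog`: a list with
#'   `all_transporters` (character vector) and `annotated` (named list of
#'   character vectors, one per annotated drug).
#' @export
read_transporter_catalog <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "drug_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
  gene <- canonical_id(df$gene_id)
  drug <- canonical_id(df$drug_id)
  all_tr <- sort_c(unique(gene[drug == ""]))
  ann_rows <- drug != ""
  bad <- setdiff(unique(gene[ann_rows]), all_tr)
  if (length(bad)) {
    abort(paste0(path, ": annotated gene(s) absent from the transporter universe: ",
                 paste(bad, collapse = ", ")))
  }
  annotated <- lapply(split(gene[ann_rows], drug[ann_rows]), function(g) sort_c(unique(g)))
  new_transporter_catalog(all_tr, annotated)
}

new_transporter_catalog <- function(all_transporters, annotated) {
  structure(list(all_transporters = all_transporters,
                 annotated = annotated[sort_c(names(annotated))]),
            class = "transporter_catalog")
}

#' @export
print.transporter_catalog <- function(x, ...) {
  cat("<transporter_catalog> ", length(x$all_transporters), " transporters/carriers, ",
      length(x$annotated), " annotated drugs\n", sep = "")
  invisible(x)
}

#' Write a transporter catalog
#'
#' @param catalog A `transporter_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transporter_catalog <- function(catalog, path) {
  rows <- c(
    paste(catalog$all_transporters, "", sep = "\t"),
    unlist(lapply(names(catalog$annotated), function(d) {
      paste(catalog$annotated[[d]], d, sep = "\t")
    }), use.names = FALSE)
  )
  writeLines(c("gene_id\tdrug_id", rows), path)
  invisible(path)
}

#' Write a drug annotation table
#'
#' @param drugs Drug tibble as produced by [read_drug_annotations()] or
#'   [simulate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_annotations <- function(drugs, path) {
  lines <- vapply(seq_len(nrow(drugs)), function(i) {
    paste(drugs$drug_id[i], drugs$name[i],
          paste(drugs$targets[[i]], collapse = ";"),
          if (is.na(drugs$smiles[i])) "" else drugs$smiles[i],
          paste(drugs$datasets[[i]], collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c("drug_id\tname\ttargets\tsmiles\tdatasets", lines), path)
  invisible(path)
}
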