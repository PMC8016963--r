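#' Align datasets to shared cell lines and shared features
#'
#' Within each dataset the sensitivity, silencing and feature matrices are
#' restricted to the intersection of their cell-line sets — the modeling
#' requires every cell line to carry a drug screen, a silencing screen and a
#' feature profile.  Column order is canonicalized (lexicographic, C
#' collation) so downstream computation is order-stable.  Feature matrices
#' are cleaned per the package's missing-data policy: features missing in
#' more than `max_missing` of cells are dropped, remaining missing feature
#' values are imputed by the feature's median.  Missing sensitivity or
#' silencing cells are left as `NA` and excluded per analysis downstream.
#'
#' @param datasets Named list; each element a list with numeric matrices
#'   `sensitivity` (drugs x cells), `silencing` (genes x cells), `features`
#'   (features x cells) and optionally `lineages` (tibble `cell_id`,
#'   `lineage`).
#' @param max_missing Missingness fraction above which a feature is dropped.
#' @return A list with `datasets` (aligned copies), `shared_cells` (tibble of
#'   pairwise shared cell-line counts and ids) and `shared_features`
#'   (character vector of features present in every dataset).
#' @export
harmonize <- function(datasets, max_missing = 0.2) {
  stopifnot(length(datasets) >= 1)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    abort("`datasets` must be a named list")
  }
  aligned <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    cells <- Reduce(intersect, list(colnames(ds$sensitivity),
                                    colnames(ds$silencing),
                                    colnames(ds$features)))
    if (length(cells) == 0) {
      abort(paste0("dataset '", nm, "': no cell line has all three profiles"))
    }
    cells <- sort_c(cells)
    feat <- ds$features[, cells, drop = FALSE]
    miss_frac <- rowMeans(is.na(feat))
    feat <- feat[miss_frac <= max_missing, , drop = FALSE]
    if (anyNA(feat)) {
      med <- apply(feat, 1, median, na.rm = TRUE)
      idx <- which(is.na(feat), arr.ind = TRUE)
      feat[idx] <- med[idx[, 1]]
    }
    out <- list(sensitivity = ds$sensitivity[, cells, drop = FALSE],
                silencing = ds$silencing[, cells, drop = FALSE],
                features = feat,
                cells = cells)
    if (!is.null(ds$lineages)) {
      lin <- ds$lineages
      out$lineages <- lin[canonical_id(lin$cell_id) %in% cells, , drop = FALSE]
    }
    out
  })
  names(aligned) <- names(datasets)

  nms <- sort_c(names(aligned))
  pairs <- if (length(nms) >= 2) {
    cmb <- combn(nms, 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      sh <- intersect(aligned[[a]]$cells, aligned[[b]]$cells)
      tibble::tibble(dataset_a = a, dataset_b = b, n_shared = length(sh),
                     cells = list(sort_c(sh)))
    })
  } else {
    tibble::tibble(dataset_a = character(), dataset_b = character(),
                   n_shared = integer(), cells = list())
  }
  shared_features <- sort_c(Reduce(intersect, lapply(aligned, function(d) rownames(d$features))))
  list(datasets = aligned, shared_cells = pairs, shared_features = shared_features)
}
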