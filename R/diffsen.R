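#' Compute the DiffSen resistance statistic for a drug
#'
#' DiffSen is the per-cell-line difference between viability under drug
#' treatment and viability under silencing of the drug's primary target.
#' Under the default `zscore` mode both profiles are z-scored first, which
#' makes AUC-scale and viability-scale screens commensurable and makes
#' DiffSen invariant to positive affine rescaling of either input.  A
#' positive value flags a cell line that tolerates the drug better than its
#' dependency on the target predicts — the signature of a resistance
#' mechanism such as drug export.
#'
#' Two-target drugs use the mean of the two z-scored silencing rows,
#' re-z-scored, as the silencing profile.
#'
#' @param drug One row of a drug tibble (or a list with `drug_id`,
#'   `targets`).
#' @param sensitivity,silencing Oriented matrices sharing cell columns.
#' @param mode `"zscore"` (default), `"raw"` (plain difference) or `"rank"`
#'   (difference of z-scored ranks).
#' @param min_cells Minimum usable cells.
#' @return Tibble `cell_id`, `diffsen` (class `diffsen_vector`), with
#'   attributes `drug_id` and `mode`.  Cells with missing input are
#'   excluded.
#' @export
compute_diffsen <- function(drug, sensitivity, silencing,
                            mode = c("zscore", "raw", "rank"), min_cells = 10) {
  mode <- match.arg(mode)
  drug_id <- if (is.data.frame(drug)) drug$drug_id[[1]] else drug$drug_id
  targets <- if (is.data.frame(drug)) drug$targets[[1]] else drug$targets
  if (!drug_id %in% rownames(sensitivity)) abort(paste0("drug not in sensitivity matrix: ", drug_id))
  cells <- intersect(colnames(sensitivity), colnames(silencing))
  prof <- target_silencing_profile(targets, silencing)
  if (is.null(prof)) abort(paste0("target of ", drug_id, " absent from silencing matrix (",
                                  paste(targets, collapse = ","), ")"))
  s <- sensitivity[drug_id, cells]
  v <- prof[cells]
  ok <- is.finite(s) & is.finite(v)
  if (sum(ok) < min_cells) {
    abort(paste0("insufficient_cells: drug ", drug_id, " has ", sum(ok),
                 " usable cells (need ", min_cells, ")"))
  }
  s <- s[ok]; v <- v[ok]
  tf <- switch(mode,
    zscore = zscore_vec,
    raw = identity,
    rank = function(x) zscore_vec(rank(x, ties.method = "average"))
  )
  zs <- tf(s); zv <- tf(v)
  if (is.null(zs) || is.null(zv)) abort(paste0("constant profile for drug ", drug_id))
  out <- tibble::tibble(cell_id = cells[ok], diffsen = unname(zs - zv))
  class(out) <- c("diffsen_vector", class(out))
  attr(out, "drug_id") <- drug_id
  attr(out, "mode") <- mode
  out
}

# named vector view of a diffsen tibble
diffsen_values <- function(d) setNames(d$diffsen, d$cell_id)

#' Split cell lines into training and testing sets
#'
#' Uniform random 70/30 split (by default), reproducible given the seed.
#'
#' @param cell_ids Character vector of cell ids.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train_cells`, `test_cells` (disjoint, covering) and
#'   `seed`.
#' @export
split_train_test <- function(cell_ids, fraction = 0.7, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1")
  }
  if (length(cell_ids) < 10) abort("need at least 10 cells to split")
  cell_ids <- sort_c(cell_ids)
  n_train <- round(fraction * length(cell_ids))
  train <- with_seed(seed, sort_c(sample(cell_ids, n_train)))
  list(train_cells = train, test_cells = setdiff(cell_ids, train), seed = seed)
}
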