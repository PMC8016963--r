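#' Full feature rank vector from one model's correlation ranking
#'
#' Rank 1 is the feature with the highest positive correlation with
#' DiffSen; tied correlations get average ranks.  The vector covers the
#' model's whole feature universe, so rank vectors from different models
#' can be averaged.
#'
#' @param selection A `feature_selection` (from [select_features()]), or
#'   any tibble with `feature_id` and `r` columns.
#' @return Named numeric vector of ranks.
#' @export
rank_features_per_model <- function(selection) {
  r <- setNames(selection$r, selection$feature_id)
  rank(-r, ties.method = "average")
}

#' Aggregate rank vectors across models
#'
#' Per-drug (or per-structure-group) integration: the arithmetic mean of
#' each feature's rank across models, over the features shared by every
#' model, sorted ascending (best mean rank first, ties by feature id).
#'
#' @param rank_vectors List of named rank vectors from
#'   [rank_features_per_model()].
#' @param scope Label recorded on the result (a drug id or group id).
#' @return Tibble of class `ranked_features`: `feature_id`, `mean_rank`,
#'   with attributes `scope` and `n_models`.
#' @export
aggregate_ranks <- function(rank_vectors, scope = NA_character_) {
  stopifnot(length(rank_vectors) >= 1)
  universe <- sort_c(Reduce(intersect, lapply(rank_vectors, names)))
  if (length(universe) == 0) abort("no features shared across the integrated models")
  m <- do.call(cbind, lapply(rank_vectors, function(v) v[universe]))
  mean_rank <- rowMeans(m)
  ord <- order(mean_rank, universe, method = "radix")
  out <- tibble::tibble(feature_id = universe[ord], mean_rank = unname(mean_rank[ord]))
  structure(out, class = c("ranked_features", class(out)),
            scope = scope, n_models = length(rank_vectors))
}

# One-sided p-value that the `k` annotated positions sit low (near the top)
# in a list of n positions. Exact enumeration over all C(n, k) placements
# when small; otherwise a finite-population normal approximation on the sum
# of k positions drawn without replacement (exact mean/variance under ties,
# continuity-corrected).
rank_sum_top_p <- function(positions, is_annotated, exact_max_n = 12, exact_max_k = 8) {
  n <- length(positions)
  k <- sum(is_annotated)
  if (k == 0 || k > n) abort("annotated set must be a non-empty subset of the universe")
  if (k == n) return(1)
  w <- sum(positions[is_annotated])
  if (n <= exact_max_n && k <= exact_max_k) {
    sums <- combn(positions, k, sum)
    return(mean(sums <= w + 1e-9))
  }
  mu <- mean(positions)
  sg2 <- mean((positions - mu)^2)
  m_w <- k * mu
  v_w <- k * sg2 * (n - k) / (n - 1)
  pnorm((w + 0.5 - m_w) / sqrt(v_w))
}

#' Enrichment of an annotated transporter set on an aggregated rank list
#'
#' Tests, one-sided, whether the annotated transporters sit nearer the top
#' of the integrated list than chance placement allows — the rank-sum of
#' their positions against all other features.  For small universes
#' (<= 12 features, <= 8 annotated) the p-value is computed by exhaustive
#' enumeration of all placements; otherwise by a finite-population normal
#' approximation with continuity correction (exact under ties).
#'
#' @param ranked A `ranked_features` list from [aggregate_ranks()].
#' @param annotated Character vector of annotated gene ids.
#' @return One-row tibble of class `enrichment_result`: `scope`,
#'   `n_universe`, `n_annotated` (size of the intersection actually
#'   tested), `statistic` (rank-sum of annotated positions), `p`,
#'   `direction`, `testable`.
#' @export
transporter_enrichment <- function(ranked, annotated) {
  universe <- ranked$feature_id
  ann <- intersect(unique(annotated), universe)
  scope <- attr(ranked, "scope") %||% NA_character_
  if (length(ann) == 0) {
    return(tibble::tibble(scope = scope, n_universe = length(universe),
                          n_annotated = 0L, statistic = NA_real_, p = NA_real_,
                          direction = "top-enriched", testable = FALSE))
  }
  # positions in the sorted list, average ranks for tied mean_rank values
  positions <- rank(ranked$mean_rank, ties.method = "average")
  is_ann <- universe %in% ann
  p <- rank_sum_top_p(positions, is_ann)
  out <- tibble::tibble(scope = scope, n_universe = length(universe),
                        n_annotated = length(ann),
                        statistic = sum(positions[is_ann]), p = p,
                        direction = "top-enriched", testable = TRUE)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Cell-line tail enrichment for one transporter
#'
#' For a candidate transporter and a drug's DiffSen profile: do the
#' `top_n` cell lines with the highest (resp. lowest) expression of the
#' transporter concentrate at the resistant end of the DiffSen-sorted cell
#' list?  Each tail is tested with a one-sided Wilcoxon rank-sum comparing
#' the tail cells' DiffSen against the remaining cells.  Ties at the tail
#' boundary are broken deterministically by cell id.
#'
#' @param feature_row Named numeric vector: the transporter's expression
#'   per cell.
#' @param diffsen A `diffsen_vector` tibble or named numeric vector.
#' @param top_n Tail size (default 10).
#' @return Tibble with rows `high` and `low`: `tail`, `p`, `n_tail`,
#'   `n_rest`, `cells` (list-column of tail cell ids).
#' @export
cellline_enrichment <- function(feature_row, diffsen, top_n = 10) {
  dv <- if (is.data.frame(diffsen)) diffsen_values(diffsen) else diffsen
  cells <- intersect(names(feature_row), names(dv))
  n <- length(cells)
  if (top_n >= n / 2) abort("`top_n` must be smaller than half the cell count")
  if (n < 3 * top_n) abort(paste0("need at least ", 3 * top_n, " cells, have ", n))
  expr <- feature_row[cells]
  # deterministic ordering: expression, then cell id
  ord_hi <- cells[order(-expr, cells, method = "radix")]
  ord_lo <- cells[order(expr, cells, method = "radix")]
  one_tail <- function(tail_cells, label) {
    rest <- setdiff(cells, tail_cells)
    p <- stats::wilcox.test(dv[tail_cells], dv[rest], alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    tibble::tibble(tail = label, p = p, n_tail = length(tail_cells),
                   n_rest = length(rest), cells = list(tail_cells))
  }
  dplyr::bind_rows(one_tail(head(ord_hi, top_n), "high"),
                   one_tail(head(ord_lo, top_n), "low"))
}

#' Overall importance scores from an aggregated rank list
#'
#' Maps mean ranks onto `(0, 1]`:
#' `score = (n_features - mean_rank + 1) / n_features`, so the top feature
#' scores 1 and the bottom feature `1/n`.  Monotone-decreasing in mean
#' rank, which makes scores comparable across drugs with equal universes.
#'
#' @param ranked A `ranked_features` list.
#' @return The tibble with an added `importance` column.
#' @export
importance_scores <- function(ranked) {
  n <- nrow(ranked)
  out <- dplyr::mutate(tibble::as_tibble(ranked),
                       importance = (n - .data$mean_rank + 1) / n)
  structure(out, scope = attr(ranked, "scope"), n_models = attr(ranked, "n_models"))
}
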