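#' Keep drugs with one or two primary targets
#'
#' Drugs with three or more primary targets have polypharmacological effects
#' that silencing a single gene cannot recapture, so they leave the
#' analysis here.
#'
#' @param drugs Drug tibble with list-column `targets`.
#' @return The surviving tibble; removed drugs are attached as attribute
#'   `"removed"` (tibble `drug_id`, `reason`).
#' @export
filter_by_target_count <- function(drugs) {
  n_t <- lengths(drugs$targets)
  keep <- n_t >= 1 & n_t <= 2
  out <- drugs[keep, , drop = FALSE]
  attr(out, "removed") <- tibble::tibble(drug_id = drugs$drug_id[!keep],
                                         reason = "target_count")
  out
}

new_concordance_report <- function(pairs, drug_tbl, skipped = NULL) {
  structure(list(pairs = pairs, drugs = drug_tbl,
                 skipped_pairs = skipped %||% tibble::tibble()),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", sum(x$drugs$surviving), "/", nrow(x$drugs),
      " drugs surviving\n", sep = "")
  invisible(x)
}

#' Same-target concordance filter
#'
#' Drugs inhibiting the same target are expected to share sensitivity
#' profiles across cell lines.  For every same-target drug pair the Pearson
#' correlation and two-sided p-value are computed over shared non-missing
#' cells; a drug survives when the (lower) median of its pairwise p-values
#' with its same-target peers is below `alpha`, i.e. when it is concordant
#' with at least half of its peers.  Targets left with fewer than three
#' surviving drugs are removed together with their drugs (a two-target drug
#' needs at least one retained target).
#'
#' @param sensitivity Oriented drugs x cells matrix.
#' @param drugs Drug tibble (post [filter_by_target_count()]).
#' @param alpha Significance level for pairwise concordance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_drugs_per_target Targets below this drug count are dropped.
#' @return A `concordance_report`: `$pairs` (target, drug_a, drug_b, n, r,
#'   p), `$drugs` (drug_id, median_p, surviving, reason), `$skipped_pairs`.
#' @export
same_target_concordance <- function(sensitivity, drugs, alpha = 0.05,
                                    method = c("pearson", "spearman"),
                                    min_drugs_per_target = 3) {
  method <- match.arg(method)
  present <- drugs$drug_id %in% rownames(sensitivity)
  reason <- setNames(rep(NA_character_, nrow(drugs)), drugs$drug_id)
  reason[!present] <- "not_in_sensitivity"
  dd <- drugs[present, , drop = FALSE]

  # drug -> targets map; target -> member drugs
  target_members <- list()
  for (i in seq_len(nrow(dd))) {
    for (t in dd$targets[[i]]) target_members[[t]] <- c(target_members[[t]], dd$drug_id[i])
  }
  rows <- list(); skipped <- list()
  for (t in sort_c(names(target_members))) {
    mem <- sort_c(target_members[[t]])
    if (length(mem) < 2) next
    cmb <- combn(mem, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      x <- sensitivity[a, ]; y <- sensitivity[b, ]
      if (method == "spearman") {
        ok <- is.finite(x) & is.finite(y)
        x[ok] <- rank(x[ok]); y[ok] <- rank(y[ok])
      }
      ct <- cor_test_pair(x, y)
      if (ct$n < 3) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(target = t, drug_a = a, drug_b = b,
                                                         n = ct$n, reason = "fewer_than_3_shared_cells")
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(target = t, drug_a = a, drug_b = b,
                                                 n = ct$n, r = ct$r, p = ct$p)
    }
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(target = character(), drug_a = character(), drug_b = character(),
                   n = integer(), r = double(), p = double())
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else tibble::tibble()

  median_p <- setNames(rep(NA_real_, nrow(drugs)), drugs$drug_id)
  for (d in dd$drug_id) {
    ps <- c(pairs$p[pairs$drug_a == d], pairs$p[pairs$drug_b == d])
    ps <- ps[is.finite(ps)]
    if (length(ps) == 0) {
      if (is.na(reason[d])) reason[d] <- "no_evaluable_same_target_peer"
    } else {
      # lower median: a drug concordant with at least half of its peers
      # survives (for an even peer count the smaller middle value decides)
      median_p[d] <- unname(stats::quantile(ps, 0.5, type = 1))
      if (median_p[d] >= alpha) reason[d] <- "same_target_discordant"
    }
  }
  # target-size rule, applied after the concordance removal
  surv1 <- dd$drug_id[is.na(reason[dd$drug_id])]
  repeat {
    target_surv <- lapply(target_members, function(m) intersect(m, surv1))
    ok_targets <- names(target_surv)[lengths(target_surv) >= min_drugs_per_target]
    keep <- vapply(seq_len(nrow(dd)), function(i) {
      dd$drug_id[i] %in% surv1 && any(dd$targets[[i]] %in% ok_targets)
    }, logical(1))
    new_surv <- dd$drug_id[keep]
    if (length(new_surv) == length(surv1)) break
    surv1 <- new_surv
  }
  drop_small <- setdiff(dd$drug_id[is.na(reason[dd$drug_id])], surv1)
  reason[drop_small] <- "target_fewer_than_min_drugs"

  drug_tbl <- tibble::tibble(drug_id = drugs$drug_id,
                             median_p = unname(median_p[drugs$drug_id]),
                             surviving = is.na(unname(reason[drugs$drug_id])),
                             reason = unname(reason[drugs$drug_id]))
  new_concordance_report(pairs, drug_tbl, skipped)
}

# silencing profile of a drug's target(s): one target -> its row; two ->
# mean of the two z-scored rows (scale-free combination).
target_silencing_profile <- function(targets, silencing) {
  targets <- intersect(targets, rownames(silencing))
  if (length(targets) == 0) return(NULL)
  if (length(targets) == 1) return(silencing[targets, ])
  zs <- lapply(targets, function(g) {
    v <- silencing[g, ]
    ok <- is.finite(v)
    z <- zscore_vec(v[ok])
    if (is.null(z)) return(NULL)
    out <- rep(NA_real_, length(v)); names(out) <- names(v)
    out[ok] <- z
    out
  })
  if (any(vapply(zs, is.null, logical(1)))) return(NULL)
  colMeans(do.call(rbind, zs))
}

#' Drug-versus-target-silencing concordance filter
#'
#' A drug's in-vitro effect should resemble the effect of silencing its
#' primary target.  Per drug, the Pearson correlation between its
#' sensitivity profile and its target's silencing profile (two-target
#' drugs: the mean of the two z-scored silencing rows) is tested; drugs
#' with `p >= alpha` are removed.
#'
#' @param sensitivity,silencing Oriented matrices over shared cells.
#' @param drugs Drug tibble.
#' @param alpha Significance level.
#' @return A `concordance_report`; `$drugs` carries per-drug `r`, `p`,
#'   `surviving` and a removal `reason`
#'   (`target_not_silenced` / `insufficient_cells` / `not_concordant`).
#' @export
drug_target_concordance <- function(sensitivity, silencing, drugs, alpha = 0.05) {
  cells <- intersect(colnames(sensitivity), colnames(silencing))
  res <- purrr::map_dfr(seq_len(nrow(drugs)), function(i) {
    d <- drugs$drug_id[i]
    if (!d %in% rownames(sensitivity)) {
      return(tibble::tibble(drug_id = d, r = NA_real_, p = NA_real_, n = 0L,
                            surviving = FALSE, reason = "not_in_sensitivity"))
    }
    prof <- target_silencing_profile(drugs$targets[[i]], silencing)
    if (is.null(prof)) {
      return(tibble::tibble(drug_id = d, r = NA_real_, p = NA_real_, n = 0L,
                            surviving = FALSE, reason = "target_not_silenced"))
    }
    ct <- cor_test_pair(sensitivity[d, cells], prof[cells])
    if (ct$n < 3 || is.na(ct$p)) {
      return(tibble::tibble(drug_id = d, r = ct$r, p = ct$p, n = as.integer(ct$n),
                            surviving = FALSE, reason = "insufficient_cells"))
    }
    ok <- ct$p < alpha
    tibble::tibble(drug_id = d, r = ct$r, p = ct$p, n = as.integer(ct$n),
                   surviving = ok, reason = if (ok) NA_character_ else "not_concordant")
  })
  new_concordance_report(tibble::tibble(), res)
}

#' Lineage-specificity screen (one-way ANOVA per feature)
#'
#' Tests, for each feature, whether its values differ across cell-line
#' lineages.  Lineages with `min_cells_per_lineage` cells or fewer are
#' excluded first.  The classic one-way ANOVA F test
#' (`stats::oneway.test(var.equal = TRUE)`) is applied per feature;
#' constant features are reported with `f = 0`, `p = 1`.
#'
#' @param features Features x cells matrix.
#' @param lineage_labels Tibble (`cell_id`, `lineage`) or named character
#'   vector.
#' @param min_cells_per_lineage Lineages must exceed this cell count.
#' @return Tibble `feature_id`, `f`, `p`, `n_lineages`, sorted by `p`.
#' @export
lineage_anova <- function(features, lineage_labels, min_cells_per_lineage = 10) {
  if (is.data.frame(lineage_labels)) {
    lab <- setNames(as.character(lineage_labels$lineage), canonical_id(lineage_labels$cell_id))
  } else lab <- setNames(as.character(lineage_labels), canonical_id(names(lineage_labels)))
  cells <- intersect(colnames(features), names(lab))
  lab <- lab[cells]
  counts <- table(lab)
  keep_lin <- names(counts)[counts > min_cells_per_lineage]
  if (length(keep_lin) < 2) abort("fewer than 2 lineages pass the minimum-cells filter")
  cells <- cells[lab %in% keep_lin]
  g <- factor(lab[cells])
  m <- features[, cells, drop = FALSE]
  res <- purrr::map_dfr(rownames(m), function(f) {
    x <- m[f, ]
    ok <- is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0) {
      return(tibble::tibble(feature_id = f, f = 0, p = 1, n_lineages = length(keep_lin)))
    }
    fit <- tryCatch(stats::oneway.test(x[ok] ~ droplevels(g[ok]), var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$p.value)) {
      return(tibble::tibble(feature_id = f, f = 0, p = 1, n_lineages = length(keep_lin)))
    }
    tibble::tibble(feature_id = f, f = unname(fit$statistic), p = fit$p.value,
                   n_lineages = length(keep_lin))
  })
  dplyr::arrange(res, .data$p, .data$feature_id)
}
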