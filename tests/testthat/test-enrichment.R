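mk_ranked <- function(ids, mean_rank, scope = "D1") {
  structure(tibble::tibble(feature_id = ids, mean_rank = mean_rank),
            class = c("ranked_features", class(tibble::tibble())),
            scope = scope, n_models = 1L)
}

test_that("per-model rank vectors are permutations with average ties", {
  sel <- tibble::tibble(feature_id = c("A", "B", "C"), r = c(0.9, 0.1, -0.5))
  expect_equal(unname(rank_features_per_model(sel)[c("A", "B", "C")]), c(1, 2, 3))
  sel2 <- tibble::tibble(feature_id = c("A", "B", "C"), r = c(0.9, 0.9, -0.5))
  expect_equal(unname(rank_features_per_model(sel2)[c("A", "B", "C")]), c(1.5, 1.5, 3))
  # conservation: ranks sum to n(n+1)/2
  set.seed(3)
  sel3 <- tibble::tibble(feature_id = sprintf("F%02d", 1:40),
                         r = round(rnorm(40), 1))
  expect_equal(sum(rank_features_per_model(sel3)), 40 * 41 / 2)
})

test_that("rank aggregation averages over the shared universe", {
  v1 <- c(A = 1, B = 2, C = 3)
  agg1 <- aggregate_ranks(list(v1), scope = "D1")
  expect_equal(agg1$feature_id, c("A", "B", "C"))
  # two reversed rankings tie everything
  v2 <- c(A = 3, B = 2, C = 1)
  agg2 <- aggregate_ranks(list(v1, v2))
  expect_true(all(agg2$mean_rank == 2))
  # order of models is irrelevant
  v3 <- c(A = 2, B = 1, C = 3)
  expect_equal(aggregate_ranks(list(v1, v3))$mean_rank,
               aggregate_ranks(list(v3, v1))$mean_rank)
  # restricted to the common universe
  v4 <- c(A = 1, B = 2)
  expect_equal(aggregate_ranks(list(v1, v4))$feature_id, c("A", "B"))
  expect_error(aggregate_ranks(list(c(A = 1), c(B = 1))), "shared")
})

test_that("small-universe enrichment matches exhaustive enumeration", {
  # 2 annotated features at ranks 1-2 of 10: p = 1/45
  ranked <- mk_ranked(sprintf("F%02d", 1:10), 1:10)
  res <- transporter_enrichment(ranked, c("F01", "F02"))
  expect_equal(res$p, 1 / 45)
  # independent oracle: enumerate all placements of 2 of 10 positions
  obs <- 1 + 2
  all_sums <- combn(1:10, 2, sum)
  expect_equal(res$p, mean(all_sums <= obs))
  # worst placement has p = 1
  res_worst <- transporter_enrichment(ranked, c("F09", "F10"))
  expect_equal(res_worst$p, 1)
  # annotated = whole universe: no contrast
  res_all <- transporter_enrichment(ranked, sprintf("F%02d", 1:10))
  expect_equal(res_all$p, 1)
  # annotated disjoint from universe: flagged untestable
  res_none <- transporter_enrichment(ranked, "ZZZ")
  expect_false(res_none$testable)
  expect_true(is.na(res_none$p))
})

test_that("normal approximation agrees with a rank-sum oracle and with enumeration", {
  # tie-free case: compare against wilcox.test's normal-approximation p
  set.seed(4)
  ranked <- mk_ranked(sprintf("F%03d", 1:60), 1:60)
  ann <- sprintf("F%03d", sample(60, 8))
  res <- transporter_enrichment(ranked, ann)
  pos <- 1:60
  in_ann <- ranked$feature_id %in% ann
  wt <- stats::wilcox.test(pos[in_ann], pos[!in_ann], alternative = "less",
                           exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p, wt, tolerance = 1e-10)

  # rejection decisions match exhaustive enumeration on small universes
  agree <- vapply(1:200, function(s) {
    set.seed(s)
    n <- sample(8:12, 1); k <- sample(2:4, 1)
    perm <- sample(n)
    ranked_s <- mk_ranked(sprintf("F%02d", 1:n), perm)
    ann_s <- sprintf("F%02d", sample(n, k))
    p_exact <- transporter_enrichment(ranked_s, ann_s)$p
    # normal approximation path, forced
    pos_s <- rank(ranked_s$mean_rank)
    in_a <- ranked_s$feature_id %in% ann_s
    p_norm <- diffsen:::rank_sum_top_p(pos_s, in_a, exact_max_n = 0)
    (p_exact < 0.05) == (p_norm < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("enrichment p-values are uniform under random placement", {
  set.seed(5)
  ps <- vapply(1:1000, function(i) {
    pos <- sample(100)
    diffsen:::rank_sum_top_p(pos, seq_len(100) <= 5, exact_max_n = 0)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cell-line tail enrichment flags expression-aligned DiffSen", {
  cells <- sprintf("C%02d", 1:50)
  set.seed(6)
  ds <- tibble::tibble(cell_id = cells, diffsen = rnorm(50))
  expr_aligned <- setNames(ds$diffsen, cells)
  res <- cellline_enrichment(expr_aligned, ds, top_n = 10)
  expect_lt(res$p[res$tail == "high"], 1e-4)
  expect_gt(res$p[res$tail == "low"], 0.5)
  # independent expression: neither tail significant in a typical draw
  ps <- replicate(50, {
    cellline_enrichment(setNames(rnorm(50), cells), ds, top_n = 10)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(as.vector(ps), "punif")$p.value), 0.001)
  expect_error(cellline_enrichment(expr_aligned, ds, top_n = 25), "top_n")
})

test_that("importance scores map mean ranks onto (0, 1] monotonically", {
  ranked <- mk_ranked(c("A", "B", "C", "D"), c(1, 2, 3, 4))
  imp <- importance_scores(ranked)
  expect_equal(imp$importance, c(1, 0.75, 0.5, 0.25))
  expect_equal(imp$importance[1], 1)
  expect_equal(imp$importance[4], 1 / 4)
  expect_true(all(diff(imp$importance) < 0))
})
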