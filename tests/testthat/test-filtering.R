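test_that("target-count filter keeps exactly the 1-2 target drugs", {
  drugs <- drug_tbl(c("A", "B", "C"),
                    list("T1", c("T1", "T2"), c("T1", "T2", "T3")))
  out <- filter_by_target_count(drugs)
  expect_equal(out$drug_id, c("A", "B"))
  expect_equal(attr(out, "removed")$drug_id, "C")
  # empty in, empty out; all-single-target is the identity
  expect_equal(nrow(filter_by_target_count(drugs[0, ])), 0L)
  single <- drug_tbl(c("A", "B"), list("T1", "T2"))
  expect_equal(filter_by_target_count(single)$drug_id, single$drug_id)
})

test_that("same-target concordance removes the discordant drug and small targets", {
  set.seed(42)
  base <- rnorm(100)
  sens <- rbind(D1 = base, D2 = base + rnorm(100, sd = 1e-6), D3 = rnorm(100))
  colnames(sens) <- sprintf("C%03d", 1:100)
  drugs <- drug_tbl(c("D1", "D2", "D3"), list("T1", "T1", "T1"))
  rep <- same_target_concordance(sens, drugs)
  # D3 is independent noise -> discordant; T1 then has 2 drugs -> all removed
  expect_equal(rep$drugs$reason[rep$drugs$drug_id == "D3"], "same_target_discordant")
  expect_true(all(!rep$drugs$surviving))
  expect_equal(rep$drugs$reason[rep$drugs$drug_id %in% c("D1", "D2")],
               rep("target_fewer_than_min_drugs", 2))

  # all profiles identical and >= 3 drugs: everyone survives
  sens4 <- rbind(D1 = base, D2 = base, D3 = base, D4 = base)
  colnames(sens4) <- colnames(sens)
  drugs4 <- drug_tbl(paste0("D", 1:4), as.list(rep("T1", 4)))
  rep4 <- same_target_concordance(sens4, drugs4)
  expect_true(all(rep4$drugs$surviving))
  expect_true(all(rep4$pairs$r == 1))

  # a 2-drug target is removed outright
  drugs2 <- drug_tbl(c("D1", "D2"), list("T1", "T1"))
  rep2 <- same_target_concordance(sens[1:2, ], drugs2)
  expect_true(all(!rep2$drugs$surviving))
})

test_that("filter reports conserve the input drug set", {
  co <- simulate_cohort(small_sim_cfg(seed = 8))
  h <- harmonize(co$datasets)
  rep <- same_target_concordance(h$datasets$ds1$sensitivity, co$drugs)
  expect_setequal(rep$drugs$drug_id, co$drugs$drug_id)
  expect_equal(sum(rep$drugs$surviving) + sum(!rep$drugs$surviving), nrow(co$drugs))
  expect_true(all(!is.na(rep$drugs$reason[!rep$drugs$surviving])))
  # applying the cascade twice equals applying it once
  surv <- co$drugs[co$drugs$drug_id %in% rep$drugs$drug_id[rep$drugs$surviving], ]
  rep_again <- same_target_concordance(h$datasets$ds1$sensitivity, surv)
  expect_setequal(rep_again$drugs$drug_id[rep_again$drugs$surviving],
                  rep$drugs$drug_id[rep$drugs$surviving])
})

test_that("drug-vs-silencing concordance keeps matched profiles and flags missing targets", {
  cells <- sprintf("C%03d", 1:80)
  set.seed(1)
  sil <- rbind(T1 = rnorm(80), T2 = rnorm(80))
  colnames(sil) <- cells
  sens <- rbind(D1 = sil["T1", ], D2 = rnorm(80), D3 = rnorm(80))
  colnames(sens) <- cells
  drugs <- drug_tbl(c("D1", "D2", "D3"), list("T1", "T2", "TX"))
  rep <- drug_target_concordance(sens, sil, drugs)
  expect_true(rep$drugs$surviving[rep$drugs$drug_id == "D1"])
  expect_equal(rep$drugs$r[rep$drugs$drug_id == "D1"], 1, tolerance = 1e-12)
  expect_equal(rep$drugs$reason[rep$drugs$drug_id == "D3"], "target_not_silenced")

  # two-target drug whose sensitivity is the mean of the z-scored silencing rows
  z <- function(x) (x - mean(x)) / sd(x)
  sens2 <- rbind(DD = (z(sil["T1", ]) + z(sil["T2", ])) / 2)
  colnames(sens2) <- cells
  rep2 <- drug_target_concordance(sens2, sil, drug_tbl("DD", list(c("T1", "T2"))))
  expect_true(rep2$drugs$surviving)
  expect_equal(rep2$drugs$r, 1, tolerance = 1e-12)
})

test_that("lineage ANOVA separates shifted lineages and calibrates under the null", {
  set.seed(7)
  n_per <- 20
  lin <- rep(c("LUNG", "BREAST", "SKIN"), each = n_per)
  cells <- sprintf("C%03d", seq_along(lin))
  labels <- tibble::tibble(cell_id = cells, lineage = lin)
  shifted <- rnorm(length(lin)) + 5 * (lin == "LUNG")
  flat <- rep(2, length(lin))
  nulls <- matrix(rnorm(200 * length(lin)), nrow = 200,
                  dimnames = list(sprintf("N%03d", 1:200), cells))
  feats <- rbind(SHIFTED = shifted, FLAT = flat, nulls)
  colnames(feats)[1:length(cells)] <- cells
  res <- lineage_anova(feats, labels, min_cells_per_lineage = 10)
  expect_lt(res$p[res$feature_id == "SHIFTED"], 1e-6)
  expect_equal(res$p[res$feature_id == "FLAT"], 1)
  null_p <- res$p[grepl("^N", res$feature_id)]
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)

  # lineages at or below the threshold are excluded; <2 remaining errors
  labels_small <- labels[labels$lineage != "SKIN", ]
  expect_error(lineage_anova(feats[, labels_small$cell_id],
                             labels_small[labels_small$lineage == "LUNG", ]),
               "fewer than 2 lineages")
})
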