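test_that("generator is bit-reproducible under a fixed seed", {
  a <- simulate_cohort(small_sim_cfg(seed = 11))
  b <- simulate_cohort(small_sim_cfg(seed = 11))
  expect_identical(a$datasets, b$datasets)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(small_sim_cfg(seed = 12))
  expect_false(identical(a$datasets$ds1$sensitivity, c2$datasets$ds1$sensitivity))
})

test_that("drug counts and target assignment follow the configuration", {
  co <- simulate_cohort(small_sim_cfg(seed = 2, n_targets = 2, drugs_per_target = 3))
  expect_equal(nrow(co$drugs), 6L)
  expect_true(all(co$drugs$n_targets == 1L))
  expect_equal(length(unique(vapply(co$drugs$targets, `[[`, character(1), 1))), 2L)
  # structure groups partition the drugs
  sg <- co$truth$structure_groups
  expect_setequal(unlist(sg), co$drugs$drug_id)
  expect_equal(anyDuplicated(unlist(sg)), 0L)
  # every planted transporter exists in the feature matrix
  expect_true(all(unlist(co$truth$planted_transporters) %in%
                    rownames(co$datasets$ds1$features)))
})

test_that("invalid configuration fields are reported by name", {
  expect_error(sim_config(overlap_fraction = 1.4), "overlap_fraction")
  expect_error(sim_config(drugs_per_target = 2), "drugs_per_target")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_transporters = -1), "n_transporters")
  expect_error(sim_config(planted_per_drug = 1e6), "planted_per_drug")
})

test_that("with zero effect size DiffSen carries no planted-transporter signal", {
  co <- simulate_cohort(small_sim_cfg(seed = 21, effect_size_beta = 0,
                                      n_cells_per_dataset = 120))
  h <- harmonize(co$datasets)
  rs <- vapply(seq_len(nrow(co$drugs)), function(i) {
    d <- co$drugs[i, ]
    y <- compute_diffsen(d, h$datasets$ds1$sensitivity, h$datasets$ds1$silencing)
    pl <- co$truth$planted_transporters[[d$drug_id]]
    mean(vapply(pl, function(t) {
      cor(h$datasets$ds1$features[t, y$cell_id], y$diffsen)
    }, numeric(1)))
  }, numeric(1))
  # mean correlation across 9 drugs x 2 planted ~ N(0, small)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("stronger planted effects raise the DiffSen association monotonically", {
  mean_abs_cor <- function(beta) {
    vals <- vapply(1:12, function(s) {
      co <- simulate_cohort(small_sim_cfg(seed = 100 + s, effect_size_beta = beta,
                                          n_cells_per_dataset = 80, n_datasets = 1,
                                          drugs_per_target = 3, n_targets = 2))
      h <- harmonize(co$datasets)
      d <- co$drugs[1, ]
      y <- compute_diffsen(d, h$datasets$ds1$sensitivity, h$datasets$ds1$silencing)
      pl <- co$truth$planted_transporters[[d$drug_id]]
      mean(abs(vapply(pl, function(t) {
        cor(h$datasets$ds1$features[t, y$cell_id], y$diffsen)
      }, numeric(1))))
    }, numeric(1))
    mean(vals)
  }
  m0 <- mean_abs_cor(0); m1 <- mean_abs_cor(1); m2 <- mean_abs_cor(2)
  expect_lt(m0, m1)
  expect_lt(m1, m2)
})

test_that("fingerprint generator hits its similarity targets", {
  drugs <- drug_tbl(c("A", "B", "C", "D"), as.list(c("T1", "T1", "T2", "T2")))
  groups <- list(g1 = c("A", "B"), g2 = c("C", "D"))
  # within 1, between 0: identical inside a group, disjoint across groups
  fp <- simulate_fingerprints(drugs, groups, within_sim = 1, between_sim = 0, seed = 1)
  expect_identical(fp$A, fp$B)
  expect_equal(tanimoto(fp$A, fp$B), 1.0)
  expect_length(intersect(fp$A, fp$C), 0)
  expect_equal(tanimoto(fp$A, fp$C), 0.0)
  # intermediate targets realized to within rounding
  fp2 <- simulate_fingerprints(drugs, groups, within_sim = 0.6, between_sim = 0.1,
                               size = 128, seed = 2)
  expect_lt(abs(tanimoto(fp2$A, fp2$B) - 0.6), 0.1)
  expect_lt(abs(tanimoto(fp2$C, fp2$D) - 0.6), 0.1)
  expect_lt(abs(tanimoto(fp2$A, fp2$C) - 0.1), 0.1)
  expect_error(simulate_fingerprints(drugs, list(g1 = character(0))), "non-empty")
})

test_that("written cohorts round-trip losslessly through the readers", {
  co <- simulate_cohort(small_sim_cfg(seed = 31))
  co$fingerprints <- simulate_fingerprints(co$drugs, co$truth$structure_groups, seed = 31)
  dir <- tempfile("cohort")
  manifest <- write_cohort(co, dir)
  expect_setequal(names(manifest$datasets), names(co$datasets))
  for (nm in names(co$datasets)) {
    expect_setequal(unlist(manifest$datasets[[nm]]),
                    paste0(nm, c("_sensitivity.tsv", "_silencing.tsv",
                                 "_features.tsv", "_lineages.tsv")))
    back <- read_matrix(file.path(dir, paste0(nm, "_sensitivity.tsv")))
    expect_equal(back, co$datasets[[nm]]$sensitivity, tolerance = 1e-12)
    feats <- read_matrix(file.path(dir, paste0(nm, "_features.tsv")))
    expect_equal(feats, co$datasets[[nm]]$features, tolerance = 1e-12)
  }
  drugs <- read_drug_annotations(file.path(dir, "drugs.tsv"))
  expect_equal(drugs$drug_id, co$drugs$drug_id)
  expect_equal(drugs$targets, co$drugs$targets)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(lapply(truth$planted_transporters, sort),
               lapply(co$truth$planted_transporters, sort))
  catalog <- read_transporter_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(catalog$annotated[names(co$truth$planted_transporters)[1]][[1]],
               co$truth$planted_transporters[[1]])
})
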