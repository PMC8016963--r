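make_xy <- function(n, p, n_signal = 0, beta = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("C%03d", 1:n), sprintf("F%03d", 1:p)))
  signal <- if (n_signal > 0) x[, seq_len(n_signal), drop = FALSE] %*% rep(beta, n_signal) else 0
  y <- as.vector(signal) + rnorm(n)
  list(x = x, y = y)
}

test_that("feature ranking puts a perfect proxy first and its negation last", {
  set.seed(1)
  cells <- sprintf("C%02d", 1:50)
  y <- setNames(rnorm(50), cells)
  feats <- rbind(POS = y, NEG = -y,
                 matrix(rnorm(5 * 50), 5, 50, dimnames = list(paste0("N", 1:5), cells)))
  sel <- select_features(feats, y, k = 3)
  expect_equal(sel$feature_id[1], "POS")
  expect_equal(sel$r[1], 1, tolerance = 1e-12)
  expect_equal(sel$feature_id[nrow(sel)], "NEG")
  expect_true("POS" %in% attr(sel, "selected"))
  expect_error(select_features(feats, y, k = 0), "k")
  # constant features are ranked as r = 0, not dropped
  feats2 <- rbind(feats, CONST = rep(1, 50))
  sel2 <- select_features(feats2, y, k = 3)
  expect_equal(sel2$r[sel2$feature_id == "CONST"], 0)
})

test_that("planted features reach the selected top-k reliably", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 140; p <- 300
    feats <- matrix(rnorm(p * n), p, n,
                    dimnames = list(sprintf("F%03d", 1:p), sprintf("C%03d", 1:n)))
    y <- setNames(2 * colSums(feats[1:3, ]) + rnorm(n), colnames(feats))
    sel <- select_features(feats, y, k = 50)
    all(c("F001", "F002", "F003") %in% attr(sel, "selected"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a noiseless linear signal is recovered by every family", {
  d <- make_xy(100, 2, seed = 1)
  y <- as.vector(d$x %*% c(3, -2))
  cand <- fit_candidates(d$x, y, seed = 1)
  cv <- vapply(cand, `[[`, numeric(1), "cv_score")
  expect_gt(cv[["lasso"]], 0.99)
  expect_gt(cv[["ridge"]], 0.99)
  expect_gt(cv[["random_forest"]], 0.95)  # OOB subsampling caps the forest's score
})

test_that("fitting is deterministic under a fixed seed", {
  d <- make_xy(60, 10, n_signal = 2, seed = 3)
  a <- fit_candidates(d$x, d$y, seed = 7)
  b <- fit_candidates(d$x, d$y, seed = 7)
  expect_identical(lapply(a, `[[`, "hyperparameters"), lapply(b, `[[`, "hyperparameters"))
  expect_identical(vapply(a, `[[`, numeric(1), "cv_score"),
                   vapply(b, `[[`, numeric(1), "cv_score"))
  expect_error(fit_candidates(d$x, rep(1, 60), seed = 1), "degenerate")
})

test_that("null responses give near-zero mean CV score", {
  cvs <- vapply(1:20, function(s) {
    d <- make_xy(100, 50, n_signal = 0, seed = 400 + s)
    vapply(fit_candidates(d$x, d$y, seed = s), `[[`, numeric(1), "cv_score")
  }, numeric(3))
  # lambda/grid selection is mildly optimistic, OOB mildly pessimistic;
  # recorded means are within 0.05, asserted with 3 SE headroom
  expect_true(all(abs(rowMeans(cvs)) < 0.12))
})

test_that("winner selection follows CV score with documented tie precedence", {
  d <- make_xy(80, 5, n_signal = 2, seed = 5)
  cand <- fit_candidates(d$x, d$y, seed = 5)
  te <- make_xy(40, 5, seed = 6)
  y_te <- as.vector(te$x[, 1:2] %*% rep(2, 2)) + rnorm(40)
  res <- pick_best_and_evaluate(cand, te$x, y_te)
  expect_equal(res$cv_score, max(vapply(cand, `[[`, numeric(1), "cv_score")))
  expect_true(res$model_family %in% names(cand))
  # perfect test agreement
  y_perfect <- res$predictions$predicted
  res2 <- pick_best_and_evaluate(cand, te$x, y_perfect)
  expect_equal(res2$test_r, 1, tolerance = 1e-10)
  # missing feature in the test matrix is a hard error naming it
  expect_error(pick_best_and_evaluate(cand, te$x[, -2], y_te), "F002")
})

test_that("test-set type-I rate is near nominal for the evaluated winner", {
  succ <- vapply(1:60, function(s) {
    d <- make_xy(70, 10, n_signal = 0, seed = 900 + s)
    cand <- fit_candidates(d$x[1:40, ], d$y[1:40], seed = s,
                           families = c("lasso", "ridge"))
    res <- pick_best_and_evaluate(cand, d$x[41:70, ], d$y[41:70])
    res$successful
  }, logical(1))
  # 99% binomial envelope around 0.05 at n = 60 reaches ~0.13
  expect_lte(mean(succ), 0.15)
})

test_that("feature selection and tuning never touch held-out cells", {
  d <- make_xy(100, 30, n_signal = 3, seed = 11)
  feats <- t(d$x)
  y <- setNames(d$y, rownames(d$x))
  train <- rownames(d$x)[1:70]; test <- rownames(d$x)[71:100]
  run <- function(y_all) {
    sel <- select_features(feats, y_all[train], k = 10)
    cand <- fit_candidates(d$x[train, attr(sel, "selected")], y_all[train], seed = 2)
    list(sel = sel$feature_id, lambda = lapply(cand, `[[`, "hyperparameters"),
         coefs = as.vector(predict(cand$lasso$fit, s = cand$lasso$hyperparameters$lambda,
                                   type = "coefficients")))
  }
  y_corrupt <- y
  y_corrupt[test] <- rnorm(30) * 100
  expect_identical(run(y), run(y_corrupt))
})

test_that("ridge in the small-lambda limit matches the normal equations", {
  set.seed(12)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.vector(x %*% c(1, -2, 0.5, 3)) + rnorm(60)
  cand <- fit_candidates(x, y, seed = 1, families = "ridge", lambda_grid = 1e-9)
  b_ridge <- as.vector(predict(cand$ridge$fit, s = 1e-9, type = "coefficients"))
  xd <- cbind(1, x)
  b_ols <- as.vector(solve(crossprod(xd), crossprod(xd, y)))
  expect_lt(max(abs(b_ridge - b_ols)), 1e-6)
})

test_that("lasso above the critical lambda is intercept-only", {
  set.seed(13)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.vector(x %*% c(2, -1, 0, 0, 0, 0)) + rnorm(50)
  xs <- scale(x)
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / nrow(x)
  cand <- fit_candidates(x, y, seed = 1, families = "lasso", lambda_grid = lmax * 1.05)
  beta <- as.vector(predict(cand$lasso$fit, s = lmax * 1.05, type = "coefficients"))
  expect_true(all(beta[-1] == 0))
})

test_that("cross-dataset transfer works on shared truth and refuses degenerate setups", {
  co <- simulate_cohort(small_sim_cfg(seed = 55, n_cells_per_dataset = 120,
                                      overlap_fraction = 0.3, effect_size_beta = 2))
  h <- harmonize(co$datasets)
  d <- co$drugs[1, ]
  res <- cross_dataset_run(d, h$datasets$ds1, h$datasets$ds2, "ds1", "ds2",
                           k = 30, seed = 1)
  expect_s3_class(res, "diffsen_model")
  expect_lt(res$test_p, 0.05)
  expect_equal(res$train_dataset, "ds1")
  # training and testing on the same dataset leaves no eligible cells
  same <- cross_dataset_run(d, h$datasets$ds1, h$datasets$ds1, "ds1", "ds1")
  expect_s3_class(same, "model_refusal")
  expect_equal(same$reason, "insufficient_test_cells")
})

test_that("transfer onto an unrelated cohort is not systematically significant", {
  co_a <- simulate_cohort(small_sim_cfg(seed = 66, n_cells_per_dataset = 100,
                                        n_datasets = 1))
  co_b <- simulate_cohort(small_sim_cfg(seed = 77, n_cells_per_dataset = 100,
                                        n_datasets = 1))
  dsb <- co_b$datasets$ds1
  for (nm in c("sensitivity", "silencing", "features")) {
    colnames(dsb[[nm]]) <- paste0("X", colnames(dsb[[nm]]))
  }
  ha <- harmonize(co_a$datasets)$datasets$ds1
  hb <- harmonize(list(ds1 = dsb))$datasets$ds1
  succ <- vapply(co_a$drugs$drug_id[1:6], function(did) {
    d <- co_a$drugs[co_a$drugs$drug_id == did, ]
    res <- cross_dataset_run(d, ha, hb, "a", "b", k = 20, seed = 3,
                             families = c("lasso", "ridge"))
    inherits(res, "diffsen_model") && isTRUE(res$successful)
  }, logical(1))
  expect_lte(sum(succ), 2)
})

test_that("tidy and glance expose the fitted model in broom shape", {
  co <- simulate_cohort(small_sim_cfg(seed = 91))
  h <- harmonize(co$datasets)
  m <- fit_drug_model(co$drugs[1, ], h$datasets$ds1, k = 20, seed = 4)
  td <- tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$model_family, m$model_family)
  expect_true(is.numeric(gl$test_p))
})
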