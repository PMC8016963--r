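#' Correlation-based feature selection
#'
#' Ranks every feature by the Pearson correlation of its values with
#' DiffSen over the supplied (training) cells — signed and descending by
#' default, so rank 1 is the feature whose high values most strongly track
#' resistance — and selects the top `k`.  Ties are broken lexicographically
#' by feature id; constant features get `r = 0`.
#'
#' @param features Features x cells matrix.
#' @param y A `diffsen_vector` tibble or named numeric vector (training
#'   cells only — the caller is responsible for not leaking test cells).
#' @param k Number of features to select.
#' @param ranking `"signed"` (default, highest positive correlation first)
#'   or `"absolute"`.
#' @return A tibble of class `feature_selection` (`feature_id`, `r`, `p`,
#'   `rank`) over the whole feature universe, with attributes `selected`,
#'   `k` and `cells`.
#' @export
select_features <- function(features, y, k = 50, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (!is.numeric(k) || k <= 0) abort("`k` must be a positive integer")
  yv <- if (is.data.frame(y)) diffsen_values(y) else y
  cells <- intersect(colnames(features), names(yv))
  if (length(cells) < 3) abort("fewer than 3 cells shared between features and y")
  m <- features[, cells, drop = FALSE]
  yv <- yv[cells]
  r <- row_cor(m, yv)
  p <- pearson_p(r, length(cells))
  key <- if (ranking == "signed") -r else -abs(r)
  ord <- order(key, rownames(m), method = "radix")
  tbl <- tibble::tibble(feature_id = rownames(m)[ord], r = unname(r[ord]),
                        p = unname(p[ord]), rank = seq_along(ord))
  selected <- head(tbl$feature_id, min(k, nrow(tbl)))
  structure(tbl, class = c("feature_selection", class(tbl)),
            selected = selected, k = k, cells = cells, ranking = ranking)
}

#' Fit the candidate model families with five-fold cross-validation
#'
#' Trains lasso and ridge regressions over a logarithmic lambda grid,
#' scoring each lambda by the mean over five seeded folds of the Pearson
#' correlation between held-out predictions and held-out DiffSen, and a
#' random forest tuned over a grid of variables-per-split
#' (`floor(sqrt(p))`, `floor(p/3)`, `floor(p/2)`) and tree counts (250,
#' 500, 1000) minimizing out-of-bag mean squared error.  All three
#' families are compared on a common correlation scale: for the forest,
#' `cv_score` is the correlation of out-of-bag predictions with the
#' response.
#'
#' @param x_train Cells x features numeric matrix (training cells only).
#' @param y_train Numeric response (DiffSen on the same cells).
#' @param seed Integer seed driving fold assignment and forest randomness.
#' @param families Subset of `c("lasso", "ridge", "random_forest")`.
#' @param nfolds Folds for the lambda search.
#' @param n_lambda Grid resolution for lasso/ridge.
#' @param rf_trees Tree-count grid for the forest.
#' @param lambda_grid Optional explicit lambda grid replacing the automatic
#'   one (useful for studying limiting behaviour).
#' @param thresh Coordinate-descent convergence threshold passed to glmnet.
#' @return List of candidate objects (`family`, `fit`, `hyperparameters`,
#'   `cv_score`, `features`).
#' @export
fit_candidates <- function(x_train, y_train, seed = 1L,
                           families = c("lasso", "ridge", "random_forest"),
                           nfolds = 5, n_lambda = 30,
                           rf_trees = c(250, 500, 1000),
                           lambda_grid = NULL, thresh = 1e-10) {
  families <- match.arg(families, several.ok = TRUE)
  n <- nrow(x_train)
  stopifnot(length(y_train) == n)
  if (sd(y_train) == 0) abort("degenerate response: y is constant")
  if (n < 5 * nfolds) abort(paste0("need at least ", 5 * nfolds, " training cells"))
  folds <- with_seed(derive_seed(seed, "folds"),
                     sample(rep(seq_len(nfolds), length.out = n)))
  candidates <- list()

  glmnet_cv <- function(alpha_gl, grid) {
    pred <- matrix(NA_real_, n, length(grid))
    for (f in seq_len(nfolds)) {
      idx <- folds == f
      fit <- glmnet::glmnet(x_train[!idx, , drop = FALSE], y_train[!idx],
                            alpha = alpha_gl, lambda = grid, thresh = thresh)
      pred[idx, ] <- predict(fit, x_train[idx, , drop = FALSE], s = grid)
    }
    cv_by_lambda <- vapply(seq_along(grid), function(l) {
      mean(vapply(seq_len(nfolds), function(f) {
        idx <- folds == f
        if (sd(pred[idx, l]) == 0 || sd(y_train[idx]) == 0) return(0)
        cor(pred[idx, l], y_train[idx])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cv_by_lambda)  # ties -> smaller index = larger lambda
    list(lambda = grid[best], cv_score = cv_by_lambda[best])
  }
  # grid anchored at the critical lambda of the standardized problem
  xs <- scale(x_train)
  xs[!is.finite(xs)] <- 0
  lmax <- max(abs(crossprod(xs, y_train - mean(y_train)))) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1

  if ("lasso" %in% families) {
    grid <- lambda_grid %||% (lmax * 10^seq(0, -4, length.out = n_lambda))
    cvres <- glmnet_cv(1, grid)
    fit <- glmnet::glmnet(x_train, y_train, alpha = 1, lambda = grid, thresh = thresh)
    candidates$lasso <- list(family = "lasso", fit = fit,
                             hyperparameters = list(lambda = cvres$lambda),
                             cv_score = cvres$cv_score, features = colnames(x_train))
  }
  if ("ridge" %in% families) {
    grid <- lambda_grid %||% (lmax * 10^seq(2, -4, length.out = n_lambda))
    cvres <- glmnet_cv(0, grid)
    fit <- glmnet::glmnet(x_train, y_train, alpha = 0, lambda = grid, thresh = thresh)
    candidates$ridge <- list(family = "ridge", fit = fit,
                             hyperparameters = list(lambda = cvres$lambda),
                             cv_score = cvres$cv_score, features = colnames(x_train))
  }
  if ("random_forest" %in% families) {
    p <- ncol(x_train)
    mtry_grid <- sort(unique(pmax(1, c(floor(sqrt(p)), floor(p / 3), floor(p / 2)))))
    best <- NULL
    for (mtry in mtry_grid) {
      for (ntree in sort(rf_trees)) {
        fit <- ranger::ranger(x = x_train, y = y_train, mtry = mtry,
                              num.trees = ntree, importance = "impurity",
                              seed = derive_seed(seed, "rf", mtry, ntree),
                              num.threads = 1)
        oob_mse <- fit$prediction.error
        if (is.null(best) || oob_mse < best$oob_mse) {
          best <- list(fit = fit, mtry = mtry, ntree = ntree, oob_mse = oob_mse)
        }
      }
    }
    oob_pred <- best$fit$predictions
    oob_pred[!is.finite(oob_pred)] <- mean(y_train)
    cv_score <- if (sd(oob_pred) == 0) 0 else cor(oob_pred, y_train)
    candidates$random_forest <- list(
      family = "random_forest", fit = best$fit,
      hyperparameters = list(mtry = best$mtry, ntree = best$ntree, oob_mse = best$oob_mse),
      cv_score = cv_score, features = colnames(x_train))
  }
  candidates
}

predict_candidate <- function(cand, x_new) {
  x_new <- x_new[, cand$features, drop = FALSE]
  if (cand$family == "random_forest") {
    unname(predict(cand$fit, data = x_new, num.threads = 1)$predictions)
  } else {
    as.vector(predict(cand$fit, x_new, s = cand$hyperparameters$lambda))
  }
}

#' Pick the best candidate by CV score and evaluate it on held-out cells
#'
#' The winner is the candidate with the highest cross-validation
#' correlation (ties broken toward the simpler family: lasso, then ridge,
#' then random forest).  Test performance is the Pearson correlation
#' between its predictions and held-out DiffSen, with a two-sided p-value;
#' the model is flagged successful when `test_p < alpha`.
#'
#' @param candidates Output of [fit_candidates()].
#' @param x_test Cells x features matrix over held-out cells; its columns
#'   must cover the training feature set.
#' @param y_test Held-out response.
#' @param alpha Success threshold on the test p-value.
#' @return An object of class `diffsen_model`.
#' @export
pick_best_and_evaluate <- function(candidates, x_test, y_test, alpha = 0.05) {
  stopifnot(length(candidates) >= 1)
  feats <- candidates[[1]]$features
  missing <- setdiff(feats, colnames(x_test))
  if (length(missing)) {
    abort(paste0("test matrix lacks training feature(s): ", paste(missing, collapse = ", ")))
  }
  precedence <- c(lasso = 1, ridge = 2, random_forest = 3)
  fam <- vapply(candidates, `[[`, character(1), "family")
  cv <- vapply(candidates, `[[`, numeric(1), "cv_score")
  ord <- order(-cv, precedence[fam])
  winner <- candidates[[ord[1]]]
  pred <- predict_candidate(winner, x_test)
  ct <- cor_test_pair(pred, y_test)
  structure(list(
    model_family = winner$family,
    hyperparameters = winner$hyperparameters,
    cv_score = winner$cv_score,
    test_r = ct$r,
    test_p = ct$p,
    successful = is.finite(ct$p) && ct$p < alpha,
    n_train = winner$fit$nobs %||% winner$fit$num.samples,
    n_test = length(y_test),
    winner = winner,
    candidate_summary = tibble::tibble(family = unname(fam), cv_score = unname(cv)),
    predictions = tibble::tibble(cell_id = rownames(x_test) %||% as.character(seq_along(y_test)),
                                 predicted = pred, observed = unname(y_test))
  ), class = "diffsen_model")
}

#' @export
print.diffsen_model <- function(x, ...) {
  cat("<diffsen_model> ", x$model_family,
      sprintf("  cv_r=%.3f  test_r=%.3f  test_p=%.3g  %s\n",
              x$cv_score, x$test_r, x$test_p,
              if (isTRUE(x$successful)) "successful" else "not significant"), sep = "")
  invisible(x)
}

#' Fit and evaluate a within-dataset model for one drug
#'
#' Convenience wrapper: computes DiffSen, makes a seeded 70/30 cell split,
#' selects features on the training cells only, fits the candidate
#' families and evaluates the CV winner on the test cells.
#'
#' @param drug One drug row.
#' @param dataset Harmonized dataset (list with `sensitivity`, `silencing`,
#'   `features`).
#' @param k Features to select.
#' @param seed Master seed; the per-drug split seed is derived from it and
#'   the drug id.
#' @param alpha Success threshold.
#' @param split_fraction Training fraction.
#' @param mode DiffSen mode, see [compute_diffsen()].
#' @param families Candidate families.
#' @return A `diffsen_model` with `$selection` and `$split` attached.
#' @export
fit_drug_model <- function(drug, dataset, k = 50, seed = 1L, alpha = 0.05,
                           split_fraction = 0.7, mode = "zscore",
                           families = c("lasso", "ridge", "random_forest")) {
  drug_id <- if (is.data.frame(drug)) drug$drug_id[[1]] else drug$drug_id
  y <- compute_diffsen(drug, dataset$sensitivity, dataset$silencing, mode = mode)
  split <- split_train_test(y$cell_id, fraction = split_fraction,
                            seed = derive_seed(seed, "split", drug_id))
  y_tr <- y[y$cell_id %in% split$train_cells, ]
  y_te <- y[y$cell_id %in% split$test_cells, ]
  sel <- select_features(dataset$features, y_tr, k = k)
  selected <- attr(sel, "selected")
  if (length(selected) < 2) abort("fewer than 2 selected features")
  x_tr <- t(dataset$features[selected, y_tr$cell_id, drop = FALSE])
  x_te <- t(dataset$features[selected, y_te$cell_id, drop = FALSE])
  cand <- fit_candidates(x_tr, diffsen_values(y_tr)[rownames(x_tr)],
                         seed = derive_seed(seed, "fit", drug_id), families = families)
  res <- pick_best_and_evaluate(cand, x_te, diffsen_values(y_te)[rownames(x_te)], alpha = alpha)
  res$drug_id <- drug_id
  res$selection <- sel
  res$split <- split
  res
}

#' Train on one dataset, test on another
#'
#' Features are restricted to those profiled in both datasets; selection
#' and tuning use all usable training-dataset cells; evaluation uses only
#' test-dataset cells absent from the training dataset, so cell lines seen
#' during training can never inflate the transfer estimate.
#'
#' @param drug One drug row.
#' @param train_ds,test_ds Harmonized datasets.
#' @param train_name,test_name Dataset labels recorded on the result.
#' @param k,seed,alpha,mode,families As in [fit_drug_model()].
#' @param min_test_cells Minimum eligible test cells before refusing.
#' @return A `diffsen_model`, or an object of class `model_refusal` (list
#'   with `drug_id` and `reason`) when the transfer is not evaluable.
#' @export
cross_dataset_run <- function(drug, train_ds, test_ds,
                              train_name = "train", test_name = "test",
                              k = 50, seed = 1L, alpha = 0.05, mode = "zscore",
                              families = c("lasso", "ridge", "random_forest"),
                              min_test_cells = 10) {
  drug_id <- if (is.data.frame(drug)) drug$drug_id[[1]] else drug$drug_id
  refusal <- function(reason) structure(list(drug_id = drug_id, reason = reason,
                                             train_dataset = train_name,
                                             test_dataset = test_name),
                                        class = "model_refusal")
  shared <- intersect(rownames(train_ds$features), rownames(test_ds$features))
  if (length(shared) < 2) return(refusal("no_shared_features"))
  elig <- setdiff(colnames(test_ds$sensitivity), colnames(train_ds$sensitivity))
  if (length(elig) < min_test_cells) return(refusal("insufficient_test_cells"))

  y_tr <- tryCatch(compute_diffsen(drug, train_ds$sensitivity, train_ds$silencing, mode = mode),
                   error = function(e) NULL)
  if (is.null(y_tr)) return(refusal("diffsen_unavailable_in_train"))
  y_te <- tryCatch(compute_diffsen(drug,
                                   test_ds$sensitivity[, elig, drop = FALSE],
                                   test_ds$silencing[, elig, drop = FALSE],
                                   mode = mode, min_cells = min_test_cells),
                   error = function(e) NULL)
  if (is.null(y_te)) return(refusal("diffsen_unavailable_in_test"))

  sel <- select_features(train_ds$features[shared, , drop = FALSE], y_tr, k = k)
  selected <- attr(sel, "selected")
  if (length(selected) < 2) return(refusal("too_few_selected_features"))
  x_tr <- t(train_ds$features[selected, y_tr$cell_id, drop = FALSE])
  x_te <- t(test_ds$features[selected, y_te$cell_id, drop = FALSE])
  cand <- fit_candidates(x_tr, diffsen_values(y_tr)[rownames(x_tr)],
                         seed = derive_seed(seed, "transfer", drug_id, train_name, test_name),
                         families = families)
  res <- pick_best_and_evaluate(cand, x_te, diffsen_values(y_te)[rownames(x_te)], alpha = alpha)
  res$drug_id <- drug_id
  res$train_dataset <- train_name
  res$test_dataset <- test_name
  res$selection <- sel
  res
}
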