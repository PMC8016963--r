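#' @importFrom generics tidy glance
NULL

#' Tidy a fitted DiffSen model
#'
#' Returns one row per feature used by the winning model: regression
#' coefficients for lasso/ridge, permutation-free node-purity importance
#' for the random forest.
#'
#' @param x A `diffsen_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `metric`.
#' @export
tidy.diffsen_model <- function(x, ...) {
  w <- x$winner
  if (w$family == "random_forest") {
    imp <- w$fit$variable.importance
    tibble::tibble(term = names(imp), estimate = unname(imp),
                   metric = "impurity_importance")
  } else {
    beta <- predict(w$fit, s = w$hyperparameters$lambda, type = "coefficients")
    tibble::tibble(term = rownames(beta), estimate = as.vector(beta),
                   metric = "coefficient")
  }
}

#' One-row summary of a fitted DiffSen model
#'
#' @param x A `diffsen_model`.
#' @param ... Unused.
#' @return Tibble with `drug_id`, `model_family`, `cv_score`, `test_r`,
#'   `test_p`, `successful`, `n_train`, `n_test`.
#' @export
glance.diffsen_model <- function(x, ...) {
  tibble::tibble(drug_id = x$drug_id %||% NA_character_,
                 train_dataset = x$train_dataset %||% NA_character_,
                 test_dataset = x$test_dataset %||% NA_character_,
                 model_family = x$model_family,
                 cv_score = x$cv_score, test_r = x$test_r, test_p = x$test_p,
                 successful = x$successful,
                 n_train = x$n_train, n_test = x$n_test)
}

#' @export
generics::tidy

#' @export
generics::glance
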