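#' @import ggplot2
NULL

#' Boxplot of same-target concordance by target
#'
#' Visualizes the same-target filter: the distribution of pairwise
#' similarity scores (negative log10 correlation p-value) among drugs
#' sharing a target.
#'
#' @param object A `concordance_report` from [same_target_concordance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  if (nrow(object$pairs) > 0) {
    df <- dplyr::mutate(object$pairs, score = -log10(pmax(.data$p, 1e-300)))
    ggplot(df, aes(x = .data$target, y = .data$score)) +
      geom_boxplot(outlier.size = 0.7, fill = "grey85") +
      geom_hline(yintercept = -log10(0.05), linetype = 2, colour = "firebrick") +
      labs(x = "target", y = expression(-log[10]~"pairwise correlation p"),
           title = "Same-target drug concordance") +
      theme_bw() + theme(axis.text.x = element_text(angle = 45, hjust = 1))
  } else {
    df <- dplyr::filter(object$drugs, is.finite(.data$p))
    ggplot(df, aes(x = .data$surviving, y = -log10(pmax(.data$p, 1e-300)))) +
      geom_jitter(width = 0.15, alpha = 0.6) +
      geom_hline(yintercept = -log10(0.05), linetype = 2, colour = "firebrick") +
      labs(x = "surviving", y = expression(-log[10]~"correlation p"),
           title = "Drug vs target-silencing concordance") +
      theme_bw()
  }
}

#' Heatmap of model transfer performance
#'
#' The machine-readable analog of a train-by-test performance matrix:
#' tiles show `-log10` test p per drug and dataset pair; grey tiles are
#' unavailable models.
#'
#' @param models The `$models` tibble of a `resistance_report` (or a
#'   report itself).
#' @return A ggplot.
#' @export
plot_model_heatmap <- function(models) {
  if (inherits(models, "resistance_report")) models <- models$models
  df <- dplyr::mutate(models,
                      pair = paste(.data$train_dataset, .data$test_dataset, sep = " -> "),
                      score = -log10(pmax(.data$test_p, 1e-16)))
  ggplot(df, aes(x = .data$pair, y = .data$drug_id, fill = .data$score)) +
    geom_tile(colour = "white") +
    scale_fill_gradient(low = "white", high = "darkgreen",
                        name = expression(-log[10]~p)) +
    labs(x = "train -> test datasets", y = NULL, title = "DiffSen model performance") +
    theme_minimal() + theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Enrichment of annotated transporters across drugs
#'
#' @param enrichment The `$enrichment` tibble of a `resistance_report` (or
#'   a report itself).
#' @return A ggplot bar chart of `-log10` enrichment p per drug.
#' @export
plot_enrichment <- function(enrichment) {
  if (inherits(enrichment, "resistance_report")) enrichment <- enrichment$enrichment
  df <- dplyr::filter(enrichment, .data$testable)
  ggplot(df, aes(x = stats::reorder(.data$scope, -.data$p), y = -log10(pmax(.data$p, 1e-16)))) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = -log10(0.05), linetype = 2, colour = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10]~"enrichment p"),
         title = "Known-transporter enrichment on aggregated feature ranks") +
    theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
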