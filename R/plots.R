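#' Plot the From->To single-nucleotide mutation matrix
#'
#' Heatmap of the 4x4 base-substitution counts from an [summarize_edits()]
#' result ("From" is the reference-genome base).
#'
#' @param summary An `edit_summary`.
#' @return A ggplot object.
#' @export
plot_mutation_matrix <- function(summary) {
  df <- as_tibble(as.data.frame(summary$mutation_matrix,
                                responseName = "count"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$To, y = .data$From,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev(DNA_BASES)) +
    ggplot2::labs(title = "Single-nucleotide mutation pattern",
                  x = "To", y = "From (reference)") +
    ggplot2::theme_minimal()
}

#' Plot influenced-type percentages per editor
#'
#' Stacked bars of significantly influenced vs non-influenced off-target
#' types per editor, from an [summarize_influence()] result.
#'
#' @param summary An `influence_summary`.
#' @return A ggplot object.
#' @export
plot_influence <- function(summary) {
  df <- summary$per_editor %>%
    mutate(influenced = .data$n_types_influenced,
           not_influenced = .data$n_types_tested - .data$n_types_influenced) %>%
    tidyr::pivot_longer(c("influenced", "not_influenced"),
                        names_to = "status", values_to = "n_types")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$editor, y = .data$n_types,
                                   fill = .data$status)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(title = "Off-target types influenced by chromatin context",
                  x = NULL, y = "Percentage of tested types", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of association p-values
#'
#' Type-by-feature heatmap of `-log10(p)` signed by direction (red positive,
#' blue negative), from [screen_types()] results.
#'
#' @param results Association results tibble.
#' @param alpha Significance level used only to annotate the colour scale.
#' @return A ggplot object.
#' @export
plot_association_heatmap <- function(results, alpha = 0.05) {
  df <- results %>%
    filter(!is.na(.data$p_value)) %>%
    mutate(signed = ifelse(.data$direction == "positive", 1, -1) *
             -log10(pmax(.data$p_value, 1e-12)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$type_id,
                                   fill = .data$signed)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "signed -log10(p)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Chromatin-feature association by off-target type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curve of an evaluated off-target model
#'
#' @param object A `model_report` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path(color = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("ROC (AUC = %s)",
                      ifelse(is.na(object$auc), "NA",
                             sprintf("%.3f", object$auc))),
      x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot feature importances of an evaluated model
#'
#' Top-`n` features by normalised importance, chromatin features
#' highlighted.
#'
#' @param report A `model_report`.
#' @param n Number of features to show (default 20).
#' @return A ggplot object.
#' @export
plot_importance <- function(report, n = 20) {
  df <- head(report$importance, n) %>%
    mutate(block = ifelse(.data$feature %in% chromatin_feature_names(),
                          "chromatin", "sequence"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$importance),
                                   y = .data$importance,
                                   fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalised importance", fill = NULL) +
    ggplot2::theme_minimal()
}
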