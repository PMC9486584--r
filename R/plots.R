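# ggplot2 views of the result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of differential drug response scores
#'
#' @param object A `drug_ranking` from [rank_drugs()].
#' @param bins Histogram bins, default 30.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drug_ranking
#' @export
autoplot.drug_ranking <- function(object, bins = 30, ...) {
  scored <- as_tibble(object)[!object$unscored, ]
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(
      x = "differential drug response score",
      y = "drugs",
      title = sprintf("%d scored drugs (%d unscored)", nrow(scored), sum(object$unscored))
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of a drug-ranking evaluation
#'
#' The dotted diagonal marks an uninformative ranking; the shaded band the
#' false-positive-rate range of the partial AUC.
#'
#' @param object A `drug_eval` from [evaluate_ranking()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drug_eval
#' @export
autoplot.drug_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 0.1, ymin = 0, ymax = 1, alpha = 0.08) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf(
        "AUC %.3f, pAUC %.4f (threshold %.3g, n = %d)",
        object$auc, object$pauc, object$gt_threshold, object$n_drugs
      )
    ) +
    ggplot2::theme_minimal()
}

#' Differential score distributions per edge type
#'
#' @param object A `differential_network`.
#' @param bins Histogram bins, default 40.
#' @param ... Unused.
#' @return A ggplot faceted by edge type.
#' @method autoplot differential_network
#' @export
autoplot.differential_network <- function(object, bins = 40, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$edge_type), scales = "free_y") +
    ggplot2::labs(
      x = sprintf(
        "differential integrated score (%s - %s)",
        attr(object, "condition_a"), attr(object, "condition_b")
      ),
      y = "edges"
    ) +
    ggplot2::theme_minimal()
}

#' Per-target differential edge distribution of one drug
#'
#' Stacked histogram of the differential scores of all edges incident to
#' the drug's targets, coloured by target — the explainability view showing
#' which target's interactions differ most between conditions.
#'
#' @param object A `drug_explanation` from [explain_drug()].
#' @param bins Histogram bins, default 30.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drug_explanation
#' @export
autoplot.drug_explanation <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$diff, fill = .data$target)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(
      x = sprintf(
        "differential integrated score (%s - %s)",
        object$condition_a, object$condition_b
      ),
      y = "incident edges",
      title = sprintf("%s: per-target differential interactions", object$drug)
    ) +
    ggplot2::theme_minimal()
}
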