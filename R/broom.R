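# broom-style accessors for fitted/derived objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a drug ranking
#'
#' @param x A `drug_ranking` from [rank_drugs()].
#' @param ... Unused.
#' @return A plain tibble with one row per drug.
#' @method tidy drug_ranking
#' @export
tidy.drug_ranking <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.drug_ranking
#' @method glance drug_ranking
#' @export
glance.drug_ranking <- function(x, ...) {
  scored <- x[!x$unscored, ]
  tibble(
    n_drugs = nrow(x),
    n_scored = nrow(scored),
    n_unscored = sum(x$unscored),
    top_drug = if (nrow(scored)) scored$drug_id[1L] else NA_character_,
    top_score = if (nrow(scored)) scored$score[1L] else NA_real_,
    aggregator = attr(x, "aggregator")
  )
}

#' Tidy an evaluation result
#'
#' `tidy()` returns the ROC coordinates; `glance()` the one-row summary
#' (AUC, partial AUC, Spearman correlation).
#'
#' @param x A `drug_eval` from [evaluate_ranking()].
#' @param ... Unused.
#' @method tidy drug_eval
#' @export
tidy.drug_eval <- function(x, ...) {
  x$roc
}

#' @rdname tidy.drug_eval
#' @method glance drug_eval
#' @export
glance.drug_eval <- function(x, ...) {
  tibble(
    auc = x$auc, pauc = x$pauc,
    spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
    n_drugs = x$n_drugs, n_pos = x$n_pos, n_neg = x$n_neg,
    gt_threshold = x$gt_threshold
  )
}

#' Tidy a drug explanation
#'
#' @param x A `drug_explanation` from [explain_drug()].
#' @param ... Unused.
#' @return The per-target edge table (one row per target-incident edge).
#' @method tidy drug_explanation
#' @export
tidy.drug_explanation <- function(x, ...) {
  x$edges
}

#' @rdname tidy.drug_explanation
#' @method glance drug_explanation
#' @export
glance.drug_explanation <- function(x, ...) {
  tibble(
    drug_id = x$drug,
    score = x$score,
    n_edges = x$n_edges,
    n_targets = length(x$targets)
  )
}
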