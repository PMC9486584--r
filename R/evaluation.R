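# Ground-truth construction, ROC/pAUC evaluation and the weighted-PageRank
# baseline.

#' Mann-Whitney ground truth from drug sensitivities
#'
#' For every drug measured at least `min_reps` times in each condition, a
#' two-sided Mann-Whitney U test compares its sensitivities between the two
#' conditions; the p-value serves as the ground-truth differential-response
#' ranking (small p = likely differential). Exact p-values are used for
#' small tie-free samples (both groups <= 10), the tie-corrected normal
#' approximation otherwise.
#'
#' @param sens A sensitivity table (see [read_sensitivities()]).
#' @param condition_a,condition_b The two condition labels to compare.
#' @param min_reps Minimal replicates per condition, default 3.
#' @return A tibble with `drug_id`, `p_value`, `n_a`, `n_b`, ordered by
#'   ascending p-value.
#' @export
ground_truth_mwu <- function(sens, condition_a, condition_b, min_reps = 3) {
  sens <- read_sensitivities(sens)
  for (cc in c(condition_a, condition_b)) {
    if (cc %not_in% sens$condition) abort(paste0("Condition absent from table: ", cc))
  }
  sens <- sens[sens$condition %in% c(condition_a, condition_b), ]
  rows <- purrr::map(split(sens, sens$drug_id), function(d) {
    xa <- d$sensitivity[d$condition == condition_a]
    xb <- d$sensitivity[d$condition == condition_b]
    if (length(xa) < min_reps || length(xb) < min_reps) {
      return(NULL)
    }
    exact <- length(xa) <= 10 && length(xb) <= 10 && !anyDuplicated(c(xa, xb))
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact)$p.value
    )
    # a fully tied comparison has zero rank variance (NaN z-score): no evidence
    if (is.nan(p)) p <- 1
    tibble(drug_id = d$drug_id[1L], p_value = p, n_a = length(xa), n_b = length(xb))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("No drug has enough replicates in both conditions.")
  out[order(out$p_value, out$drug_id), ]
}

# ROC coordinates for scores (descending = predicted positive first) against
# binary labels; tied scores collapse into one diagonal step
roc_points <- function(score, label) {
  ord <- order(-score)
  score <- score[ord]
  label <- label[ord]
  last <- !duplicated(score, fromLast = TRUE) # end of each tie block
  tp <- cumsum(label)[last]
  fp <- cumsum(!label)[last]
  tibble(
    fpr = c(0, fp / sum(!label)),
    tpr = c(0, tp / sum(label))
  )
}

trapezoid_area <- function(x, y, upper = max(x)) {
  # area under the piecewise-linear curve for x in [0, upper]
  if (upper < max(x)) {
    keep <- x < upper
    y_up <- stats::approx(x, y, xout = upper, ties = "ordered")$y
    x <- c(x[keep], upper)
    y <- c(y[keep], y_up)
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' ROC, AUC and partial AUC of a drug ranking against ground truth
#'
#' Drugs are binarized by the ground-truth p-value (`p < gt_threshold` is a
#' true positive) and ranked by descending predicted score. Only drugs with
#' both a prediction and a ground-truth value enter. The AUC is computed by
#' the trapezoid rule; the partial AUC is the unnormalized area over false
#' positive rates in \[0, 0.1\] (0.005 for an uninformative ranking, 0.1
#' for a perfect one), which measures enrichment of true positives among
#' the top-ranked drugs. Tied predicted scores are collapsed into one
#' diagonal ROC segment, making the result independent of input order.
#'
#' @param ranking A data frame with columns `drug_id` and `score` (e.g. a
#'   `drug_ranking`; unscored drugs are dropped).
#' @param truth A ground-truth table from [ground_truth_mwu()].
#' @param gt_threshold Ground-truth p-value threshold, default 0.01.
#' @return A list with `auc`, `pauc`, `n_drugs`, `n_pos`, `n_neg` and the
#'   ROC coordinates `roc` (tibble `fpr`, `tpr`).
#' @export
roc_metrics <- function(ranking, truth, gt_threshold = 0.01) {
  joined <- dplyr::inner_join(
    as_tibble(ranking)[, c("drug_id", "score")],
    as_tibble(truth)[, c("drug_id", "p_value")],
    by = "drug_id"
  )
  joined <- joined[!is.na(joined$score), ]
  label <- joined$p_value < gt_threshold
  if (sum(label) == 0L || sum(!label) == 0L) {
    abort("Binarized ground truth is degenerate (needs >= 1 positive and >= 1 negative).")
  }
  roc <- roc_points(joined$score, label)
  list(
    auc = trapezoid_area(roc$fpr, roc$tpr),
    pauc = trapezoid_area(roc$fpr, roc$tpr, upper = 0.1),
    n_drugs = nrow(joined),
    n_pos = sum(label),
    n_neg = sum(!label),
    roc = roc
  )
}

#' Spearman correlation between prediction and ground truth
#'
#' Correlates predicted scores with ground-truth p-values over the drugs
#' common to both tables. Because small p-values mean likely differential
#' response, a good prediction yields a negative correlation.
#'
#' @inheritParams roc_metrics
#' @return A list with `rho`, `p_value`, `n_drugs`.
#' @export
rank_correlation <- function(ranking, truth) {
  joined <- dplyr::inner_join(
    as_tibble(ranking)[, c("drug_id", "score")],
    as_tibble(truth)[, c("drug_id", "p_value")],
    by = "drug_id"
  )
  joined <- joined[!is.na(joined$score), ]
  if (nrow(joined) < 3L) abort("Need >= 3 commonly ranked drugs.")
  ct <- suppressWarnings(
    stats::cor.test(joined$score, joined$p_value, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_drugs = nrow(joined))
}

#' Full evaluation of a drug ranking
#'
#' Combines [roc_metrics()] and [rank_correlation()] into one result object
#' with [generics::glance()], [generics::tidy()] and
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams roc_metrics
#' @return A `drug_eval` object.
#' @export
evaluate_ranking <- function(ranking, truth, gt_threshold = 0.01) {
  roc <- roc_metrics(ranking, truth, gt_threshold)
  cor <- rank_correlation(ranking, truth)
  structure(
    list(
      auc = roc$auc, pauc = roc$pauc,
      spearman_rho = cor$rho, spearman_p = cor$p_value,
      n_drugs = roc$n_drugs, n_pos = roc$n_pos, n_neg = roc$n_neg,
      gt_threshold = gt_threshold, roc = roc$roc
    ),
    class = "drug_eval"
  )
}

#' @export
print.drug_eval <- function(x, ...) {
  cat(sprintf(
    paste0(
      "# drug_eval: %d drugs (%d+/%d-), ground-truth threshold %.3g\n",
      "#   AUC %.3f | pAUC (FPR 0-0.1) %.4f | Spearman rho %.3f (p = %.3g)\n"
    ),
    x$n_drugs, x$n_pos, x$n_neg, x$gt_threshold,
    x$auc, x$pauc, x$spearman_rho, x$spearman_p
  ))
  invisible(x)
}

#' Weighted-PageRank baseline drug ranking
#'
#' A node-centric alternative to path-based differential scoring: weighted
#' PageRank is run on the undirected differential network using the
#' absolute differential edge scores as weights, and each drug is scored by
#' the mean PageRank of its mapped targets. Drugs with no target in the
#' network are unscored.
#'
#' @param diff A `differential_network`.
#' @param drug_targets A drug-target table.
#' @param damping PageRank damping factor, default 0.85.
#' @return A tibble with `drug_id`, `score`, `unscored`.
#' @export
pagerank_baseline <- function(diff, drug_targets, damping = 0.85) {
  stopifnot(inherits(diff, "differential_network"))
  drug_targets <- read_drug_targets(drug_targets)
  nodes <- attr(diff, "nodes")
  keys <- node_key(nodes$layer, nodes$feature)
  el <- data.frame(
    from = node_key(diff$layer_from, diff$from),
    to = node_key(diff$layer_to, diff$to),
    weight = abs(diff$diff)
  )
  el <- el[el$weight > 0, ] # zero-weight edges carry no transition mass
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = keys)
  pr <- igraph::page_rank(g, damping = damping, weights = igraph::E(g)$weight)$vector
  by_drug <- split(
    node_key(drug_targets$target_layer, drug_targets$target_id),
    drug_targets$drug_id
  )
  rows <- purrr::imap(by_drug, function(tk, drug) {
    tk <- intersect(unique(tk), keys)
    tibble(
      drug_id = drug,
      score = if (length(tk) == 0L) NA_real_ else mean(pr[tk]),
      unscored = length(tk) == 0L
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-dplyr::coalesce(out$score, -Inf), out$drug_id), ]
}
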