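# Differential network between conditions and differential drug response
# scoring with per-target explainability.

#' Contrast two conditions' integrated networks
#'
#' Takes the union of both edge sets; an edge absent from one condition
#' contributes a score of zero there, so condition-specific edges survive
#' into the differential network. The differential score of each edge is
#' `score_a - score_b`, with the first argument's condition listed first.
#' Nodes of either network are included.
#'
#' @param int_a,int_b `integrated_network`s of the two conditions, built
#'   from the same layer and connector configuration.
#' @return A `differential_network`: a tibble with the edge identity
#'   columns, per-condition scores `score_a`/`score_b`, the differential
#'   score `diff`, the `presence` of the edge (`"both"`, `"a_only"`,
#'   `"b_only"`) and the `computed` flag (integrated score computed in
#'   either condition).
#' @export
differential_network <- function(int_a, int_b) {
  stopifnot(inherits(int_a, "integrated_network"), inherits(int_b, "integrated_network"))
  if (!identical(attr(int_a, "max_path_length"), attr(int_b, "max_path_length"))) {
    abort("Both networks must use the same maximal path length.")
  }
  key_cols <- c("layer_from", "from", "layer_to", "to", "edge_type")
  a <- as_tibble(int_a)[, c(key_cols, "score", "computed")]
  b <- as_tibble(int_b)[, c(key_cols, "score", "computed")]
  joined <- dplyr::full_join(a, b, by = key_cols, suffix = c("_a", "_b"))
  joined$presence <- dplyr::case_when(
    is.na(joined$score_a) ~ "b_only",
    is.na(joined$score_b) ~ "a_only",
    TRUE ~ "both"
  )
  joined$score_a <- dplyr::coalesce(joined$score_a, 0)
  joined$score_b <- dplyr::coalesce(joined$score_b, 0)
  joined$computed <- dplyr::coalesce(joined$computed_a, FALSE) |
    dplyr::coalesce(joined$computed_b, FALSE)
  joined$diff <- joined$score_a - joined$score_b
  joined <- joined[, c(key_cols, "score_a", "score_b", "diff", "presence", "computed")]
  nodes <- dplyr::distinct(dplyr::bind_rows(attr(int_a, "nodes"), attr(int_b, "nodes")))
  structure(
    joined,
    condition_a = attr(int_a, "condition"),
    condition_b = attr(int_b, "condition"),
    nodes = nodes,
    class = c("differential_network", class(joined))
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "# differential_network: '%s' - '%s', %d nodes, %d edges\n",
    attr(x, "condition_a"), attr(x, "condition_b"), nrow(attr(x, "nodes")), nrow(x)
  ))
  NextMethod()
}

# rows of `diff` incident to any of the given node keys, each edge once
incident_edges <- function(diff, target_keys) {
  kf <- node_key(diff$layer_from, diff$from)
  kt <- node_key(diff$layer_to, diff$to)
  diff[kf %in% target_keys | kt %in% target_keys, ]
}

#' Differential drug response score for one target set
#'
#' The absolute value of the mean (default) or median of the differential
#' scores over the union of edges incident to any target node; each edge
#' enters once even when it touches two targets.
#'
#' @param diff A `differential_network`.
#' @param target_nodes Character vector of node keys (`"layer::feature"`).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return A list with `score` (`NA` when no incident edge exists, in which
#'   case the drug is unscored) and `n_edges`.
#' @export
drug_response_score <- function(diff, target_nodes, aggregator = c("mean", "median")) {
  stopifnot(inherits(diff, "differential_network"))
  aggregator <- match.arg(aggregator)
  inc <- incident_edges(diff, unique(target_nodes))
  if (nrow(inc) == 0L) {
    return(list(score = NA_real_, n_edges = 0L))
  }
  agg <- if (aggregator == "mean") mean(inc$diff) else stats::median(inc$diff)
  list(score = abs(agg), n_edges = nrow(inc))
}

#' Rank drugs by differential drug response score
#'
#' Every drug of the target table is scored via [drug_response_score()];
#' drugs without any edge incident to their mapped targets (including drugs
#' whose targets are absent from the network) are reported as unscored
#' rather than dropped, so evaluations can account for them. Scored drugs
#' are ranked by descending score, ties broken lexicographically by drug
#' identifier.
#'
#' @param diff A `differential_network`.
#' @param drug_targets A drug-target table (see [read_drug_targets()]).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return A `drug_ranking` tibble with columns `drug_id`, `score`,
#'   `n_edges`, `rank` (`NA` for unscored drugs) and `unscored`.
#' @export
rank_drugs <- function(diff, drug_targets, aggregator = c("mean", "median")) {
  stopifnot(inherits(diff, "differential_network"))
  aggregator <- match.arg(aggregator)
  drug_targets <- read_drug_targets(drug_targets)
  by_drug <- split(
    node_key(drug_targets$target_layer, drug_targets$target_id),
    drug_targets$drug_id
  )
  rows <- purrr::imap(by_drug, function(keys, drug) {
    s <- drug_response_score(diff, keys, aggregator)
    tibble(drug_id = drug, score = s$score, n_edges = s$n_edges)
  })
  tab <- dplyr::bind_rows(rows)
  tab$unscored <- is.na(tab$score)
  scored <- tab[!tab$unscored, ]
  scored <- scored[order(-scored$score, scored$drug_id), ]
  scored$rank <- seq_len(nrow(scored))
  unscored <- tab[tab$unscored, ]
  if (nrow(unscored) > 0L) {
    unscored$rank <- NA_integer_
    unscored <- unscored[order(unscored$drug_id), ]
  }
  out <- dplyr::bind_rows(scored, unscored)[, c("drug_id", "score", "n_edges", "rank", "unscored")]
  structure(
    out,
    aggregator = aggregator,
    condition_a = attr(diff, "condition_a"),
    condition_b = attr(diff, "condition_b"),
    class = c("drug_ranking", class(out))
  )
}

#' Trace a drug's differential score back to molecular edges
#'
#' For every target of the drug, lists the incident differential edges with
#' their per-condition integrated scores and the differential score, plus a
#' per-target summary (edge count, mean absolute differential). This is the
#' explainability view: it shows which target, and which molecular
#' interaction of that target, drives a high differential drug response
#' score. Targets without differential edges are summarized with zero
#' counts.
#'
#' @param diff A `differential_network`.
#' @param drug A drug identifier present in `drug_targets`.
#' @param drug_targets A drug-target table.
#' @return A `drug_explanation` object: list with `drug`, `edges` (columns
#'   `target`, `partner`, `edge_type`, `score_a`, `score_b`, `diff`),
#'   per-target `summary`, and the recomputed `score`/`n_edges` (mean
#'   aggregator, identical to [drug_response_score()] on the union of the
#'   listed edges).
#' @export
explain_drug <- function(diff, drug, drug_targets) {
  stopifnot(inherits(diff, "differential_network"))
  drug_targets <- read_drug_targets(drug_targets)
  dt <- drug_targets[drug_targets$drug_id == drug, ]
  if (nrow(dt) == 0L) abort(paste0("Unknown drug: ", drug))
  target_keys <- unique(node_key(dt$target_layer, dt$target_id))
  kf <- node_key(diff$layer_from, diff$from)
  kt <- node_key(diff$layer_to, diff$to)
  edges <- dplyr::bind_rows(purrr::map(target_keys, function(tk) {
    hit <- kf == tk | kt == tk
    inc <- diff[hit, ]
    partner <- ifelse(kf[hit] == tk, kt[hit], kf[hit])
    tibble(
      target = rep(tk, nrow(inc)), partner = partner,
      edge_type = inc$edge_type,
      score_a = inc$score_a, score_b = inc$score_b, diff = inc$diff
    )
  }))
  summary <- dplyr::bind_rows(purrr::map(target_keys, function(tk) {
    d <- edges$diff[edges$target == tk]
    tibble(target = tk, n_edges = length(d), mean_abs_diff = if (length(d)) mean(abs(d)) else 0)
  }))
  # union of incident edges, each once, reproduces the drug's score
  inc <- incident_edges(diff, target_keys)
  score <- if (nrow(inc) == 0L) NA_real_ else abs(mean(inc$diff))
  structure(
    list(
      drug = drug, targets = target_keys, edges = edges, summary = summary,
      score = score, n_edges = nrow(inc),
      condition_a = attr(diff, "condition_a"),
      condition_b = attr(diff, "condition_b")
    ),
    class = "drug_explanation"
  )
}

#' @export
print.drug_explanation <- function(x, ...) {
  cat(sprintf(
    "# drug_explanation: %s (%d targets, %d incident edges, score %s)\n",
    x$drug, length(x$targets), x$n_edges,
    if (is.na(x$score)) "unscored" else format(x$score, digits = 4)
  ))
  print(x$summary, ...)
  invisible(x)
}
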