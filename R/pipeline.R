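# End-to-end wrapper: omics matrices in, drug ranking out.

#' Run the full differential drug response pipeline
#'
#' Chains the individual steps for both conditions: correlation network per
#' layer, hard-threshold reduction (harmonized across conditions for the
#' scale-free criterion), multi-layer assembly with connectors, path-based
#' integration of edge scores, differential network, and drug ranking.
#'
#' @param omics_a,omics_b Named lists of [omics_matrix()] objects, one per
#'   layer, for the two conditions (same layer names in both).
#' @param drug_targets A drug-target table (see [read_drug_targets()]).
#' @param connectors List of `connector_spec` objects; `NULL` (default)
#'   links adjacent layers by same-name connectors of weight 1.
#' @param reduction List with element `method` plus its parameter
#'   (`target_degree`, `target_density`, or `r2_target`/`threshold_grid`),
#'   as in [reduce_network()]. Default: average degree 10.
#' @param correlation_method,min_pairs Passed to [correlation_network()].
#' @param max_path_length,restrict_to_targets Passed to
#'   [integrate_network()].
#' @param aggregator Passed to [rank_drugs()].
#' @return A `drug_pipeline` list with elements `layer_networks` (reduced,
#'   per condition), `multilayer`, `integrated`, `differential` and
#'   `ranking`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(
#'   layers = c(mrna = 40L, protein = 40L), n_samples = 20L,
#'   n_blocks = 4L, n_perturbed = 2L, n_drugs = 6L, seed = 7L
#' ))
#' res <- run_differential_pipeline(
#'   fx$omics[[1]], fx$omics[[2]], fx$drug_targets,
#'   reduction = list(method = "average_degree", target_degree = 6)
#' )
#' res$ranking
run_differential_pipeline <- function(omics_a, omics_b, drug_targets,
                                      connectors = NULL,
                                      reduction = list(method = "average_degree", target_degree = 10),
                                      correlation_method = "spearman",
                                      min_pairs = 5,
                                      max_path_length = 3,
                                      restrict_to_targets = TRUE,
                                      aggregator = "mean") {
  if (!identical(sort(names(omics_a)), sort(names(omics_b)))) {
    abort("The two conditions must provide the same layers.")
  }
  drug_targets <- read_drug_targets(drug_targets)
  if (is.null(connectors)) {
    lns <- names(omics_a)
    connectors <- purrr::map(
      seq_len(max(length(lns) - 1L, 0L)),
      function(i) connector_same_name(lns[i], lns[i + 1L], weight = 1)
    )
  }

  nets_a <- purrr::map(omics_a, correlation_network, method = correlation_method, min_pairs = min_pairs)
  nets_b <- purrr::map(omics_b, correlation_network, method = correlation_method, min_pairs = min_pairs)

  if (identical(reduction$method, "scale_free")) {
    harm <- purrr::map(names(nets_a), function(ln) {
      do.call(harmonize_scale_free, c(
        list(net_a = nets_a[[ln]], net_b = nets_b[[ln]]),
        reduction[intersect(names(reduction), c("r2_target", "threshold_grid", "relax_step"))]
      ))
    })
    red_a <- stats::setNames(purrr::map(harm, "net_a"), names(nets_a))
    red_b <- stats::setNames(purrr::map(harm, "net_b"), names(nets_a))
  } else {
    reduce_one <- function(net) do.call(reduce_network, c(list(net = net), reduction))
    red_a <- purrr::map(nets_a, reduce_one)
    red_b <- purrr::map(nets_b, reduce_one)
  }

  ml_a <- assemble_multilayer(red_a, connectors)
  ml_b <- assemble_multilayer(red_b, connectors)
  int_a <- integrate_network(ml_a, drug_targets, max_path_length, restrict_to_targets)
  int_b <- integrate_network(ml_b, drug_targets, max_path_length, restrict_to_targets)
  diff <- differential_network(int_a, int_b)
  ranking <- rank_drugs(diff, drug_targets, aggregator)

  structure(
    list(
      layer_networks = list(a = red_a, b = red_b),
      multilayer = list(a = ml_a, b = ml_b),
      integrated = list(a = int_a, b = int_b),
      differential = diff,
      ranking = ranking
    ),
    class = "drug_pipeline"
  )
}

#' @export
print.drug_pipeline <- function(x, ...) {
  cat(sprintf(
    "# drug_pipeline: '%s' vs '%s', %d differential edges, %d/%d drugs scored\n",
    attr(x$differential, "condition_a"), attr(x$differential, "condition_b"),
    nrow(x$differential), sum(!x$ranking$unscored), nrow(x$ranking)
  ))
  print(utils::head(as_tibble(x$ranking), 10L))
  invisible(x)
}
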