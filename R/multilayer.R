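# Assembly of per-layer networks into one heterogeneous multi-layer network.

#' Connector specifications between two omics layers
#'
#' Inter-layer edges encode prior knowledge and come in two flavours:
#' `connector_same_name()` joins nodes carrying the identical feature name
#' in two layers with a fixed weight (the central-dogma style mRNA-protein
#' or protein-phosphosite correspondence), while `connector_pairs()` joins
#' explicitly listed feature pairs with per-pair weights (e.g.
#' protein-metabolite links scored by an interaction database).
#'
#' @param layer_a,layer_b The two distinct layer names to connect.
#' @param weight Fixed edge weight for same-name connectors, default 1.
#' @param pairs For `connector_pairs()`: a data frame with columns
#'   `layer_a`, `node_a`, `layer_b`, `node_b`, `weight`.
#' @return A `connector_spec` object consumed by [assemble_multilayer()].
#' @export
connector_same_name <- function(layer_a, layer_b, weight = 1) {
  if (identical(layer_a, layer_b)) abort("Connector layers must differ.")
  structure(
    list(mode = "same_name", layer_a = layer_a, layer_b = layer_b, weight = weight),
    class = "connector_spec"
  )
}

#' @rdname connector_same_name
#' @export
connector_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  need <- c("layer_a", "node_a", "layer_b", "node_b", "weight")
  if (!all(need %in% names(pairs))) {
    abort(paste0("Connector pair table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(pairs$weight))) abort("Connector pair weights must be finite.")
  if (any(pairs$layer_a == pairs$layer_b)) abort("Connector layers must differ.")
  structure(list(mode = "pair_table", pairs = pairs[, need]), class = "connector_spec")
}

#' Same-name inter-layer edges
#'
#' @param layers Named list of `layer_network`s (names = layer names).
#' @param layer_a,layer_b Layer names to connect.
#' @param weight Fixed weight assigned to every connector edge.
#' @return A tibble of inter-layer edges (`layer_from`, `from`, `layer_to`,
#'   `to`, `weight`, `edge_type`), one per feature name present in both
#'   layers.
#' @export
connect_same_name <- function(layers, layer_a, layer_b, weight = 1) {
  for (ln in c(layer_a, layer_b)) {
    if (ln %not_in% names(layers)) abort(paste0("Unknown layer: ", ln))
  }
  shared <- intersect(network_nodes(layers[[layer_a]]), network_nodes(layers[[layer_b]]))
  tibble(
    layer_from = rep(layer_a, length(shared)), from = shared,
    layer_to = rep(layer_b, length(shared)), to = shared,
    weight = rep(as.numeric(weight), length(shared)),
    edge_type = rep(paste(layer_a, layer_b, sep = "-"), length(shared))
  )
}

#' Pair-table inter-layer edges
#'
#' Pairs whose endpoints are absent from the given layers are skipped; the
#' number skipped is reported and attached as attribute `n_skipped`.
#'
#' @param layers Named list of `layer_network`s.
#' @param spec A `connector_spec` from [connector_pairs()].
#' @return A tibble of inter-layer edges as in [connect_same_name()].
#' @export
connect_pairs <- function(layers, spec) {
  stopifnot(inherits(spec, "connector_spec"), spec$mode == "pair_table")
  p <- spec$pairs
  for (ln in unique(c(p$layer_a, p$layer_b))) {
    if (ln %not_in% names(layers)) abort(paste0("Unknown layer: ", ln))
  }
  present <- function(layer, node) {
    mapply(function(l, f) f %in% network_nodes(layers[[l]]), layer, node, USE.NAMES = FALSE)
  }
  ok <- if (nrow(p) == 0L) logical(0) else present(p$layer_a, p$node_a) & present(p$layer_b, p$node_b)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    inform(sprintf("Skipped %d connector pair(s) with endpoints absent from the layers.", n_skipped))
  }
  p <- p[ok, ]
  out <- tibble(
    layer_from = p$layer_a, from = p$node_a,
    layer_to = p$layer_b, to = p$node_b,
    weight = p$weight,
    edge_type = paste(p$layer_a, p$layer_b, sep = "-")
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

# orient every edge so that key(from) <= key(to); keys are unique per node
canonicalize_edges <- function(edges) {
  ka <- node_key(edges$layer_from, edges$from)
  kb <- node_key(edges$layer_to, edges$to)
  flip <- ka > kb
  if (any(flip)) {
    tmp_l <- edges$layer_from[flip]
    tmp_f <- edges$from[flip]
    edges$layer_from[flip] <- edges$layer_to[flip]
    edges$from[flip] <- edges$to[flip]
    edges$layer_to[flip] <- tmp_l
    edges$to[flip] <- tmp_f
  }
  edges
}

#' Assemble a heterogeneous multi-layer network for one condition
#'
#' Nodes are (layer, feature) pairs — the same feature name in two layers is
#' two distinct nodes. Intra-layer edges carry the (reduced) correlation
#' weights unchanged and are tagged with their layer name as `edge_type`;
#' inter-layer edges come from the connector specifications. The graph is
#' undirected and simple: a duplicate connector edge is an error. Connector
#' weights outside \[-1, 1\] trigger a warning because the path-integration
#' score bound assumes weights in that range.
#'
#' @param layers Named list of `layer_network`s, all of the same condition.
#' @param connectors List of `connector_spec` objects (see
#'   [connector_same_name()] and [connector_pairs()]).
#' @return A `multilayer_network`: a tibble of edges (`layer_from`, `from`,
#'   `layer_to`, `to`, `weight`, `edge_type`) with the condition label and a
#'   node table (`layer`, `feature`) as attributes.
#' @export
assemble_multilayer <- function(layers, connectors = list()) {
  stopifnot(length(layers) >= 1L)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- vapply(layers, function(l) attr(l, "layer"), character(1))
  }
  conds <- unique(vapply(layers, function(l) attr(l, "condition"), character(1)))
  if (length(conds) != 1L) {
    abort(paste0("All layers must share one condition; got: ", paste(conds, collapse = ", ")))
  }
  if (inherits(connectors, "connector_spec")) connectors <- list(connectors)

  intra <- purrr::imap(layers, function(net, ln) {
    tibble(
      layer_from = rep(ln, nrow(net)), from = net$from,
      layer_to = rep(ln, nrow(net)), to = net$to,
      weight = net$weight, edge_type = rep(ln, nrow(net))
    )
  })
  inter <- purrr::map(connectors, function(spec) {
    stopifnot(inherits(spec, "connector_spec"))
    if (spec$mode == "same_name") {
      connect_same_name(layers, spec$layer_a, spec$layer_b, spec$weight)
    } else {
      connect_pairs(layers, spec)
    }
  })
  edges <- canonicalize_edges(dplyr::bind_rows(c(intra, inter)))
  keys <- edge_pair_key(
    node_key(edges$layer_from, edges$from),
    node_key(edges$layer_to, edges$to)
  )
  if (anyDuplicated(keys)) {
    abort("Duplicate edges produced by the connector specifications; multigraphs are not allowed.")
  }
  if (nrow(edges) > 0L && any(abs(edges$weight) > 1)) {
    warn("Some edge weights lie outside [-1, 1]; integrated scores may exceed the nominal bound.")
  }
  nodes <- dplyr::bind_rows(purrr::imap(layers, function(net, ln) {
    tibble(layer = rep(ln, length(network_nodes(net))), feature = network_nodes(net))
  }))
  edges <- edges[order(keys), ]
  structure(
    edges,
    condition = conds, nodes = nodes,
    class = c("multilayer_network", class(edges))
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(
    "# multilayer_network: condition '%s', %d nodes (%d layers), %d edges\n",
    attr(x, "condition"), nrow(attr(x, "nodes")),
    length(unique(attr(x, "nodes")$layer)), nrow(x)
  ))
  NextMethod()
}
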