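# Semi-local integrated interaction scores: an edge's weight is replaced by
# the sum, over path lengths 1..L, of the mean product-of-weights over all
# simple paths of that length joining the edge's endpoints. The direct edge
# is the single length-1 path, so L = 1 leaves weights unchanged, and with
# all |weights| <= 1 every score lies in [-L, L].

# adjacency lists over integer node ids; nodes = character keys
build_adjacency <- function(net) {
  nodes <- attr(net, "nodes", exact = TRUE)
  keys <- node_key(nodes$layer, nodes$feature)
  idx <- stats::setNames(seq_along(keys), keys)
  ei <- unname(idx[node_key(net$layer_from, net$from)])
  ej <- unname(idx[node_key(net$layer_to, net$to)])
  n <- length(keys)
  adj <- vector("list", n)
  wts <- vector("list", n)
  ends <- c(ei, ej)
  others <- c(ej, ei)
  w2 <- c(net$weight, net$weight)
  ord <- order(ends)
  ends <- ends[ord]
  others <- others[ord]
  w2 <- w2[ord]
  runs <- split(seq_along(ends), ends)
  for (nm in names(runs)) {
    i <- as.integer(nm)
    adj[[i]] <- others[runs[[nm]]]
    wts[[i]] <- w2[runs[[nm]]]
  }
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer(0))
  wts[empty] <- list(numeric(0))
  list(keys = keys, idx = idx, adj = adj, wts = wts, ei = ei, ej = ej)
}

# bounded DFS accumulating, per path length, the sum of weight products and
# the number of simple u->v paths; started from the lower-degree endpoint
score_pair_dfs <- function(g, u, v, max_len) {
  if (length(g$adj[[v]]) < length(g$adj[[u]])) {
    tmp <- u
    u <- v
    v <- tmp
  }
  sums <- numeric(max_len)
  cnts <- integer(max_len)
  visited <- logical(length(g$adj))
  visited[u] <- TRUE
  recurse <- function(node, depth, prod) {
    nb <- g$adj[[node]]
    ww <- g$wts[[node]]
    for (i in seq_along(nb)) {
      nxt <- nb[i]
      if (nxt == v) {
        sums[depth + 1L] <<- sums[depth + 1L] + prod * ww[i]
        cnts[depth + 1L] <<- cnts[depth + 1L] + 1L
      } else if (depth + 1L < max_len && !visited[nxt]) {
        visited[nxt] <<- TRUE
        recurse(nxt, depth + 1L, prod * ww[i])
        visited[nxt] <<- FALSE
      }
    }
  }
  recurse(u, 0L, 1)
  sum(sums[cnts > 0L] / cnts[cnts > 0L])
}

resolve_node <- function(g, node) {
  if (node %not_in% names(g$idx)) {
    abort(paste0("Unknown node: ", node, " (use 'layer::feature' keys)."))
  }
  unname(g$idx[node])
}

#' Enumerate simple paths of a fixed length between two nodes
#'
#' A path of length `l` uses exactly `l` edges and visits no node twice.
#' Each geometrically distinct path is reported once, oriented from `u` to
#' `v`.
#'
#' @param net A `multilayer_network`.
#' @param u,v Distinct node keys of the form `"layer::feature"`.
#' @param length Path length (number of edges), a positive integer.
#' @return A list of character vectors, each a node-key sequence of
#'   `length + 1` nodes from `u` to `v`; empty list if no such path exists.
#' @export
enumerate_simple_paths <- function(net, u, v, length) {
  stopifnot(length >= 1L)
  if (identical(u, v)) abort("`u` and `v` must differ.")
  g <- build_adjacency(net)
  ui <- resolve_node(g, u)
  vi <- resolve_node(g, v)
  paths <- list()
  visited <- logical(base::length(g$adj))
  visited[ui] <- TRUE
  recurse <- function(node, trail, depth) {
    for (nxt in g$adj[[node]]) {
      if (nxt == vi) {
        if (depth + 1L == length) paths[[base::length(paths) + 1L]] <<- c(trail, vi)
      } else if (depth + 1L < length && !visited[nxt]) {
        visited[nxt] <<- TRUE
        recurse(nxt, c(trail, nxt), depth + 1L)
        visited[nxt] <<- FALSE
      }
    }
  }
  recurse(ui, ui, 0L)
  lapply(paths, function(p) g$keys[p])
}

#' Integrated interaction score of a single edge
#'
#' @param net A `multilayer_network` containing the edge `(u, v)`.
#' @param u,v Node keys (`"layer::feature"`) of an existing edge.
#' @param max_path_length Maximal path length L considered, default 3.
#' @return The integrated interaction score: the sum over path lengths
#'   `1..max_path_length` of the mean product-of-weights over all simple
#'   paths of that length joining `u` and `v`; lengths with no path
#'   contribute 0.
#' @export
integrated_edge_score <- function(net, u, v, max_path_length = 3) {
  stopifnot(max_path_length >= 1L)
  g <- build_adjacency(net)
  ui <- resolve_node(g, u)
  vi <- resolve_node(g, v)
  if (!any((g$ei == ui & g$ej == vi) | (g$ei == vi & g$ej == ui))) {
    abort(paste0("No edge between ", u, " and ", v, "."))
  }
  score_pair_dfs(g, ui, vi, as.integer(max_path_length))
}

#' Replace edge weights by integrated interaction scores
#'
#' Computes the integrated interaction score for every edge incident to a
#' drug target (the default, which keeps run time proportional to the
#' drug-relevant part of the network), or for every edge when
#' `restrict_to_targets = FALSE`. Edges whose score is not computed retain
#' their raw weight and are flagged accordingly; downstream drug scoring
#' only ever reads target-incident edges, so un-computed raw weights never
#' leak into drug scores.
#'
#' @param net A `multilayer_network`.
#' @param targets A drug-target table (see [read_drug_targets()]) or `NULL`.
#' @param max_path_length Maximal path length L, default 3.
#' @param restrict_to_targets If `TRUE` (default), only score edges incident
#'   to a target node; requires at least one target mapping into the
#'   network.
#' @return An `integrated_network`: the edge tibble of `net` extended with
#'   `score` and a logical `computed` flag.
#' @export
integrate_network <- function(net, targets = NULL, max_path_length = 3,
                              restrict_to_targets = TRUE) {
  stopifnot(inherits(net, "multilayer_network"), max_path_length >= 1L)
  g <- build_adjacency(net)
  if (restrict_to_targets) {
    if (is.null(targets)) {
      abort("`restrict_to_targets = TRUE` requires a drug-target table.")
    }
    tkeys <- unique(node_key(targets$target_layer, targets$target_id))
    tids <- unname(g$idx[intersect(tkeys, names(g$idx))])
    if (length(tids) == 0L) {
      abort("No drug target maps to a node of the network.")
    }
    compute <- (g$ei %in% tids) | (g$ej %in% tids)
  } else {
    compute <- rep(TRUE, nrow(net))
  }
  L <- as.integer(max_path_length)
  score <- net$weight
  score[compute] <- vapply(
    which(compute),
    function(e) score_pair_dfs(g, g$ei[e], g$ej[e], L),
    numeric(1)
  )
  out <- as_tibble(net)
  out$score <- score
  out$computed <- compute
  structure(
    out,
    condition = attr(net, "condition"),
    nodes = attr(net, "nodes"),
    max_path_length = L,
    restricted = restrict_to_targets,
    class = c("integrated_network", class(out))
  )
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf(
    "# integrated_network: condition '%s', %d edges (%d scored, L = %d)\n",
    attr(x, "condition"), nrow(x), sum(x$computed), attr(x, "max_path_length")
  ))
  NextMethod()
}
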