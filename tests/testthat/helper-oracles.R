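# Shared builders and independent oracles used across test files.

# one-layer multilayer network from a plain weighted edge list
ml_from_edges <- function(edges, layer = "x", condition = "A", nodes = NULL) {
  assemble_multilayer(
    list(layer_network(edges, layer = layer, condition = condition, nodes = nodes))
  )
}

mlkey <- function(feature, layer = "x") paste(layer, feature, sep = "::")

# Erdos-Renyi weighted graph with weights ~ U[-1, 1]; caller controls the seed
random_edge_table <- function(n_nodes, p_edge = 0.5) {
  pairs <- t(utils::combn(sprintf("n%02d", seq_len(n_nodes)), 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  tibble::tibble(
    from = pairs[keep, 1],
    to = pairs[keep, 2],
    weight = stats::runif(sum(keep), -1, 1)
  )
}

# brute-force integrated score: enumerate simple paths with igraph and
# average their weight products per length (independent of the package DFS)
brute_force_score <- function(ml, u, v, max_len) {
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = paste(ml$layer_from, ml$from, sep = "::"),
      to = paste(ml$layer_to, ml$to, sep = "::"),
      weight = ml$weight
    ),
    directed = FALSE
  )
  total <- 0
  for (l in seq_len(max_len)) {
    paths <- igraph::all_simple_paths(g, from = u, to = v, cutoff = l)
    paths <- paths[lengths(paths) == l + 1]
    if (length(paths) == 0) next
    prods <- vapply(
      paths,
      function(p) prod(igraph::E(g, path = p)$weight),
      numeric(1)
    )
    total <- total + mean(prods)
  }
  total
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
mwu_exact_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  n <- length(xa)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  u_all <- apply(utils::combn(length(pooled), n), 2, u_stat)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# weighted PageRank by dense power iteration
power_iteration_pagerank <- function(edges, nodes, damping = 0.85, tol = 1e-12) {
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    w[edges$from[i], edges$to[i]] <- w[edges$from[i], edges$to[i]] + edges$weight[i]
    w[edges$to[i], edges$from[i]] <- w[edges$to[i], edges$from[i]] + edges$weight[i]
  }
  strength <- rowSums(w)
  trans <- w / ifelse(strength > 0, strength, 1)
  pr <- rep(1 / n, n)
  repeat {
    nxt <- (1 - damping) / n + damping * as.vector(t(trans) %*% pr)
    if (max(abs(nxt - pr)) < tol) break
    pr <- nxt
  }
  stats::setNames(nxt, nodes)
}

# small but complete fixture for fast end-to-end tests
small_fixture_spec <- function(seed = 11L, ...) {
  fixture_spec(
    layers = c(mrna = 60L, protein = 60L),
    n_samples = 25L, n_blocks = 6L, n_perturbed = 3L,
    n_drugs = 12L, targets_per_drug = 2L,
    seed = seed, ...
  )
}
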