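# Condition-specific single-layer correlation networks and their reduction.

#' Construct a single-layer network from an edge table
#'
#' Mostly produced by [correlation_network()], but networks from other
#' sources (e.g. a curated interaction resource) can be supplied directly.
#' The graph is undirected and simple: no self-loops, each unordered
#' feature pair at most once, weights finite and in \[-1, 1\].
#'
#' @param edges A data frame with columns `from`, `to`, `weight`.
#' @param layer Layer name.
#' @param condition Condition label.
#' @param nodes Optional character vector of all features (to represent
#'   isolated nodes); defaults to the features appearing in `edges`.
#' @return A `layer_network` tibble with attributes `layer`, `condition`,
#'   `nodes`.
#' @export
layer_network <- function(edges, layer, condition, nodes = NULL) {
  edges <- as_tibble(edges)
  need <- c("from", "to", "weight")
  if (!all(need %in% names(edges))) {
    abort("`edges` needs columns from, to, weight.")
  }
  edges <- edges[, need]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
  if (any(!is.finite(edges$weight))) abort("Edge weights must be finite.")
  if (any(abs(edges$weight) > 1)) abort("Layer edge weights must lie in [-1, 1].")
  pair <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
  if (anyDuplicated(pair)) abort("Each unordered feature pair may appear at most once.")
  nodes <- nodes %||% unique(c(edges$from, edges$to))
  if (anyDuplicated(nodes)) abort("Duplicate node identifiers.")
  missing_nodes <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing_nodes) > 0L) {
    abort(paste0("Edges reference features absent from `nodes`: ", missing_nodes[1L]))
  }
  new_layer_network(edges, layer, condition, nodes)
}

new_layer_network <- function(edges, layer, condition, nodes) {
  structure(
    as_tibble(edges),
    layer = layer, condition = condition, nodes = nodes,
    class = c("layer_network", class(as_tibble(edges)))
  )
}

#' @export
print.layer_network <- function(x, ...) {
  cat(sprintf(
    "# layer_network: layer '%s', condition '%s', %d nodes, %d edges\n",
    attr(x, "layer"), attr(x, "condition"), length(attr(x, "nodes")), nrow(x)
  ))
  NextMethod()
}

#' Nodes of a network object
#'
#' @param net A `layer_network` (character vector of feature identifiers,
#'   including isolated features) or a `multilayer_network` (tibble with
#'   columns `layer`, `feature`).
#' @return The node set carried by the object.
#' @export
network_nodes <- function(net) attr(net, "nodes", exact = TRUE)

#' Build a correlation network for one layer and condition
#'
#' Every pair of features is connected by an edge weighted with the
#' correlation of their abundance profiles over the condition's samples
#' (Spearman by default, robust to outliers and monotone nonlinearity).
#' With missing values, each pair's correlation uses its pairwise-complete
#' observations; pairs with fewer than `min_pairs` complete observations, or
#' with undefined correlation (zero variance), carry no edge.
#'
#' @param m An [omics_matrix()] with at least 2 features and 2 samples.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @param min_pairs Minimal number of pairwise-complete observations for an
#'   edge, default 5.
#' @return A `layer_network`: a tibble of edges (`from`, `to`, `weight` in
#'   \[-1, 1\]) carrying the layer, condition and full node set as
#'   attributes.
#' @export
correlation_network <- function(m, method = c("spearman", "pearson"), min_pairs = 5) {
  stopifnot(inherits(m, "omics_matrix"))
  method <- match.arg(method)
  v <- omics_values(m)
  if (nrow(v) < 2L) abort("Need at least 2 features to build a network.")
  if (ncol(v) < 2L) abort("Need at least 2 samples to build a network.")
  cmat <- suppressWarnings(
    stats::cor(t(v), method = method, use = "pairwise.complete.obs")
  )
  n_obs <- tcrossprod(!is.na(v)) # complete observations per feature pair
  cmat[n_obs < min_pairs] <- NA_real_
  keep <- which(upper.tri(cmat) & !is.na(cmat), arr.ind = TRUE)
  edges <- tibble(
    from = rownames(v)[keep[, 1L]],
    to = rownames(v)[keep[, 2L]],
    weight = cmat[keep]
  )
  new_layer_network(edges, layer_name(m), condition_label(m), rownames(v))
}

# keep the k largest-|weight| edges; ties at the implied cut are all kept
keep_top_edges <- function(net, k) {
  k <- as.integer(round(k))
  if (k >= nrow(net)) {
    if (k > nrow(net)) {
      warn(sprintf(
        "Reduction target implies %d edges but only %d exist; keeping all.",
        k, nrow(net)
      ))
    }
    return(net)
  }
  if (k <= 0L) {
    return(new_layer_network(net[0L, ], attr(net, "layer"), attr(net, "condition"), network_nodes(net)))
  }
  aw <- sort(abs(net$weight), decreasing = TRUE)
  cut <- aw[k]
  new_layer_network(
    net[abs(net$weight) >= cut, ],
    attr(net, "layer"), attr(net, "condition"), network_nodes(net)
  )
}

#' Reduce a correlation network by hard thresholding
#'
#' Keeps only edges with the largest absolute weights — strong negative
#' correlations survive alongside strong positive ones, and retained weights
#' keep their sign. The threshold is set by one of three criteria:
#' `"average_degree"` keeps `round(n * target_degree / 2)` edges,
#' `"density"` keeps `round(target_density * n * (n - 1) / 2)` edges, and
#' `"scale_free"` searches `threshold_grid` for the smallest absolute-weight
#' cut whose reduced degree distribution reaches a signed scale-free fit
#' R^2 of at least `r2_target` (see [fit_scale_free_r2()]).
#'
#' Ties at a count-based cut are all kept, so the target count may be
#' slightly exceeded; this makes the reduction deterministic and
#' order-independent.
#'
#' @param net A `layer_network` from [correlation_network()].
#' @param method Reduction criterion.
#' @param target_degree Desired average node degree (for `"average_degree"`).
#' @param target_density Desired fraction of possible edges (for `"density"`).
#' @param r2_target Minimal signed R^2 of the scale-free fit (for
#'   `"scale_free"`), default 0.8.
#' @param threshold_grid Ascending candidate absolute-weight cuts for the
#'   scale-free search.
#' @return A reduced `layer_network` over the same node set.
#' @export
reduce_network <- function(net,
                           method = c("average_degree", "density", "scale_free"),
                           target_degree = NULL,
                           target_density = NULL,
                           r2_target = 0.8,
                           threshold_grid = seq(0.1, 0.9, by = 0.02)) {
  stopifnot(inherits(net, "layer_network"))
  method <- match.arg(method)
  if (nrow(net) == 0L) abort("Cannot reduce an empty network.")
  n <- length(network_nodes(net))
  if (method == "average_degree") {
    if (is.null(target_degree) || target_degree <= 0) {
      abort("`target_degree` must be a positive number.")
    }
    return(keep_top_edges(net, round(n * target_degree / 2)))
  }
  if (method == "density") {
    if (is.null(target_density) || target_density < 0 || target_density > 1) {
      abort("`target_density` must be a fraction in [0, 1].")
    }
    return(keep_top_edges(net, round(target_density * n * (n - 1) / 2)))
  }
  # scale_free: pick the smallest cut reaching r2_target, else the best fit
  fits <- grid_scale_free_fits(net, threshold_grid)
  if (all(is.na(fits$signed_r2))) {
    abort("No grid cut yields a degree distribution with >= 2 occupied bins.")
  }
  qualifying <- which(!is.na(fits$signed_r2) & fits$signed_r2 >= r2_target)
  cut <- if (length(qualifying) > 0L) {
    fits$cut[qualifying[1L]]
  } else {
    warn(sprintf(
      "No cut reaches signed R^2 >= %.2f; using the best-fitting cut.", r2_target
    ))
    fits$cut[which.max(fits$signed_r2)]
  }
  cut_network(net, cut)
}

cut_network <- function(net, cut) {
  new_layer_network(
    net[abs(net$weight) >= cut, ],
    attr(net, "layer"), attr(net, "condition"), network_nodes(net)
  )
}

#' Degree histogram of a network
#'
#' @param net A `layer_network`.
#' @return A tibble with columns `degree` and `count` over occupied positive
#'   degrees (isolated nodes do not contribute).
#' @export
degree_histogram <- function(net) {
  deg <- table(c(net$from, net$to))
  tab <- table(as.integer(deg))
  tibble(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Goodness of fit to a scale-free degree distribution
#'
#' Regresses `log10 p(k)` on `log10 k` over the occupied degree bins of a
#' degree histogram (no log-binning) and returns the fit's R^2, signed
#' negative when the regression slope is positive — a decaying degree
#' distribution is the scale-free signature, so an "anti-scale-free" rising
#' distribution must not count as a good fit.
#'
#' @param degree_counts A data frame with columns `degree` and `count` (as
#'   from [degree_histogram()]), or a named numeric vector mapping degree to
#'   count.
#' @return A list with `signed_r2` (in \[-1, 1\]) and `slope`.
#' @export
#' @examples
#' fit_scale_free_r2(c(`1` = 8, `2` = 4, `4` = 2, `8` = 1))
fit_scale_free_r2 <- function(degree_counts) {
  if (is.data.frame(degree_counts)) {
    k <- as.numeric(degree_counts$degree)
    cnt <- as.numeric(degree_counts$count)
  } else {
    k <- as.numeric(names(degree_counts))
    cnt <- as.numeric(degree_counts)
  }
  ok <- !is.na(k) & k > 0 & cnt > 0
  k <- k[ok]
  cnt <- cnt[ok]
  if (length(unique(k)) < 2L) {
    abort("Scale-free fit needs >= 2 distinct occupied positive degrees.")
  }
  p <- cnt / sum(cnt)
  fit <- stats::lm(log10(p) ~ log10(k))
  slope <- unname(stats::coef(fit)[2L])
  # exact power laws fit perfectly; the summary()-internal warning about it
  # is expected, not a problem
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(signed_r2 = if (slope > 0) -r2 else r2, slope = slope)
}

# signed R^2 for every grid cut; NA where the fit is undefined
grid_scale_free_fits <- function(net, threshold_grid) {
  aw <- abs(net$weight)
  res <- purrr::map(threshold_grid, function(cut) {
    sub <- net[aw >= cut, c("from", "to")]
    if (nrow(sub) == 0L) {
      return(list(signed_r2 = NA_real_, n_edges = 0L))
    }
    hist <- degree_histogram(new_layer_network(
      cbind(sub, weight = 1), attr(net, "layer"), attr(net, "condition"),
      network_nodes(net)
    ))
    r2 <- tryCatch(fit_scale_free_r2(hist)$signed_r2, error = function(e) NA_real_)
    list(signed_r2 = r2, n_edges = nrow(sub))
  })
  tibble(
    cut = threshold_grid,
    signed_r2 = purrr::map_dbl(res, "signed_r2"),
    n_edges = purrr::map_int(res, ~ as.integer(.x$n_edges))
  )
}

#' Jointly threshold two conditions' networks by scale-free fit
#'
#' The two conditions of one layer are reduced with (possibly different)
#' absolute-weight cuts chosen so that both reduced networks reach the
#' scale-free fit target while their edge counts stay as similar as possible
#' — a size imbalance between conditions would otherwise bias the
#' differential comparison. Among all grid cut pairs whose reduced networks
#' reach `signed_r2 >= r2_target` in both conditions, the pair minimizing
#' the edge-count difference is chosen (ties: smallest cut for A, then for
#' B). If no pair qualifies, the target is relaxed in steps of `relax_step`
#' with a warning.
#'
#' @param net_a,net_b `layer_network`s of the same layer, one per condition.
#' @param r2_target Minimal signed R^2, default 0.8.
#' @param threshold_grid Ascending candidate cuts in (0, 1).
#' @param relax_step Decrement applied to `r2_target` when no cut pair
#'   qualifies, default 0.05.
#' @return A list with `cut_a`, `cut_b`, the reduced networks `net_a`,
#'   `net_b`, and `r2_target_used`.
#' @export
harmonize_scale_free <- function(net_a, net_b, r2_target = 0.8,
                                 threshold_grid = seq(0.1, 0.9, by = 0.02),
                                 relax_step = 0.05) {
  stopifnot(inherits(net_a, "layer_network"), inherits(net_b, "layer_network"))
  if (!identical(attr(net_a, "layer"), attr(net_b, "layer"))) {
    abort("Both networks must belong to the same layer.")
  }
  if (length(threshold_grid) == 0L) abort("`threshold_grid` is empty.")
  fits_a <- grid_scale_free_fits(net_a, threshold_grid)
  fits_b <- grid_scale_free_fits(net_b, threshold_grid)
  if (all(is.na(fits_a$signed_r2)) || all(is.na(fits_b$signed_r2))) {
    abort("A network has no grid cut with a defined scale-free fit.")
  }
  target <- r2_target
  repeat {
    ok_a <- which(!is.na(fits_a$signed_r2) & fits_a$signed_r2 >= target)
    ok_b <- which(!is.na(fits_b$signed_r2) & fits_b$signed_r2 >= target)
    if (length(ok_a) > 0L && length(ok_b) > 0L) break
    target <- target - relax_step
    warn(sprintf("No qualifying cut pair; relaxing R^2 target to %.2f.", target))
    if (target < -1) abort("Scale-free harmonization failed even with a fully relaxed target.")
  }
  grid <- expand.grid(ia = ok_a, ib = ok_b)
  gap <- abs(fits_a$n_edges[grid$ia] - fits_b$n_edges[grid$ib])
  # min gap; ties broken by smallest cut for A, then for B
  ord <- order(gap, fits_a$cut[grid$ia], fits_b$cut[grid$ib])
  best <- grid[ord[1L], ]
  list(
    cut_a = fits_a$cut[best$ia],
    cut_b = fits_b$cut[best$ib],
    net_a = cut_network(net_a, fits_a$cut[best$ia]),
    net_b = cut_network(net_b, fits_b$cut[best$ib]),
    r2_target_used = target
  )
}
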