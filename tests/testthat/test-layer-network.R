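# Correlation networks, hard-threshold reduction and scale-free fitting.

cor_matrix_of <- function(net) {
  w <- stats::setNames(net$weight, paste(net$from, net$to))
  w
}

test_that("spearman correlation network reproduces hand-derived weights", {
  m <- toy_cor_matrix <- omics_matrix(
    data.frame(
      feature = c("f1", "f2", "f3", "f4"),
      s1 = c(1, 2, 4, 1), s2 = c(2, 4, 3, 3),
      s3 = c(3, 6, 2, 2), s4 = c(4, 8, 1, 4)
    ),
    "mrna", "A"
  )
  net <- correlation_network(m, min_pairs = 3)
  w <- cor_matrix_of(net)
  expect_equal(unname(w["f1 f2"]), 1) # monotone identical ranks
  expect_equal(unname(w["f1 f3"]), -1) # reversed ranks
  # ranks of f4 vs f1 differ by d = (0, 1, 1, 0): 1 - 6*2 / (4*15) = 0.8
  expect_equal(unname(w["f1 f4"]), 0.8)
})

test_that("pairwise-complete observations drive correlations with missing data", {
  m <- omics_matrix(
    data.frame(
      feature = c("f1", "f2"),
      s1 = c(1, 2), s2 = c(2, 4), s3 = c(NA, 6), s4 = c(4, 8)
    ),
    "mrna", "A"
  )
  net <- correlation_network(m, min_pairs = 3)
  expect_equal(net$weight, 1) # 3 complete pairs, perfectly monotone
  # with min_pairs above the number of complete observations the edge is gone
  expect_identical(nrow(correlation_network(m, min_pairs = 4)), 0L)
})

test_that("zero-variance features and too-small inputs are handled", {
  m <- omics_matrix(
    data.frame(feature = c("f1", "f2", "f3"), s1 = c(1, 5, 1), s2 = c(2, 5, 3),
               s3 = c(3, 5, 2), s4 = c(4, 5, 5), s5 = c(5, 5, 4)),
    "mrna", "A"
  )
  net <- correlation_network(m)
  # constant f2 yields no edges rather than NaN weights
  expect_false("f2" %in% c(net$from, net$to))
  expect_true("f2" %in% network_nodes(net))
  expect_error(correlation_network(m[1, ]), "2 features")
})

test_that("spearman networks are invariant under monotone feature transforms", {
  set.seed(5)
  df <- as.data.frame(matrix(rnorm(80), 8))
  names(df) <- paste0("s", 1:10)
  m1 <- omics_matrix(cbind(data.frame(feature = paste0("f", 1:8)), df), "x", "A")
  df2 <- df
  df2[3, ] <- exp(df2[3, ]) # strictly increasing transform of one feature
  m2 <- omics_matrix(cbind(data.frame(feature = paste0("f", 1:8)), df2), "x", "A")
  expect_equal(
    correlation_network(m1)$weight,
    correlation_network(m2)$weight,
    tolerance = 1e-12
  )
})

toy_net <- function(weights = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)) {
  pairs <- t(utils::combn(c("a", "b", "c", "d"), 2))
  layer_network(
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = weights),
    layer = "x", condition = "A"
  )
}

test_that("count-based reductions keep the computed top-|weight| edge counts", {
  net <- toy_net()
  red <- reduce_network(net, "average_degree", target_degree = 2)
  expect_identical(nrow(red), 4L) # round(4 * 2 / 2) edges
  expect_true(all(abs(red$weight) >= 0.6))
  expect_identical(nrow(reduce_network(net, "density", target_density = 1)), 6L)
  expect_identical(nrow(reduce_network(net, "density", target_density = 0.5)), 3L)
  expect_warning(
    keep_all <- reduce_network(net, "average_degree", target_degree = 10),
    "keeping all"
  )
  expect_identical(nrow(keep_all), 6L)
})

test_that("negative weights survive on absolute value and values are untouched", {
  net <- toy_net(c(0.9, -0.85, 0.7, -0.6, 0.5, 0.1))
  red <- reduce_network(net, "average_degree", target_degree = 1)
  expect_identical(sort(red$weight), sort(c(0.9, -0.85)))
  expect_true(all(red$weight %in% net$weight))
})

test_that("ties at the cut are all kept", {
  net <- toy_net(c(0.9, 0.5, 0.5, 0.5, 0.4, 0.3))
  red <- reduce_network(net, "average_degree", target_degree = 1)
  # target is 2 edges but the 0.5 block is inseparable: all ties retained
  expect_identical(nrow(red), 4L)
})

test_that("raising the cut yields nested edge subsets", {
  set.seed(9)
  net <- layer_network(random_edge_table(12, 0.8), "x", "A")
  prev <- NULL
  for (d in c(8, 6, 4, 2, 1)) {
    red <- reduce_network(net, "average_degree", target_degree = d)
    key <- paste(red$from, red$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("scale-free fit matches exact power-law histograms", {
  fit <- fit_scale_free_r2(c(`1` = 8, `2` = 4, `4` = 2, `8` = 1))
  expect_equal(fit$signed_r2, 1)
  expect_equal(fit$slope, -1)
  # perfect fit with rising distribution is signed negative
  fit2 <- fit_scale_free_r2(c(`1` = 1, `2` = 4, `4` = 16))
  expect_equal(fit2$signed_r2, -1)
  expect_equal(fit2$slope, 2)
  expect_error(fit_scale_free_r2(c(`4` = 10)), "2 distinct")
  expect_equal(
    fit_scale_free_r2(tibble::tibble(degree = c(1, 2, 4, 8), count = c(8, 4, 2, 1)))$signed_r2,
    1
  )
})

test_that("harmonization returns identical cuts for identical networks", {
  set.seed(21)
  net <- layer_network(random_edge_table(14, 0.9), "x", "A")
  net_b <- layer_network(as.data.frame(net), "x", "B")
  res <- harmonize_scale_free(net, net_b, r2_target = -1, threshold_grid = c(0.2, 0.4, 0.6))
  expect_identical(res$cut_a, res$cut_b)
  expect_identical(nrow(res$net_a), nrow(res$net_b))
})

test_that("harmonization minimizes the edge-count gap over qualifying cut pairs", {
  set.seed(33)
  net_a <- layer_network(random_edge_table(14, 0.9), "x", "A")
  net_b <- layer_network(random_edge_table(14, 0.7), "x", "B")
  grid <- c(0.2, 0.4, 0.6)
  res <- harmonize_scale_free(net_a, net_b, r2_target = -1, threshold_grid = grid)
  # independent exhaustive search over the grid product
  counts <- function(net) vapply(grid, function(ct) sum(abs(net$weight) >= ct), numeric(1))
  gaps <- abs(outer(counts(net_a), counts(net_b), "-"))
  expect_identical(
    abs(nrow(res$net_a) - nrow(res$net_b)),
    as.integer(min(gaps))
  )
})

test_that("an unreachable fit target is relaxed with a warning", {
  set.seed(12)
  net_a <- layer_network(random_edge_table(12, 0.9), "x", "A")
  net_b <- layer_network(random_edge_table(12, 0.9), "x", "B")
  expect_warning(
    res <- harmonize_scale_free(net_a, net_b,
      r2_target = 0.999999,
      threshold_grid = c(0.2, 0.5)
    ),
    "relaxing"
  )
  expect_lt(res$r2_target_used, 0.999999)
})
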