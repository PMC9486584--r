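# Differential network, drug scoring, ranking and explanation traces.

integrated_toy <- function(edges, condition = "A") {
  ml <- ml_from_edges(edges, condition = condition)
  integrate_network(ml, max_path_length = 1, restrict_to_targets = FALSE)
}

test_that("differential scores subtract with zero-fill for one-sided edges", {
  int_a <- integrated_toy(data.frame(
    from = c("p", "p"), to = c("q", "r"), weight = c(1, 0.6)
  ), "A")
  int_b <- integrated_toy(data.frame(
    from = c("p", "r"), to = c("q", "s"), weight = c(0.25, -0.4)
  ), "B")
  diff <- differential_network(int_a, int_b)
  expect_identical(nrow(diff), 3L) # union of edges
  d <- stats::setNames(diff$diff, paste(diff$from, diff$to))
  expect_equal(unname(d["p q"]), 0.75)
  expect_equal(unname(d["p r"]), 0.6) # edge only in A
  expect_equal(unname(d["r s"]), 0.4) # edge only in B: 0 - (-0.4)
  prov <- stats::setNames(diff$presence, paste(diff$from, diff$to))
  expect_identical(unname(prov[c("p q", "p r", "r s")]), c("both", "a_only", "b_only"))
  # union node set
  expect_identical(sort(attr(diff, "nodes")$feature), c("p", "q", "r", "s"))
})

random_edge_table_fixed <- function() {
  withr::with_seed(101, random_edge_table(8, 0.6))
}

test_that("identical inputs give an all-zero differential network", {
  int <- integrated_toy(random_edge_table_fixed())
  diff <- differential_network(int, int)
  expect_true(all(diff$diff == 0))
})

test_that("drug response score aggregates incident differential edges once", {
  int_a <- integrated_toy(data.frame(
    from = c("t", "t", "t", "q"), to = c("q", "r", "s", "r"),
    weight = c(0.5, -0.3, 0.4, 0.9)
  ), "A")
  int_b <- integrated_toy(data.frame(
    from = c("t", "q"), to = c("q", "r"), weight = c(0, 0.9)
  ), "B")
  diff <- differential_network(int_a, int_b)
  # incident differentials for target t: {0.5, -0.3, 0.4}
  s_mean <- drug_response_score(diff, mlkey("t"))
  expect_equal(s_mean$score, abs(mean(c(0.5, -0.3, 0.4))))
  expect_identical(s_mean$n_edges, 3L)
  s_med <- drug_response_score(diff, mlkey("t"), aggregator = "median")
  expect_equal(s_med$score, 0.4)
  # two targets sharing an edge: the shared edge counts once
  s_two <- drug_response_score(diff, mlkey(c("t", "q")))
  expect_identical(s_two$n_edges, 4L)
  # no incident edges -> unscored
  expect_true(is.na(drug_response_score(diff, mlkey("zz"))$score))
})

test_that("ranking sorts by descending score with lexicographic ties", {
  int_a <- integrated_toy(data.frame(
    from = c("a", "c", "e"), to = c("b", "d", "f"), weight = c(0.4, 0.1, 0.4)
  ), "A")
  int_b <- integrated_toy(data.frame(
    from = c("a", "c", "e"), to = c("b", "d", "f"), weight = c(0, 0, 0)
  ), "B")
  diff <- differential_network(int_a, int_b)
  targets <- data.frame(
    drug_id = c("zeta", "alpha", "mid", "ghost"),
    target_id = c("a", "e", "c", "nope"),
    target_layer = "x"
  )
  rk <- rank_drugs(diff, targets)
  scored <- rk[!rk$unscored, ]
  expect_identical(scored$drug_id, c("alpha", "zeta", "mid")) # tie 0.4: alpha < zeta
  expect_identical(scored$rank, 1:3)
  expect_identical(rk$drug_id[rk$unscored], "ghost")
  expect_true(is.na(rk$rank[rk$unscored]))
})

test_that("swapping conditions negates differentials but not drug scores", {
  set.seed(55)
  et_a <- random_edge_table(10, 0.5)
  et_b <- random_edge_table(10, 0.5)
  int_a <- integrated_toy(et_a, "A")
  int_b <- integrated_toy(et_b, "B")
  d_ab <- differential_network(int_a, int_b)
  d_ba <- differential_network(int_b, int_a)
  key <- function(d) paste(d$from, d$to)
  m <- match(key(d_ab), key(d_ba))
  expect_equal(d_ab$diff, -d_ba$diff[m], tolerance = 1e-14)
  targets <- data.frame(
    drug_id = c("d1", "d2"),
    target_id = c(et_a$from[1], et_b$to[1]),
    target_layer = "x"
  )
  rk_ab <- rank_drugs(d_ab, targets)
  rk_ba <- rank_drugs(d_ba, targets)
  expect_equal(
    rk_ab[order(rk_ab$drug_id), c("score", "n_edges")],
    rk_ba[order(rk_ba$drug_id), c("score", "n_edges")],
    ignore_attr = TRUE
  )
})

test_that("identical condition networks give every drug a zero score", {
  int <- integrated_toy(random_edge_table_fixed())
  diff <- differential_network(int, int)
  targets <- data.frame(
    drug_id = c("d1", "d2"),
    target_id = unique(c(diff$from, diff$to))[1:2],
    target_layer = "x"
  )
  rk <- rank_drugs(diff, targets)
  expect_true(all(rk$score[!rk$unscored] == 0))
})

test_that("explanation traces reproduce the drug score and handle quiet targets", {
  set.seed(56)
  int_a <- integrated_toy(random_edge_table(9, 0.6), "A")
  int_b <- integrated_toy(random_edge_table(9, 0.6), "B")
  diff <- differential_network(int_a, int_b)
  feats <- unique(c(diff$from, diff$to))
  targets <- data.frame(
    drug_id = "d1",
    target_id = c(feats[1], feats[2]),
    target_layer = "x"
  )
  ex <- explain_drug(diff, "d1", targets)
  expect_identical(ex$edges$diff, ex$edges$score_a - ex$edges$score_b)
  # recomputing the score from the union of traced edges reproduces rank_drugs
  uniq <- !duplicated(t(apply(ex$edges[, c("target", "partner")], 1, sort)))
  expect_equal(ex$score, abs(mean(ex$edges$diff[uniq])))
  rk <- rank_drugs(diff, targets)
  expect_equal(rk$score[rk$drug_id == "d1"], ex$score)
  expect_identical(rk$n_edges[rk$drug_id == "d1"], ex$n_edges)
  # a target with no incident differential edges gets a zero summary
  lonely <- data.frame(drug_id = "d2", target_id = "isolated", target_layer = "x")
  diff2 <- diff
  attr(diff2, "nodes") <- rbind(attr(diff, "nodes"), data.frame(layer = "x", feature = "isolated"))
  ex2 <- explain_drug(diff2, "d2", lonely)
  expect_identical(nrow(ex2$edges), 0L)
  expect_identical(ex2$summary$n_edges, 0L)
  expect_equal(ex2$summary$mean_abs_diff, 0)
  expect_error(explain_drug(diff, "unknown", targets), "Unknown drug")
})
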