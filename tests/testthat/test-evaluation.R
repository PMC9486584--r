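# Ground truth, ROC/pAUC, rank correlation and the PageRank baseline.

sens_table <- function(a, b, drug = "d1") {
  data.frame(
    cell_line_id = sprintf("c%02d", seq_len(length(a) + length(b))),
    condition = rep(c("A", "B"), c(length(a), length(b))),
    drug_id = drug,
    sensitivity = c(a, b)
  )
}

test_that("exact Mann-Whitney p-values match exhaustive enumeration", {
  gt <- ground_truth_mwu(sens_table(1:3, 4:6), "A", "B")
  expect_equal(gt$p_value, 0.1) # U = 0, 2/20 assignments as extreme
  set.seed(71)
  for (i in 1:15) {
    n <- sample(3:5, 1)
    m <- sample(3:5, 1)
    a <- round(rnorm(n), 6)
    b <- round(rnorm(m, 0.5), 6)
    gt <- ground_truth_mwu(sens_table(a, b), "A", "B")
    expect_equal(gt$p_value, mwu_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical pooled values give no evidence of separation", {
  gt <- ground_truth_mwu(sens_table(c(1, 1, 1), c(1, 1, 1)), "A", "B")
  expect_equal(gt$p_value, 1)
})

test_that("drugs with too few replicates are excluded", {
  tab <- rbind(
    sens_table(1:3, 4:6, "keep"),
    sens_table(1:2, 4:6, "drop")
  )
  gt <- ground_truth_mwu(tab, "A", "B", min_reps = 3)
  expect_identical(gt$drug_id, "keep")
  expect_error(ground_truth_mwu(sens_table(1:3, 4:6), "A", "Z"), "Condition absent")
})

make_truth <- function(p) {
  data.frame(drug_id = sprintf("d%02d", seq_along(p)), p_value = p)
}

test_that("perfect, reversed and uninformative rankings give the analytic metrics", {
  truth <- make_truth(c(0.001, 0.002, 0.5, 0.6, 0.7, 0.8))
  perfect <- data.frame(drug_id = truth$drug_id, score = 6:1)
  res <- roc_metrics(perfect, truth, gt_threshold = 0.01)
  expect_equal(res$auc, 1)
  expect_equal(res$pauc, 0.1)
  reversed <- data.frame(drug_id = truth$drug_id, score = 1:6)
  expect_equal(roc_metrics(reversed, truth, 0.01)$auc, 0)
  # all-tied scores trace the diagonal: AUC 1/2 and pAUC 0.1^2/2
  tied <- data.frame(drug_id = truth$drug_id, score = rep(1, 6))
  res_tied <- roc_metrics(tied, truth, 0.01)
  expect_equal(res_tied$auc, 0.5)
  expect_equal(res_tied$pauc, 0.005)
  expect_error(roc_metrics(perfect, truth, gt_threshold = 1e-9), "degenerate")
})

test_that("reversing a ranking complements the AUC", {
  set.seed(72)
  for (i in 1:10) {
    truth <- make_truth(runif(30))
    pred <- data.frame(drug_id = truth$drug_id, score = rnorm(30))
    a1 <- roc_metrics(pred, truth, 0.5)$auc
    pred$score <- -pred$score
    a2 <- roc_metrics(pred, truth, 0.5)$auc
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
    expect_gte(roc_metrics(pred, truth, 0.5)$pauc, 0)
    expect_lte(roc_metrics(pred, truth, 0.5)$pauc, 0.1)
  }
})

test_that("AUC and partial AUC agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  truth <- make_truth(runif(60))
  pred <- data.frame(drug_id = truth$drug_id, score = rnorm(60))
  mine <- roc_metrics(pred, truth, 0.5)
  ref <- pROC::roc(
    response = truth$p_value < 0.5, predictor = pred$score,
    direction = "<", quiet = TRUE
  )
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ref_pauc <- pROC::auc(ref,
    partial.auc = c(1, 0.9), partial.auc.focus = "specificity",
    partial.auc.correct = FALSE
  )
  expect_equal(mine$pauc, as.numeric(ref_pauc), tolerance = 1e-10)
})

test_that("rank correlation hits the analytic extremes and is centred under permutation", {
  truth <- make_truth((1:20) / 40)
  anti <- data.frame(drug_id = truth$drug_id, score = 20:1) # reverse of p order
  expect_equal(rank_correlation(anti, truth)$rho, -1)
  aligned <- data.frame(drug_id = truth$drug_id, score = 1:20)
  expect_equal(rank_correlation(aligned, truth)$rho, 1)
  set.seed(74)
  truth100 <- make_truth(runif(100))
  rhos <- replicate(400, {
    pred <- data.frame(drug_id = truth100$drug_id, score = sample(100))
    rank_correlation(pred, truth100)$rho
  })
  se_mean <- 1 / sqrt(99) / sqrt(400) # sd(rho) ~ 1/sqrt(n - 1) per draw
  expect_lt(abs(mean(rhos)), 3 * se_mean)
  expect_error(rank_correlation(aligned[1:2, ], truth), ">= 3")
})

test_that("pagerank baseline matches symmetry and power-iteration oracles", {
  one_edge <- differential_network(
    integrate_network(ml_from_edges(data.frame(from = "a", to = "b", weight = 0.8)),
      max_path_length = 1, restrict_to_targets = FALSE
    ),
    integrate_network(ml_from_edges(data.frame(from = "a", to = "b", weight = 0.3), condition = "B"),
      max_path_length = 1, restrict_to_targets = FALSE
    )
  )
  targets <- data.frame(drug_id = "d1", target_id = "a", target_layer = "x")
  pr <- pagerank_baseline(one_edge, targets)
  expect_equal(pr$score, 0.5) # two-node symmetry
  set.seed(75)
  et_a <- random_edge_table(6, 0.9)
  et_b <- et_a
  et_b$weight <- pmax(pmin(et_a$weight + runif(nrow(et_a), -0.3, 0.3), 1), -1)
  diff <- differential_network(
    integrate_network(ml_from_edges(et_a), max_path_length = 1, restrict_to_targets = FALSE),
    integrate_network(ml_from_edges(et_b, condition = "B"), max_path_length = 1, restrict_to_targets = FALSE)
  )
  nodes <- paste("x", attr(diff, "nodes")$feature, sep = "::")
  oracle <- power_iteration_pagerank(
    data.frame(
      from = paste("x", diff$from, sep = "::"),
      to = paste("x", diff$to, sep = "::"),
      weight = abs(diff$diff)
    ),
    nodes
  )
  expect_equal(sum(oracle), 1, tolerance = 1e-9)
  feats <- attr(diff, "nodes")$feature
  targets <- data.frame(drug_id = paste0("d", seq_along(feats)), target_id = feats, target_layer = "x")
  pr <- pagerank_baseline(diff, targets)
  pr <- pr[order(pr$drug_id), ]
  expected <- unname(oracle[paste("x", targets$target_id[order(targets$drug_id)], sep = "::")])
  expect_equal(pr$score, expected, tolerance = 1e-8)
  # a drug with no mapped target is unscored
  ghost <- data.frame(drug_id = "ghost", target_id = "none", target_layer = "x")
  expect_true(pagerank_baseline(diff, ghost)$unscored)
})

test_that("evaluate_ranking bundles metrics with tidy/glance/autoplot support", {
  set.seed(76)
  truth <- make_truth(runif(40))
  pred <- data.frame(drug_id = truth$drug_id, score = -rank(truth$p_value) + rnorm(40, 0, 3))
  ev <- evaluate_ranking(pred, truth, gt_threshold = 0.5)
  g <- glance(ev)
  expect_identical(nrow(g), 1L)
  expect_equal(g$auc, roc_metrics(pred, truth, 0.5)$auc)
  expect_lt(g$spearman_rho, 0) # prediction anti-correlates with p-values
  expect_identical(names(tidy(ev)), c("fpr", "tpr"))
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})
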