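test_that("metric point values match hand computations", {
  expect_equal(metric_pearson(1:4, 1:4), 1.0)
  expect_equal(metric_pearson(1:4, -(1:4)), -1.0)
  expect_equal(metric_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(metric_kendall(1:5, 1:5), 1.0)
  expect_equal(metric_kendall(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(metric_auc(c("LoF", "WT-like", "LoF", "WT-like"),
                          c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(metric_auc(c("LoF", "LoF", "WT-like"), c(3, 2, 1)), 1.0)
  expect_equal(metric_auc(c("LoF", "LoF", "WT-like"), c(1, 2, 3)), 0.0)
})

test_that("degenerate inputs raise the degenerate-metric condition", {
  expect_condition(metric_pearson(c(1, 1, 1), c(1, 2, 3)),
                   class = "stk11_degenerate_metric")
  expect_condition(metric_kendall(c(2, 2, 2), c(1, 2, 3)),
                   class = "stk11_degenerate_metric")
  expect_condition(metric_auc(c("LoF", "LoF"), c(1, 2)),
                   class = "stk11_degenerate_metric")
})

test_that("kendall tau-b agrees with brute-force pair enumeration", {
  set.seed(101)
  for (n in 3:8) {
    for (rep in 1:40) {
      x <- sample(1:3, n, replace = TRUE)
      y <- sample(1:3, n, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_equal(metric_kendall(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
      expect_lte(abs(metric_kendall(x, y)), 1)
    }
  }
})

test_that("auc agrees with the exhaustive concordance oracle incl. ties", {
  set.seed(202)
  for (n in 2:8) {
    labsets <- if (n <= 5) {
      # every non-degenerate label pattern
      m <- expand.grid(rep(list(c("LoF", "WT-like")), n), stringsAsFactors = FALSE)
      asplit(as.matrix(m), 1)
    } else {
      replicate(20, sample(c("LoF", "WT-like"), n, replace = TRUE),
                simplify = FALSE)
    }
    for (lab in labsets) {
      lab <- as.character(lab)
      if (length(unique(lab)) < 2) next
      for (rep in 1:3) {
        risk <- sample(1:3, n, replace = TRUE)       # tie-rich scores
        expect_equal(metric_auc(lab, risk), oracle_auc(lab, risk))
      }
    }
  }
})

test_that("auc is invariant under strictly increasing transforms", {
  set.seed(7)
  lab <- sample(c("LoF", "WT-like"), 12, replace = TRUE)
  lab[1:2] <- c("LoF", "WT-like")
  risk <- rnorm(12)
  a0 <- metric_auc(lab, risk)
  expect_equal(metric_auc(lab, exp(risk)), a0)
  expect_equal(metric_auc(lab, rank(risk)), a0)
})

test_that("stratified bootstrap preserves class counts; plain need not", {
  labels <- rep(c("LoF", "WT-like"), c(15, 13))
  idx <- bootstrap_indices(labels = labels, n_boot = 200, stratified = TRUE,
                           seed = 1)
  counts <- apply(idx, 2, function(i) sum(labels[i] == "LoF"))
  expect_true(all(counts == 15))
  expect_identical(dim(idx), c(28L, 200L))
  expect_error(bootstrap_indices(labels = c("LoF", "WT-like", "WT-like"),
                                 stratified = TRUE, n_boot = 2),
               ">= 2 variants per class")
})

test_that("bootstrap of a perfect predictor is degenerate at 1.0", {
  truth <- seq(0, 2, length.out = 22)
  est <- bootstrap_metric("pearson", truth = truth, pred = truth,
                          n_boot = 50, seed = 3)
  expect_equal(est$point, 1.0)
  expect_equal(est$draws, rep(1.0, 50))
  expect_equal(est$ci90, c(1.0, 1.0))
})

test_that("bootstrap estimates are bit-reproducible under a fixed seed", {
  set.seed(9); truth <- rnorm(20); pred <- truth + rnorm(20, 0, 0.5)
  a <- bootstrap_metric("kendall_tau", truth = truth, pred = pred,
                        n_boot = 100, seed = 77)
  b <- bootstrap_metric("kendall_tau", truth = truth, pred = pred,
                        n_boot = 100, seed = 77)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ci90, b$ci90)
  expect_length(a$draws, 100)
  expect_true(a$ci90[1] <= median(a$draws) && median(a$draws) <= a$ci90[2])
})

test_that("bootstrap ci90 width shrinks stochastically with set size", {
  width <- sapply(c(15, 60, 240), function(n) {
    set.seed(5)
    truth <- rnorm(n); pred <- truth + rnorm(n, 0, 0.8)
    est <- bootstrap_metric("pearson", truth = truth, pred = pred,
                            n_boot = 300, seed = 11)
    diff(est$ci90)
  })
  expect_true(all(diff(width) < 0))
})

test_that("compare_binomial counts strict wins with exact tail probabilities", {
  expect_error(compare_binomial(1:3, 1:4), "equal length")
  same <- compare_binomial(rep(0.5, 100), rep(0.5, 100))
  expect_identical(same$wins, 0L)
  expect_identical(same$ties, 100L)
  expect_equal(same$p_value, 1)
  sweep <- compare_binomial(rep(1, 1000), rep(0, 1000))
  expect_equal(sweep$p_value, 0.5^1000)
  expect_equal(sweep$log10_p, 1000 * log10(0.5), tolerance = 1e-9)
  # antisymmetry: wins(a>b) + wins(b>a) + ties = n
  set.seed(3)
  a <- rnorm(500); b <- rnorm(500); b[1:50] <- a[1:50]
  ab <- compare_binomial(a, b); ba <- compare_binomial(b, a)
  expect_identical(ab$wins + ba$wins + ab$ties, 500L)
})

test_that("ranking averages per-metric ranks, with two-stage team selection", {
  tab <- data.frame(
    predictor = c("a1", "a2", "b1", "base1", "base2"),
    team = c("A", "A", "B", NA, NA),
    baseline = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    pearson = c(0.9, 0.5, 0.7, 0.8, 0.8),
    kendall_tau = c(0.7, 0.4, 0.6, 0.6, 0.6),
    auc = c(0.95, 0.70, 0.85, 0.9, 0.9))
  rk <- rank_predictors(tab, two_stage = TRUE)
  expect_identical(rk$participants$predictor, c("a1", "b1"))  # a2 dropped in stage 1
  expect_equal(rk$participants$avg_rank, c(1, 2))
  # identical baselines tie on every metric
  expect_equal(rk$baselines$avg_rank, c(1.5, 1.5))
  single <- rank_predictors(tab[tab$predictor == "a1", ])
  expect_equal(single$participants$avg_rank, 1)
})

test_that("paired evaluation gives identical bootstrap sets to all predictors", {
  sim <- generate_assay(seed = 31)
  gt <- build_ground_truth(sim$measurements)
  preds <- list(
    generate_predictor(sim$truth, "activity", 0.3, seed = 1, name = "x", team = "X"),
    generate_predictor(sim$truth, "activity", 0.3, seed = 1, name = "y", team = "Y"))
  ev <- evaluate_predictors(preds, gt, gt$variant, n_boot = 50, seed = 2)
  # identical predictors on identical bootstrap sets -> all draws tie
  cmp <- compare_binomial(ev$estimates$x$auc$draws, ev$estimates$y$auc$draws)
  expect_identical(cmp$ties, 50L)
  expect_identical(cmp$wins, 0L)
})

test_that("correlation matrix is symmetric off-diagonal with truth diagonal", {
  sim <- generate_assay(seed = 13)
  gt <- build_ground_truth(sim$measurements)
  perfect <- generate_predictor(sim$truth, "activity", 0, seed = 1, name = "perfect")
  noisy <- generate_predictor(sim$truth, "activity", 0.5, seed = 2, name = "noisy")
  twin <- generate_predictor(sim$truth, "activity", 0.5, seed = 2, name = "twin")
  m <- predictor_correlations(list(perfect, noisy, twin), gt, gt$variant)
  expect_equal(m, t(m))
  expect_equal(m["noisy", "twin"], 1.0)              # identical predictors
  expect_equal(m["perfect", "perfect"], metric_pearson(gt$mean_rwt,
               sim$truth[gt$variant]))
  expect_gt(m["perfect", "perfect"], 0.99)           # ~truth vs assay mean
})
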