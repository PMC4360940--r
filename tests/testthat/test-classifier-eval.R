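# SVM scoring, Mann-Whitney AUC, operating points, leakage guards.

test_that("AUC handles the perfect and reversed rankings", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(compute_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals the O(n^2) pairwise oracle, ties included", {
  for (seed in 1:20) {
    mbtie:::with_seed(seed, {
      n <- sample(20:120, 1)
      labels <- rbinom(n, 1, 0.3)
      if (sum(labels) == 0) labels[1] <- 1
      if (sum(labels) == n) labels[1] <- 0
      # coarse grid injects plenty of ties
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    })
    expect_equal(compute_auc(scores, labels),
                 oracle_auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  mbtie:::with_seed(8, {
    labels <- rbinom(150, 1, 0.25)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(150) + labels
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing transforms", {
  mbtie:::with_seed(3, {
    scores <- rnorm(200)
    labels <- rbinom(200, 1, 0.4)
  })
  base <- compute_auc(scores, labels)
  expect_equal(compute_auc(exp(scores), labels), base)
  expect_equal(compute_auc(rank(scores), labels), base)
  expect_equal(compute_auc(scores * 100 - 7, labels), base)
})

test_that("a separable problem separates train-equals-test scores", {
  mbtie:::with_seed(1, {
    y <- rep(c(0L, 1L), each = 30)
    cols <- list(u = y * 2L + rbinom(60, 1, 0.0),
                 v = sample(0:1, 60, TRUE))
  })
  ds <- make_discrete_dataset(cols, y)
  sc <- train_and_score(ds, ds, c("u", "v"), lean_eval())
  expect_gt(min(sc[y == 1]), max(sc[y == 0]))
})

test_that("standardization derives from the training partition only", {
  ds <- make_two_signal_dataset(n = 400, n_noise = 2, seed = 5)
  tr <- mbtie:::subset_dataset(ds, 1:300)
  te <- mbtie:::subset_dataset(ds, 301:400)
  sc1 <- train_and_score(tr, te, c("sig_1", "sig_2"), lean_eval())
  # perturbing some test rows must leave the other test scores unchanged
  te2 <- te
  te2$features$sig_1[1:40] <- 2L - te2$features$sig_1[1:40]
  sc2 <- train_and_score(tr, te2, c("sig_1", "sig_2"), lean_eval())
  expect_equal(sc1[41:100], sc2[41:100])
})

test_that("random labels score at chance level", {
  aucs <- numeric(20)
  for (i in 1:20) {
    mbtie:::with_seed(100 + i, {
      y <- rbinom(500, 1, 0.3)
      cols <- list(a = sample(0:2, 500, TRUE), b = sample(0:2, 500, TRUE))
    })
    ds <- make_discrete_dataset(cols, y)
    tr <- mbtie:::subset_dataset(ds, 1:350)
    te <- mbtie:::subset_dataset(ds, 351:500)
    sc <- train_and_score(tr, te, c("a", "b"), lean_eval())
    aucs[i] <- compute_auc(sc, te$outcome)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("sensitivity/specificity behave across the threshold sweep", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  tab <- sens_spec_table(scores, labels, thresholds = c(-1, 0.5, 2))
  expect_equal(tab$operating_points$sensitivity, c(1, 1, 0))
  expect_equal(tab$operating_points$specificity, c(0, 1, 1))
  # direct count oracle at t = 0.5
  expect_equal(tab$operating_points$sensitivity[2], 1)
  expect_equal(tab$operating_points$specificity[2], 1)
  # monotone as the threshold sweeps
  full <- sens_spec_table(rnorm(50), rep_len(c(0, 1), 50))
  op <- full$operating_points
  expect_true(all(diff(op$sensitivity) <= 0))
  expect_true(all(diff(op$specificity) >= 0))
})

test_that("cost selection and empty feature sets are guarded", {
  ds <- make_two_signal_dataset(n = 300, n_noise = 1, seed = 9)
  expect_error(train_and_score(ds, ds, character(0)), "empty")
  res <- cv_scores(ds, c("sig_1", "sig_2"),
                   eval_config(cost_grid = c(0.1, 1), internal_folds = 3))
  expect_true(res$cost %in% c(0.1, 1))
  expect_length(res$scores, 300L)
  expect_gt(res$auc, 0.6)
})
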