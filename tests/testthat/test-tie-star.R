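# Equivalence criterion, canonical keys, and the boundary-enumeration
# search itself.

test_that("canonical keys are order-free and injective over sets", {
  expect_equal(canonicalize(c("B", "A")), "A|B")
  expect_equal(canonicalize(character(0)), "")
  expect_equal(canonicalize(c("A", "A")), "A")
  expect_identical(canonicalize(c("x", "y")), canonicalize(c("y", "x")))
})

test_that("identical scores are equivalent under both criteria", {
  mbtie:::with_seed(1, {
    labels <- rep_len(c(1, 0, 0), 90)
    scores <- rnorm(90) + labels
  })
  expect_true(equivalence_check(scores, scores, labels,
                                equivalence_criterion("auc_margin")))
  expect_true(equivalence_check(scores, scores, labels,
                                equivalence_criterion("paired_permutation",
                                                      n_permutations = 200)))
})

test_that("the margin rule applies exact threshold arithmetic", {
  # constructed rankings: reference AUC 75/100, candidate AUC 74/100
  ref <- make_scores_with_auc(c(10, 10, 10, 10, 10, 10, 5, 4, 3, 3))
  new <- make_scores_with_auc(c(10, 10, 10, 10, 10, 10, 5, 4, 3, 2))
  expect_equal(compute_auc(ref$scores, ref$labels), 0.75)
  expect_equal(compute_auc(new$scores, new$labels), 0.74)
  expect_true(equivalence_check(new$scores, ref$scores, ref$labels,
                                equivalence_criterion(margin = 0.01)))
  expect_false(equivalence_check(new$scores, ref$scores, ref$labels,
                                 equivalence_criterion(margin = 0.005)))
})

test_that("the permutation test rejects a noise model against a strong one", {
  crit <- equivalence_criterion("paired_permutation", n_permutations = 200)
  rejected <- 0L
  for (seed in 1:100) {
    mbtie:::with_seed(seed, {
      labels <- rbinom(500, 1, 0.3)
      labels[1:2] <- c(0, 1)
      strong <- labels + rnorm(500, sd = 0.6)
      noise <- rnorm(500)
    })
    ok <- equivalence_check(noise, strong, labels, crit, seed = seed)
    if (!ok) rejected <- rejected + 1L
  }
  expect_gte(rejected, 95L)
})

test_that("a duplicated predictor yields exactly the two singleton pools", {
  ds <- make_duplicated_pair_dataset(n = 800, seed = 42)
  pool <- run_tie_star(ds, eval_cfg = lean_eval(),
                       criterion = equivalence_criterion(margin = 0.02))
  keys <- vapply(pool$mbs, function(m) canonicalize(m$features),
                 character(1))
  expect_setequal(keys, c("A", "A_copy"))
  expect_false(pool$truncated)
})

test_that("the search is deterministic and never duplicates a pool entry", {
  sim <- generate_dataset(demo_generator_config(n = 1200, seed = 6,
                                                n_noise = 4))
  ds <- discretize(sim$dataset)
  p1 <- run_tie_star(ds, eval_cfg = lean_eval())
  p2 <- run_tie_star(ds, eval_cfg = lean_eval())
  k1 <- vapply(p1$mbs, function(m) canonicalize(m$features), character(1))
  k2 <- vapply(p2$mbs, function(m) canonicalize(m$features), character(1))
  expect_identical(k1, k2)
  expect_identical(vapply(p1$mbs, `[[`, numeric(1), "auc"),
                   vapply(p2$mbs, `[[`, numeric(1), "auc"))
  expect_equal(anyDuplicated(k1), 0L)
})

test_that("admitted boundaries hold up on an independent evaluation split", {
  sim <- generate_dataset(demo_generator_config(n = 3000, seed = 17,
                                                n_noise = 4))
  ds <- discretize(sim$dataset)
  tr <- mbtie:::subset_dataset(ds, 1:2000)
  te <- mbtie:::subset_dataset(ds, 2001:3000)
  pool <- run_tie_star(tr, eval_cfg = lean_eval())
  aucs <- vapply(pool$mbs, function(mb) {
    compute_auc(train_and_score(tr, te, mb$features, lean_eval()),
                te$outcome)
  }, numeric(1))
  # equivalent boundaries stay equivalent out of sample
  expect_lt(max(aucs) - min(aucs), 0.05)
  expect_gt(min(aucs), 0.6)
})

test_that("an empty reference boundary yields an empty pool", {
  mbtie:::with_seed(3, {
    cols <- list(n1 = sample(0:2, 300, TRUE), n2 = sample(0:2, 300, TRUE))
    y <- rbinom(300, 1, 0.3)
  })
  ds <- make_discrete_dataset(cols, y)
  expect_warning(
    expect_warning(pool <- run_tie_star(ds, eval_cfg = lean_eval()),
                   "no feature"),
    "empty pool")
  expect_length(pool$mbs, 0L)
})

test_that("the budget truncates the agenda and flags the pool", {
  sim <- generate_dataset(demo_generator_config(n = 1200, seed = 6,
                                                n_noise = 2))
  ds <- discretize(sim$dataset)
  pool <- run_tie_star(ds, eval_cfg = lean_eval(), budget = 2)
  expect_true(pool$truncated)
})
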