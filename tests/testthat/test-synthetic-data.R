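# Synthetic generator: ground-truth enumeration, prevalence calibration,
# exact information equivalence, reproducibility, Bayes-AUC oracle.

grp <- function(members, ...) equivalence_group(members, ...)

test_that("true boundaries are the Cartesian product over nonzero groups", {
  g23 <- list(grp(c("a1", "a2")), grp(c("b1", "b2", "b3")))
  sets <- enumerate_true_mbs(g23, c(1, 0.5))
  expect_length(sets, 6L)
  expect_equal(vapply(sets, canonicalize, character(1)),
               c("a1|b1", "a1|b2", "a1|b3", "a2|b1", "a2|b2", "a2|b3"))
  # zero-weight group excluded
  expect_length(enumerate_true_mbs(g23, c(1, 0)), 2L)
  # singleton groups
  expect_equal(enumerate_true_mbs(list(grp(c("x1", "x2", "x3"))), 1),
               list("x1", "x2", "x3"))
  expect_equal(enumerate_true_mbs(list(grp("solo")), 2)[[1]], "solo")
})

test_that("generated data carry the configured structure", {
  cfg <- demo_generator_config(n = 2000, seed = 21)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  expect_equal(n_subjects(ds), 2000L)
  expect_length(sim$ground_truth$true_mbs, 6L)
  expect_setequal(
    feature_names(ds),
    c("g1_a", "g1_b", "g2_a", "g2_b", "g2_c",
      sprintf("noise_%02d", 1:10)))
  kinds <- vapply(ds$schema, `[[`, character(1), "kind")
  expect_true(all(c("continuous", "ordinal", "binary") %in% kinds))
  # realized prevalence inside the exact binomial 99% interval of 0.17
  band <- qbinom(c(0.005, 0.995), 2000, 0.17)
  expect_gte(sum(ds$outcome), band[1])
  expect_lte(sum(ds$outcome), band[2])
})

test_that("same seed gives byte-identical data, different seeds differ", {
  cfg <- demo_generator_config(n = 400, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset, b$dataset)
  c <- generate_dataset(demo_generator_config(n = 400, seed = 10))
  expect_false(identical(a$dataset$features, c$dataset$features))
})

test_that("group members are exactly information-equivalent", {
  sim <- generate_dataset(demo_generator_config(n = 1500, seed = 4))
  ds <- sim$dataset
  cfg <- sim$ground_truth$config
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    base <- NULL
    for (m in seq_along(g$members)) {
      v <- mbtie:::invert_transform(ds$features[[g$members[m]]],
                                    g$transform_kinds[m])
      tab <- table(v, ds$outcome)
      if (is.null(base)) base <- tab else expect_equal(unname(tab),
                                                       unname(base))
    }
  }
})

test_that("noise features are marginally independent of the outcome", {
  rejections <- 0L
  tests <- 0L
  for (seed in 1:15) {
    sim <- generate_dataset(demo_generator_config(n = 800, seed = seed,
                                                  n_noise = 6))
    ds <- discretize(sim$dataset)
    for (nm in grep("^noise", feature_names(ds), value = TRUE)) {
      res <- g2_test(ds$features[[nm]], ds$outcome)
      tests <- tests + 1L
      if (res$reliable && res$p_value <= 0.05) rejections <- rejections + 1L
    }
  }
  rate <- rejections / tests
  # type-I behaviour: alpha plus Monte-Carlo slack
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})

test_that("intercept calibration fails loudly when unbracketable", {
  cfg <- generator_config(
    n = 500, groups = list(grp("a")), weights = 40,
    prevalence = 0.17, seed = 1)
  # 2/3 of source cells saturate at p = 1, so prevalence 0.17 is
  # unreachable for any intercept
  expect_error(generate_dataset(cfg), "bracket")
})

test_that("config validation rejects malformed settings", {
  expect_error(generator_config(100, list(grp("a")), 1, prevalence = 1.5),
               "prevalence")
  expect_error(generator_config(100, list(grp("a"), grp("a")), c(1, 1)),
               "disjoint")
  expect_error(generator_config(100, list(grp("a")), Inf), "finite")
})

test_that("Bayes-AUC estimate matches the enumeration oracle", {
  # closed-form oracle: exhaustive summation over the 3-level source
  # support for one group with weight 1.5 at prevalence 0.17
  w <- 1.5; prev <- 0.17
  f <- function(a) mean(plogis(a + w * (0:2))) - prev
  a <- uniroot(f, c(-60, 60), tol = 1e-12)$root
  p <- plogis(a + w * (0:2))
  wc <- p / sum(p); wn <- (1 - p) / sum(1 - p)
  oracle <- sum(outer(wc, wn) * (outer(p, p, ">") + 0.5 * outer(p, p, "==")))

  cfg <- generator_config(5000, list(grp("a")), w, prevalence = prev)
  est <- estimate_bayes_auc(cfg, mc_samples = 2e4, seed = 2)
  expect_equal(as.numeric(est), oracle, tolerance = 6 * attr(est, "se"))
  # the generator's stored exact value agrees with the oracle tightly
  sim <- generate_dataset(generator_config(200, list(grp("a")), w,
                                           prevalence = prev, seed = 3))
  expect_equal(sim$ground_truth$bayes_auc, oracle, tolerance = 1e-10)
})

test_that("Bayes AUC hits the no-signal and saturated limits", {
  null_cfg <- generator_config(1000, list(grp("a"), grp("b")), c(0, 0),
                               prevalence = 0.3)
  est0 <- estimate_bayes_auc(null_cfg, mc_samples = 2e4, seed = 1)
  expect_equal(as.numeric(est0), 0.5, tolerance = 0.02)
  # saturated weight with prevalence 1/3: outcome deterministic in the
  # source, AUC at the perfect-ranking limit
  sat_cfg <- generator_config(1000, list(grp("a")), 40, prevalence = 1 / 3)
  est1 <- estimate_bayes_auc(sat_cfg, mc_samples = 2e4, seed = 1)
  expect_gt(as.numeric(est1), 0.995)
})
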