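# Dataset construction, CSV round trip, imputation, discretization.

mixed_fixture <- function(n = 12, seed = 3) {
  mbtie:::with_seed(seed, {
    features <- data.frame(
      bp = round(rnorm(n, 120, 10), 3),
      pain = sample(0:2, n, replace = TRUE),
      head_injury = sample(0:1, n, replace = TRUE)
    )
    schema <- list(
      feature_schema("bp", "continuous"),
      feature_schema("pain", "ordinal", levels = c("none", "mild", "severe")),
      feature_schema("head_injury", "binary", levels = c("no", "yes"))
    )
    mb_dataset(features, schema,
               outcome = rep_len(c(1L, 0L, 0L), n), id = "mixed")
  })
}

test_that("write then read reproduces values, kinds and outcome exactly", {
  ds <- mixed_fixture()
  ds$features$bp[3] <- NA
  ds$features$pain[5] <- NA
  csv <- tempfile(fileext = ".csv")
  sch <- tempfile(fileext = ".yaml")
  write_dataset(ds, csv, sch)
  back <- read_dataset(csv, sch, id = "mixed")
  expect_equal(back$features, ds$features)
  expect_equal(back$outcome, ds$outcome)
  expect_equal(vapply(back$schema, `[[`, character(1), "kind"),
               vapply(ds$schema, `[[`, character(1), "kind"))
  expect_equal(lapply(back$schema, `[[`, "levels"),
               lapply(ds$schema, `[[`, "levels"))
})

test_that("rows with missing outcome are dropped and counted", {
  ds <- mixed_fixture(n = 5)
  csv <- tempfile(fileext = ".csv")
  sch <- tempfile(fileext = ".yaml")
  write_dataset(ds, csv, sch)
  lines <- readLines(csv)
  # blank the outcome cell of the first data row
  lines[2] <- sub(",[01]$", ",", lines[2])
  writeLines(lines, csv)
  expect_message(back <- read_dataset(csv, sch), "dropped 1 row")
  expect_equal(n_subjects(back), 4L)
})

test_that("invalid inputs are rejected with informative errors", {
  ds <- mixed_fixture(n = 6)
  csv <- tempfile(fileext = ".csv")
  sch <- tempfile(fileext = ".yaml")
  write_dataset(ds, csv, sch)

  # outcome with three distinct values
  lines <- readLines(csv)
  lines[2] <- sub(",[01]$", ",2", lines[2])
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_dataset(bad, sch), "binary")

  # schema naming an unknown column
  schema2 <- c(ds$schema, list(feature_schema("ghost", "continuous")))
  sch2 <- tempfile(fileext = ".yaml")
  write_schema(schema2, sch2)
  expect_error(read_dataset(csv, sch2), "ghost")

  # empty file
  empty <- tempfile(fileext = ".csv")
  writeLines("bp,pain,head_injury,outcome", empty)
  expect_error(read_dataset(empty, sch), "empty")

  # single-class outcome rejected at construction
  expect_error(
    mb_dataset(ds$features, ds$schema, rep(1L, 6)), "both classes")
})

test_that("equal-frequency discretization matches the sorted-thirds rule", {
  cols <- list(v = c(1, 2, 3, 4, 5, 6), b = c(0L, 1L, 0L, 1L, 0L, 1L))
  schema <- list(feature_schema("v", "continuous"),
                 feature_schema("b", "binary", levels = c("0", "1")))
  names(schema) <- c("v", "b")
  ds <- mb_dataset(data.frame(v = cols$v, b = cols$b), schema,
                   outcome = c(1L, 0L, 1L, 0L, 1L, 0L))
  out <- discretize(ds, bins = 3)
  expect_equal(out$features$v, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(out$schema$v$kind, "ordinal")
  # binary column untouched by the kind filter
  expect_equal(out$features$b, cols$b)
  expect_equal(out$schema$b$kind, "binary")
})

test_that("constant continuous column collapses with a warning", {
  ds <- mb_dataset(data.frame(v = rep(2.5, 6)),
                   list(feature_schema("v", "continuous")),
                   outcome = rep_len(c(1L, 0L), 6))
  expect_warning(out <- discretize(ds, bins = 3), "collapsed")
  expect_equal(unique(out$features$v), 0L)
})

test_that("discretization is monotone and permutation-equivariant", {
  for (seed in 1:5) {
    v <- mbtie:::with_seed(seed, rnorm(40))
    ds <- mb_dataset(data.frame(v = v),
                     list(feature_schema("v", "continuous")),
                     outcome = rep_len(c(1L, 0L), 40))
    code <- discretize(ds, bins = 4)$features$v
    ord <- order(v)
    expect_true(all(diff(code[ord]) >= 0))  # monotone in the raw value
    perm <- mbtie:::with_seed(seed + 50, sample.int(40))
    ds_p <- mb_dataset(data.frame(v = v[perm]), ds$schema,
                       outcome = ds$outcome)
    expect_equal(discretize(ds_p, bins = 4)$features$v, code[perm])
  }
})

test_that("imputation fills mode for discrete and median for continuous", {
  features <- data.frame(
    bp = c(10, 20, NA, 30, 40),
    pain = c(2L, 2L, 0L, NA, 2L)
  )
  schema <- list(feature_schema("bp", "continuous"),
                 feature_schema("pain", "ordinal", levels = c("0", "1", "2")))
  ds <- mb_dataset(features, schema, outcome = c(1L, 0L, 1L, 0L, 1L))
  expect_message(out <- impute_missing(ds), "imputed")
  expect_equal(out$features$bp[3], 25)     # median of observed
  expect_equal(out$features$pain[4], 2L)   # mode of observed
  expect_false(anyNA(out$features))
})
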