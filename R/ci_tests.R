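# Conditional-independence tests: the statistical engine behind Markov
# boundary induction. Two engines: G-squared (likelihood-ratio chi-square)
# on discrete data, Fisher-z on partial correlations for continuous data.

#' Configuration for conditional-independence testing
#'
#' @param alpha Significance level for declaring dependence.
#' @param max_k Maximum conditioning-set size explored by the induction
#'   search. With ~10^3 subjects and 3-level variables, strata beyond
#'   `|Z| = 3` rarely retain enough samples per cell for a reliable test.
#' @param min_avg_cell Minimum average sample count per contingency cell for
#'   a G-squared test to be flagged reliable.
#' @param engine Default test engine: `"g2"` for discrete(ized) data,
#'   `"fisher_z"` for continuous pipelines.
#' @return An object of class `mb_ci_config`.
#' @export
ci_config <- function(alpha = 0.05, max_k = 3L, min_avg_cell = 5,
                      engine = c("g2", "fisher_z")) {
  engine <- match.arg(engine)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must be in (0,1)")
  }
  max_k <- as.integer(max_k)
  if (max_k < 0L) stop_input("max_k must be >= 0")
  if (!is.numeric(min_avg_cell) || min_avg_cell <= 0) {
    stop_input("min_avg_cell must be > 0")
  }
  structure(list(alpha = alpha, max_k = max_k,
                 min_avg_cell = min_avg_cell, engine = engine),
            class = "mb_ci_config")
}

new_ci_result <- function(statistic, dof, p_value, reliable, test_kind) {
  structure(list(statistic = statistic, dof = as.integer(dof),
                 p_value = p_value, reliable = isTRUE(reliable),
                 test_kind = test_kind),
            class = "mb_ci_result")
}

#' @export
print.mb_ci_result <- function(x, ...) {
  cat(sprintf("<%s test> statistic=%.4g dof=%d p=%.4g reliable=%s\n",
              x$test_kind, x$statistic, x$dof, x$p_value, x$reliable))
  invisible(x)
}

as_condition_list <- function(Z) {
  if (is.null(Z)) return(list())
  if (is.data.frame(Z)) return(as.list(Z))
  if (is.list(Z)) return(Z)
  list(Z)
}

#' G-squared conditional-independence test
#'
#' Likelihood-ratio chi-square test of `x` independent of `y` within each
#' stratum of the conditioning variables `Z`:
#' \deqn{G^2 = 2 \sum_z \sum_{i,j} O_{ijz} \ln(O_{ijz}/E_{ijz})}
#' with expected counts from the within-stratum margins. Degrees of freedom
#' sum \eqn{(r_z - 1)(c_z - 1)} over strata using per-stratum realized level
#' counts. The p-value is the upper chi-square tail. The test is flagged
#' reliable when the average sample count per contingency cell reaches
#' `min_avg_cell`; the induction algorithm never removes a candidate on an
#' unreliable test.
#'
#' @param x,y Discrete vectors (integer codes or factors) of equal length.
#' @param Z Conditioning set: `NULL`, a vector, a list of vectors, or a
#'   data frame of discrete columns.
#' @param config A [ci_config()].
#' @return An `mb_ci_result` with fields `statistic`, `dof`, `p_value`,
#'   `reliable`, `test_kind`.
#' @export
#' @examples
#' x <- rep(c(0, 1), each = 50)
#' g2_test(x, x)            # maximal dependence
#' g2_test(x, rev(x) * 0)   # degenerate y: dof 0, p 1
g2_test <- function(x, y, Z = NULL, config = ci_config()) {
  Z <- as_condition_list(Z)
  n <- length(x)
  if (length(y) != n || any(lengths(Z) != n)) {
    stop_input("x, y and all conditioning columns must have equal length")
  }
  keep <- !is.na(x) & !is.na(y)
  for (z in Z) keep <- keep & !is.na(z)
  x <- x[keep]; y <- y[keep]
  Z <- lapply(Z, `[`, keep)
  n <- length(x)
  if (n == 0L) return(new_ci_result(0, 0L, 1, FALSE, "g2"))

  stratum <- if (length(Z)) {
    as.integer(interaction(lapply(Z, as.integer), drop = TRUE))
  } else rep.int(1L, n)
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  nx <- max(xi); ny <- max(yi); ns <- max(stratum)
  # degenerate input: a variable with a single realized level overall
  if (nx < 2L || ny < 2L) return(new_ci_result(0, 0L, 1, FALSE, "g2"))

  g2 <- 0; dof <- 0L
  counts <- tabulate(xi + nx * (yi - 1L) + nx * ny * (stratum - 1L),
                     nbins = nx * ny * ns)
  dim(counts) <- c(nx, ny, ns)
  for (s in seq_len(ns)) {
    tab <- counts[, , s, drop = TRUE]
    dim(tab) <- c(nx, ny)
    rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
    r <- sum(rs > 0); cc <- sum(cs > 0)
    if (tot == 0 || r < 2L || cc < 2L) next
    expd <- outer(rs, cs) / tot
    pos <- tab > 0
    g2 <- g2 + 2 * sum(tab[pos] * log(tab[pos] / expd[pos]))
    dof <- dof + (r - 1L) * (cc - 1L)
  }
  reliable <- n / (nx * ny * ns) >= config$min_avg_cell
  # dof 0 with both variables varying overall: x is deterministic within
  # every stratum of Z (e.g. Z contains a copy of x) -- exact conditional
  # independence, p = 1, reliability judged by cell counts as usual
  p <- if (dof == 0L) 1 else
    stats::pchisq(g2, df = dof, lower.tail = FALSE)
  new_ci_result(g2, dof, p, reliable, "g2")
}

#' Fisher-z conditional-independence test
#'
#' Tests zero partial correlation of `x` and `y` given `Z` via the inverse
#' correlation matrix, with the Fisher variance-stabilising transform
#' \eqn{z = \tfrac{1}{2}\ln\frac{1+r}{1-r}\sqrt{n - |Z| - 3}} and a
#' two-sided normal p-value. Intended for continuous features left
#' undiscretized.
#'
#' @inheritParams g2_test
#' @return An `mb_ci_result` with `test_kind = "fisher_z"`. A singular
#'   correlation structure yields `reliable = FALSE`, `p_value = 1`.
#' @export
fisher_z_test <- function(x, y, Z = NULL, config = ci_config()) {
  Z <- as_condition_list(Z)
  n <- length(x)
  if (length(y) != n || any(lengths(Z) != n)) {
    stop_input("x, y and all conditioning columns must have equal length")
  }
  keep <- !is.na(x) & !is.na(y)
  for (z in Z) keep <- keep & !is.na(z)
  x <- x[keep]; y <- y[keep]
  Z <- lapply(Z, `[`, keep)
  n <- length(x)
  k <- length(Z)
  if (n <= k + 3L) stop_input("fisher_z_test requires n > |Z| + 3")

  mat <- cbind(as.numeric(x), as.numeric(y))
  for (z in Z) mat <- cbind(mat, as.numeric(z))
  r <- if (k == 0L) {
    suppressWarnings(stats::cor(mat[, 1], mat[, 2]))
  } else {
    cm <- suppressWarnings(stats::cor(mat))
    if (anyNA(cm)) NA_real_ else {
      inv <- tryCatch(solve(cm), error = function(e) NULL)
      if (is.null(inv)) NA_real_ else
        -inv[1, 2] / sqrt(inv[1, 1] * inv[2, 2])
    }
  }
  if (!is.finite(r)) return(new_ci_result(0, 0L, 1, FALSE, "fisher_z"))
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(n - k - 3)
  p <- 2 * stats::pnorm(-abs(z))
  new_ci_result(abs(z), max(n - k - 3L, 0L), p, n > k + 10L, "fisher_z")
}

# Engine dispatch used by the induction layer.
ci_test <- function(x, y, Z = NULL, config = ci_config()) {
  switch(config$engine,
         g2 = g2_test(x, y, Z, config),
         fisher_z = fisher_z_test(x, y, Z, config))
}

#' Decide dependence from a test result
#'
#' Dependence is declared only on a reliable test with `p <= alpha`.
#' An unreliable result is never itself evidence of independence; how to act
#' on it is the caller's policy (the induction algorithm keeps the variable
#' under consideration).
#'
#' @param result An `mb_ci_result`.
#' @param config A [ci_config()].
#' @return Logical.
#' @export
is_dependent <- function(result, config = ci_config()) {
  isTRUE(result$reliable) && result$p_value <= config$alpha
}
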