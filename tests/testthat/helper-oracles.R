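# Independent oracles and small fixture builders shared across tests.
# Every oracle is a deliberately naive computation (brute force,
# enumeration, direct formula) kept separate from the package code paths
# it checks.

# O(n^2) pairwise Mann-Whitney AUC with half credit for ties.
oracle_auc_pairwise <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# Direct cell-sum likelihood-ratio statistic for an unconditional r x c
# contingency table.
oracle_g2_table <- function(tab) {
  tab <- as.matrix(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g2 <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) g2 <- g2 + 2 * tab[i, j] * log(tab[i, j] / expd[i, j])
  }
  dof <- (sum(rowSums(tab) > 0) - 1) * (sum(colSums(tab) > 0) - 1)
  list(statistic = g2, dof = dof,
       p_value = stats::pchisq(g2, dof, lower.tail = FALSE))
}

# Expand a contingency table into paired discrete vectors.
table_to_columns <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    x <- c(x, rep.int(i, tab[i, j]))
    y <- c(y, rep.int(j, tab[i, j]))
  }
  list(x = x, y = y)
}

combn_sets <- function(items, k) {
  if (k == 0L) return(list(character(0)))
  utils::combn(sort(items), k, simplify = FALSE)
}

# Exhaustive search over all 2^p feature subsets for the minimal
# "sufficient" sets under the same CI criterion the learner uses: S is
# sufficient when every feature outside S is reliably independent of the
# outcome given some subset of S of size <= max_k; minimal sets have no
# sufficient proper subset.
oracle_minimal_sufficient <- function(dataset, config = ci_config()) {
  feats <- feature_names(dataset)
  memo <- new.env(parent = emptyenv())
  indep <- function(x, Z) {
    key <- paste(x, paste(sort(Z), collapse = ","), sep = "|")
    r <- memo[[key]]
    if (is.null(r)) {
      res <- g2_test(dataset$features[[x]], dataset$outcome,
                     if (length(Z)) dataset$features[Z] else NULL, config)
      r <- res$reliable && res$p_value > config$alpha
      memo[[key]] <- r
    }
    r
  }
  sufficient <- function(S) {
    for (x in setdiff(feats, S)) {
      found <- FALSE
      for (k in 0:min(config$max_k, length(S))) {
        for (Z in combn_sets(S, k)) {
          if (indep(x, Z)) { found <- TRUE; break }
        }
        if (found) break
      }
      if (!found) return(FALSE)
    }
    TRUE
  }
  suff <- list()
  for (size in 0:length(feats)) {
    for (S in combn_sets(feats, size)) {
      if (sufficient(S)) suff <- c(suff, list(sort(S)))
    }
  }
  Filter(function(S) {
    !any(vapply(suff, function(T) {
      length(T) < length(S) && all(T %in% S)
    }, logical(1)))
  }, suff)
}

# Build an all-discrete mb_dataset from integer-code columns.
make_discrete_dataset <- function(columns, outcome, id = "fixture") {
  schema <- lapply(names(columns), function(nm) {
    nlev <- max(max(columns[[nm]], na.rm = TRUE) + 1L, 2L)
    feature_schema(nm, if (nlev == 2L) "binary" else "ordinal",
                   levels = as.character(seq_len(nlev) - 1L))
  })
  names(schema) <- names(columns)
  mb_dataset(as.data.frame(columns), schema, outcome, id = id)
}

# Dataset with one predictive feature A, an exact duplicate A_copy, and a
# few independent noise columns. Both {A} and {A_copy} are true MBs.
make_duplicated_pair_dataset <- function(n = 800, n_noise = 2, seed = 42) {
  mbtie:::with_seed(seed, {
    a <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-2 + 1.3 * a))
    cols <- list(A = a, A_copy = a)
    for (i in seq_len(n_noise)) {
      cols[[paste0("noise_", i)]] <- sample(0:2, n, replace = TRUE)
    }
    make_discrete_dataset(cols, y, id = "dup_pair")
  })
}

# Dataset with two independent discrete signal sources and noise columns.
make_two_signal_dataset <- function(n = 2000, n_noise = 8, seed = 7,
                                    w = c(1.1, 0.9)) {
  mbtie:::with_seed(seed, {
    s1 <- sample(0:2, n, replace = TRUE)
    s2 <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-2.5 + w[1] * s1 + w[2] * s2))
    cols <- list(sig_1 = s1, sig_2 = s2)
    for (i in seq_len(n_noise)) {
      cols[[sprintf("noise_%02d", i)]] <- sample(0:2, n, replace = TRUE)
    }
    make_discrete_dataset(cols, y, id = "two_signal")
  })
}

# Score vector whose AUC against `labels` (n1 cases, n0 controls at ranks
# 1..n0) equals sum(counts)/(n1*n0): case i sits just above `counts[i]`
# controls.
make_scores_with_auc <- function(counts, n0 = 10) {
  ctrl <- seq_len(n0)
  case <- counts + 0.5
  list(scores = c(case, ctrl),
       labels = c(rep(1, length(counts)), rep(0, n0)))
}

lean_eval <- function(seed = 1L, folds = 5L) {
  eval_config(cost_grid = 1, internal_folds = folds, seed = seed)
}
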