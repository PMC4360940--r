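# Repeated stratified k-fold evaluation: the equivalence search runs inside
# each training partition; every pooled boundary is scored on the held-out
# fold; AUCs and feature frequencies are aggregated across all runs.

#' Stratified fold assignment
#'
#' Subjects are shuffled within outcome class and dealt round-robin into
#' `k` folds, so per-fold case counts differ by at most one across folds,
#' and likewise control counts.
#'
#' @param labels 0/1 outcome vector.
#' @param k Fold count (>= 2).
#' @param seed Integer seed for the within-class shuffles.
#' @return An `mb_folds` object: `fold` (length-n assignment in `1..k`),
#'   `k`, `seed`.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop_input("k must be >= 2 (no held-out data otherwise)")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stop_input("each class must have at least k subjects (counts: ",
               paste(counts, collapse = "/"), ")")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold = fold, k = k, seed = as.integer(seed)),
            class = "mb_folds")
}

#' Enumerate the train/test runs of a repeated k-fold schedule
#'
#' One row per (repeat, fold) pair; fold assignments for repeat `r` use the
#' derived seed `master seed + r`. `repeats = 10, k = 10` yields the
#' 100-run schedule of the standard repeated 10-fold design.
#'
#' @param labels 0/1 outcome vector.
#' @param repeats Number of independent fold assignments.
#' @param k Fold count per repeat.
#' @param seed Master seed.
#' @return Data frame with columns `rep`, `fold`, plus the per-repeat
#'   `mb_folds` objects attached as attribute `"folds"`.
#' @export
cv_schedule <- function(labels, repeats, k, seed = 1L) {
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_input("repeats must be >= 1")
  folds <- lapply(seq_len(repeats), function(r) {
    make_stratified_folds(labels, k, derive_seed(seed, r))
  })
  out <- expand.grid(fold = seq_len(as.integer(k)),
                     rep = seq_len(repeats))[, c("rep", "fold")]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Repeated stratified k-fold evaluation of the equivalence search
#'
#' For each of `repeats * k` runs the boundary-equivalence search
#' ([run_tie_star()]) runs on the training partition alone, and every
#' boundary of its pool is scored ([train_and_score()]) on the held-out
#' fold. Per-boundary test AUCs are pooled across all runs into the mean
#' AUC and its empirical 2.5/97.5 percentile range; the feature-frequency
#' table counts, for every feature, the fraction of all discovered
#' boundaries containing it.
#'
#' @param dataset An `mb_dataset` (discrete features for the `"g2"` engine).
#' @param repeats Number of repeats (10 in the standard design).
#' @param k Folds per repeat (10 in the standard design).
#' @param induction An [induction_config()].
#' @param eval_cfg An [eval_config()].
#' @param criterion An [equivalence_criterion()].
#' @param seed Master seed; per-repeat fold seeds are derived from it.
#' @param budget Agenda budget per run (see [run_tie_star()]).
#' @param aggregate `"per_mb"` pools every boundary's test AUC across runs
#'   (the default); `"per_run"` averages within run first.
#' @return An `mb_cv_result`: `runs_table` (one row per boundary per run),
#'   `mean_auc`, `auc_range_95`, `mean_mbs_per_run`, `feature_frequency`,
#'   `n_runs`, and the empty-pool run count.
#' @export
run_repeated_cv <- function(dataset, repeats = 10L, k = 10L,
                            induction = induction_config(),
                            eval_cfg = eval_config(),
                            criterion = equivalence_criterion(),
                            seed = 1L, budget = 5000L,
                            aggregate = c("per_mb", "per_run")) {
  stopifnot(inherits(dataset, "mb_dataset"))
  aggregate <- match.arg(aggregate)
  sched <- cv_schedule(dataset$outcome, repeats, k, seed)
  folds <- attr(sched, "folds")

  rows <- list()
  n_empty <- 0L
  for (i in seq_len(nrow(sched))) {
    r <- sched$rep[i]
    j <- sched$fold[i]
    assign_r <- folds[[r]]$fold
    tr <- subset_dataset(dataset, assign_r != j)
    te <- subset_dataset(dataset, assign_r == j)
    pool <- withCallingHandlers(
      run_tie_star(tr, induction, eval_cfg, criterion, budget),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!length(pool$mbs)) {
      n_empty <- n_empty + 1L
      message("run rep=", r, " fold=", j, ": empty pool")
      next
    }
    aucs <- vapply(pool$mbs, function(mb) {
      compute_auc(train_and_score(tr, te, mb$features, eval_cfg),
                  te$outcome)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r, fold = j,
      mb = vapply(pool$mbs, function(m) canonicalize(m$features),
                  character(1)),
      size = vapply(pool$mbs, function(m) length(m$features), integer(1)),
      test_auc = aucs
    )
  }
  runs_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rep = integer(0), fold = integer(0), mb = character(0),
               size = integer(0), test_auc = numeric(0))
  rownames(runs_table) <- NULL

  pooled <- if (aggregate == "per_mb") runs_table$test_auc else
    tapply(runs_table$test_auc,
           interaction(runs_table$rep, runs_table$fold, drop = TRUE),
           mean)
  pooled <- as.numeric(pooled)
  n_runs <- nrow(sched)
  structure(list(
    runs_table = runs_table,
    mean_auc = if (length(pooled)) mean(pooled) else NA_real_,
    auc_range_95 = if (length(pooled)) {
      stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
    } else c(NA_real_, NA_real_),
    mean_mbs_per_run = nrow(runs_table) / max(n_runs - n_empty, 1L),
    feature_frequency = feature_frequency(runs_table),
    n_runs = n_runs,
    n_empty_runs = n_empty,
    aggregate = aggregate,
    seed = as.integer(seed)
  ), class = "mb_cv_result")
}

#' @export
print.mb_cv_result <- function(x, ...) {
  cat(sprintf(paste0("<mb_cv_result> %d runs, %.1f boundaries/run, mean ",
                     "test AUC %.3f (95%% range %.3f-%.3f)\n"),
              x$n_runs, x$mean_mbs_per_run, x$mean_auc,
              x$auc_range_95[1], x$auc_range_95[2]))
  invisible(x)
}

#' Fraction of discovered boundaries containing each feature
#'
#' The robustness measure: for each feature, the number of boundaries
#' (across all runs) containing it divided by the total number of
#' boundaries. Accepts an `mb_cv_result`, an `mb_pool`, or a runs table
#' with an `mb` column of canonical keys.
#'
#' @param x Boundaries to count over.
#' @return Named numeric vector of fractions in `[0, 1]`, descending.
#' @export
feature_frequency <- function(x) {
  keys <- if (inherits(x, "mb_cv_result")) {
    x$runs_table$mb
  } else if (inherits(x, "mb_pool")) {
    vapply(x$mbs, function(m) canonicalize(m$features), character(1))
  } else if (is.data.frame(x)) {
    x$mb
  } else {
    stop_input("unsupported input to feature_frequency")
  }
  if (!length(keys)) stop_input("no boundaries to count over")
  members <- strsplit(keys, "|", fixed = TRUE)
  counts <- table(unlist(members))
  freq <- as.numeric(counts) / length(keys)
  names(freq) <- names(counts)
  sort(freq, decreasing = TRUE)
}

#' Features present in more than a threshold fraction of boundaries
#'
#' Strict inequality: a feature qualifies only when its frequency exceeds
#' the threshold (`> 0.75` reads "present in over 75% of boundaries").
#'
#' @param frequency Named vector from [feature_frequency()].
#' @param threshold Fraction in (0, 1).
#' @return Character vector of qualifying features, by descending frequency.
#' @export
robust_features <- function(frequency, threshold = 0.75) {
  if (threshold < 0 || threshold >= 1) {
    stop_input("threshold must be in [0,1)")
  }
  frequency <- sort(frequency, decreasing = TRUE)
  names(frequency)[frequency > threshold]
}
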