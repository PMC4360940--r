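# Target-information-equivalence search: enumerate every Markov boundary
# whose predictive accuracy is statistically equivalent to the reference
# boundary, by iteratively excluding discovered boundary members and
# re-inducing on the reduced feature set.

#' Equivalence criterion for admitting a candidate boundary
#'
#' Two readings of "equivalent predictive accuracy" are supported:
#' `"auc_margin"` admits a candidate whose AUC is within `margin` below the
#' reference AUC (deterministic; the default for unit-level work), and
#' `"paired_permutation"` admits a candidate when a two-sided paired
#' permutation test of the AUC difference (per-subject score swapping)
#' fails to reject at `alpha`.
#'
#' @param kind `"auc_margin"` or `"paired_permutation"`.
#' @param alpha Significance level for the permutation test.
#' @param margin Allowed AUC shortfall in margin mode.
#' @param n_permutations Permutation draws.
#' @return An object of class `mb_equivalence_criterion`.
#' @export
equivalence_criterion <- function(kind = c("auc_margin",
                                           "paired_permutation"),
                                  alpha = 0.05, margin = 0.01,
                                  n_permutations = 2000L) {
  kind <- match.arg(kind)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0,1)")
  if (margin < 0) stop_input("margin must be >= 0")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop_input("n_permutations must be >= 1")
  structure(list(kind = kind, alpha = alpha, margin = margin,
                 n_permutations = n_permutations),
            class = "mb_equivalence_criterion")
}

#' Test predictive equivalence of two score vectors
#'
#' Both score vectors must refer to the same subjects (paired). In
#' `auc_margin` mode the candidate passes iff
#' `AUC(new) >= AUC(ref) - margin`. In `paired_permutation` mode the
#' observed `|AUC(new) - AUC(ref)|` is compared against its null
#' distribution obtained by independently swapping the two models' scores
#' per subject; the candidate passes iff the two-sided permutation p-value
#' exceeds `alpha`.
#'
#' @param scores_new,scores_ref Per-subject score vectors of equal length.
#' @param labels 0/1 outcome vector; both classes must be present.
#' @param criterion An [equivalence_criterion()].
#' @param seed Seed for the permutation draws.
#' @return Logical, with attributes `auc_new`, `auc_ref`, and (permutation
#'   mode) `p_value`.
#' @export
equivalence_check <- function(scores_new, scores_ref, labels,
                              criterion = equivalence_criterion(),
                              seed = 1L) {
  if (length(scores_new) != length(scores_ref) ||
      length(scores_new) != length(labels)) {
    stop_input("scores_new, scores_ref and labels must have equal length")
  }
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop_input("labels must contain both classes")
  }
  auc_new <- compute_auc(scores_new, labels)
  auc_ref <- compute_auc(scores_ref, labels)
  if (criterion$kind == "auc_margin") {
    out <- auc_new >= auc_ref - criterion$margin - 1e-12
    attributes(out) <- list(auc_new = auc_new, auc_ref = auc_ref)
    return(out)
  }
  observed <- abs(auc_new - auc_ref)
  n <- length(labels)
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(criterion$n_permutations)) {
      swap <- stats::runif(n) < 0.5
      a <- ifelse(swap, scores_ref, scores_new)
      r <- ifelse(swap, scores_new, scores_ref)
      if (abs(compute_auc(a, labels) - compute_auc(r, labels)) >=
          observed - 1e-15) {
        hits <- hits + 1L
      }
    }
    hits
  })
  p <- (1 + count) / (1 + criterion$n_permutations)
  out <- p > criterion$alpha
  attributes(out) <- list(auc_new = auc_new, auc_ref = auc_ref, p_value = p)
  out
}

#' Canonical key of a feature set
#'
#' Sorted, `|`-joined feature names; injective over feature sets, used to
#' deduplicate boundaries and exclusion sets.
#'
#' @param features Character vector (order-free).
#' @return A single string.
#' @export
#' @examples
#' canonicalize(c("B", "A"))  # "A|B"
canonicalize <- function(features) {
  paste(sort(unique(as.character(features))), collapse = "|")
}

#' Enumerate all equivalent Markov boundaries on one training set
#'
#' The search (1) induces a reference boundary on the full feature set and
#' scores it by internal stratified cross-validation confined to `train`;
#' (2) seeds a removal agenda with every single-member exclusion of the
#' reference boundary; (3) for each agenda entry, re-induces a boundary
#' with those features excluded and admits it to the pool iff its feature
#' set is new and its internal-CV score passes the equivalence criterion
#' against the reference; each admission extends the agenda with every
#' union of an already-processed exclusion set and one member of the new
#' boundary; (4) stops when the agenda empties or `budget` entries have
#' been processed. The agenda is processed in (size ascending, then
#' lexicographic) order and never revisits an exclusion set, so the search
#' is deterministic and finite.
#'
#' @param train An `mb_dataset` (discrete features for the `"g2"` engine).
#' @param induction An [induction_config()].
#' @param eval_cfg An [eval_config()] used for internal-CV scoring.
#' @param criterion An [equivalence_criterion()].
#' @param budget Maximum number of agenda entries processed.
#' @return An `mb_pool`: list of admitted `mb_boundary` objects (admission
#'   order, reference first), `reference_auc`, the criterion, counters, and
#'   a `truncated` flag set when the budget was exhausted.
#' @export
run_tie_star <- function(train, induction = induction_config(),
                         eval_cfg = eval_config(),
                         criterion = equivalence_criterion(),
                         budget = 5000L) {
  stopifnot(inherits(train, "mb_dataset"))
  budget <- as.integer(budget)
  if (budget < 1L) stop_input("budget must be >= 1")
  cache <- new_ci_cache()

  ref <- induce_mb(train, character(0), induction, cache)
  if (!length(ref$features)) {
    warning("reference boundary is empty; returning an empty pool",
            call. = FALSE)
    return(new_pool(list(), NA_real_, criterion, truncated = FALSE,
                    n_evaluated = 0L))
  }
  ref_eval <- cv_scores(train, ref$features, eval_cfg)
  ref$auc <- ref_eval$auc
  pool <- list(ref)
  pool_keys <- canonicalize(ref$features)
  score_cache <- new.env(parent = emptyenv())
  score_cache[[pool_keys]] <- ref_eval

  # agenda and visited sets are tracked by canonical exclusion keys
  agenda <- lapply(ref$features, identity)
  names(agenda) <- vapply(agenda, canonicalize, character(1))
  visited <- character(0)
  processed <- list()
  n_eval <- 0L
  truncated <- FALSE

  pop_next <- function() {
    keys <- names(agenda)
    ord <- order(lengths(agenda), keys)
    agenda[[ord[1]]]
  }

  while (length(agenda)) {
    if (n_eval >= budget) {
      truncated <- TRUE
      break
    }
    excl <- pop_next()
    key <- canonicalize(excl)
    agenda[[key]] <- NULL
    visited <- c(visited, key)
    processed[[key]] <- excl
    n_eval <- n_eval + 1L

    mb <- withCallingHandlers(
      induce_mb(train, excl, induction, cache),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!length(mb$features)) next
    mb_key <- canonicalize(mb$features)
    if (mb_key %in% pool_keys) next

    ev <- score_cache[[mb_key]]
    if (is.null(ev)) {
      ev <- cv_scores(train, mb$features, eval_cfg)
      score_cache[[mb_key]] <- ev
    }
    mb$auc <- ev$auc
    ok <- equivalence_check(ev$scores, ref_eval$scores, train$outcome,
                            criterion, seed = eval_cfg$seed)
    if (!isTRUE(as.logical(ok))) next

    pool <- c(pool, list(mb))
    pool_keys <- c(pool_keys, mb_key)
    for (v in processed) {
      for (f in mb$features) {
        cand <- sort(unique(c(v, f)))
        ckey <- canonicalize(cand)
        if (!(ckey %in% visited) && !(ckey %in% names(agenda))) {
          agenda[[ckey]] <- cand
        }
      }
    }
  }

  new_pool(pool, ref$auc, criterion, truncated = truncated,
           n_evaluated = n_eval)
}

new_pool <- function(mbs, reference_auc, criterion, truncated, n_evaluated) {
  structure(list(mbs = mbs, reference_auc = reference_auc,
                 criterion = criterion, truncated = truncated,
                 n_evaluated = n_evaluated),
            class = "mb_pool")
}

#' @export
print.mb_pool <- function(x, ...) {
  cat("<mb_pool> ", length(x$mbs), " boundaries (reference AUC ",
      ifelse(is.na(x$reference_auc), "NA",
             sprintf("%.3f", x$reference_auc)),
      if (x$truncated) ", truncated" else "", ")\n", sep = "")
  for (mb in x$mbs) {
    cat(sprintf("  [%.3f] %s\n", mb$auc, canonicalize(mb$features)))
  }
  invisible(x)
}

#' @export
length.mb_pool <- function(x) length(x$mbs)

#' Serialize a pool of boundaries as a data frame
#'
#' @param x An `mb_pool`.
#' @param ... Unused.
#' @return Data frame with one row per boundary: canonical key, size, AUC.
#' @export
as.data.frame.mb_pool <- function(x, ...) {
  data.frame(
    mb = vapply(x$mbs, function(m) canonicalize(m$features), character(1)),
    size = vapply(x$mbs, function(m) length(m$features), integer(1)),
    auc = vapply(x$mbs, `[[`, numeric(1), "auc")
  )
}
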