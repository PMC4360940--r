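# Markov boundary induction: a semi-interleaved HITON-PC-style learner.
# The boundary of the outcome is grown by admitting candidates in order of
# univariate association strength, eliminating any member rendered
# conditionally independent of the outcome by a small subset of the other
# members, and finishing with a full backward pass.

#' Configuration for Markov boundary induction
#'
#' @param ci A [ci_config()] supplying the test engine, `alpha` and the
#'   maximum conditioning-set size `max_k`.
#' @param max_candidates Optional cap on the number of ranked candidates
#'   admitted to the inclusion queue.
#' @param seed Integer; reserved for tie-breaking (all ties are in fact
#'   broken lexicographically, so induction is deterministic regardless).
#' @return An object of class `mb_induction_config`.
#' @export
induction_config <- function(ci = ci_config(), max_candidates = NULL,
                             seed = 1L) {
  stopifnot(inherits(ci, "mb_ci_config"))
  structure(list(ci = ci, max_candidates = max_candidates,
                 seed = as.integer(seed)),
            class = "mb_induction_config")
}

new_boundary <- function(features, auc = NA_real_, provenance = list()) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop_input("duplicate features in boundary")
  structure(list(features = sort(features), auc = auc,
                 provenance = provenance),
            class = "mb_boundary")
}

#' @export
print.mb_boundary <- function(x, ...) {
  cat("<mb_boundary> {", paste(x$features, collapse = ", "), "}",
      if (!is.na(x$auc)) sprintf(" AUC=%.3f", x$auc), "\n", sep = "")
  invisible(x)
}

# Memoised CI testing against the outcome. Results depend only on
# (feature, conditioning set, engine/config), so one cache serves every
# re-induction on the same dataset -- the dominant cost of the TIE* search.
new_ci_cache <- function() new.env(parent = emptyenv())

outcome_test <- function(dataset, x, Z, config, cache) {
  key <- paste0(x, "|", paste(sort(Z), collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- ci_test(dataset$features[[x]], dataset$outcome,
                 if (length(Z)) dataset$features[Z] else NULL, config)
  cache[[key]] <- res
  res
}

# TRUE when some conditioning subset of `others` (size <= max_k) reliably
# renders `x` independent of the outcome. Unreliable tests are skipped:
# insufficient data never removes a candidate.
separable <- function(dataset, x, others, config, cache) {
  others <- sort(others)
  for (k in 0:min(config$max_k, length(others))) {
    sets <- if (k == 0L) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (Z in sets) {
      res <- outcome_test(dataset, x, Z, config, cache)
      if (res$reliable && res$p_value > config$alpha) return(TRUE)
    }
  }
  FALSE
}

#' Rank features by univariate association with the outcome
#'
#' Each feature outside `excluded` is tested unconditionally against the
#' outcome; features are ordered by ascending p-value, ties broken by
#' descending statistic then ascending name, making the ranking fully
#' deterministic.
#'
#' @param dataset An `mb_dataset` (discrete features for the `"g2"` engine).
#' @param excluded Character vector of feature names to leave out.
#' @param config An [induction_config()].
#' @return Character vector of ordered feature names, with the per-feature
#'   test table attached as attribute `"table"`.
#' @export
rank_by_association <- function(dataset, excluded = character(),
                                config = induction_config()) {
  stopifnot(inherits(dataset, "mb_dataset"))
  if (config$ci$engine == "g2") assert_discrete(dataset, "rank_by_association")
  cand <- setdiff(feature_names(dataset), excluded)
  if (!length(cand)) {
    out <- character(0)
    attr(out, "table") <- data.frame(feature = character(0),
                                     statistic = numeric(0),
                                     p_value = numeric(0),
                                     reliable = logical(0))
    return(out)
  }
  res <- lapply(cand, function(f) {
    ci_test(dataset$features[[f]], dataset$outcome, NULL, config$ci)
  })
  tab <- data.frame(
    feature = cand,
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    reliable = vapply(res, `[[`, logical(1), "reliable")
  )
  ord <- order(tab$p_value, -tab$statistic, tab$feature)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  out <- tab$feature
  attr(out, "table") <- tab
  out
}

#' Induce one Markov boundary of the outcome
#'
#' Semi-interleaved inclusion/elimination: candidates with reliable
#' univariate association enter in rank order; after each admission any
#' member rendered conditionally independent of the outcome given some
#' subset (size at most `max_k`) of the other members is eliminated, and a
#' final backward pass confirms no member is redundant. On data where the
#' outcome has no spouses (direct parents only, as in the synthetic
#' generator), the parents/children set returned here is the Markov
#' boundary.
#'
#' @inheritParams rank_by_association
#' @param cache Optional environment from `new_ci_cache()` to share
#'   memoised test results across repeated inductions on the same dataset.
#' @return An `mb_boundary` (empty, with a warning, when no feature shows
#'   reliable dependence on the outcome).
#' @export
induce_mb <- function(dataset, excluded = character(),
                      config = induction_config(), cache = NULL) {
  stopifnot(inherits(dataset, "mb_dataset"))
  if (config$ci$engine == "g2") assert_discrete(dataset, "induce_mb")
  if (is.null(cache)) cache <- new_ci_cache()
  ranked <- rank_by_association(dataset, excluded, config)
  tab <- attr(ranked, "table")
  open <- tab$feature[tab$reliable & tab$p_value <= config$ci$alpha]
  if (!is.null(config$max_candidates)) {
    open <- utils::head(open, config$max_candidates)
  }
  if (!length(open)) {
    warning("no feature shows reliable dependence on the outcome; ",
            "returning an empty boundary", call. = FALSE)
    return(new_boundary(character(0),
                        provenance = list(dataset = dataset$id,
                                          excluded = sort(excluded))))
  }

  eliminate <- function(members) {
    repeat {
      removed <- FALSE
      for (m in members) {
        if (separable(dataset, m, setdiff(members, m), config$ci, cache)) {
          members <- setdiff(members, m)
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
    members
  }

  tpc <- character(0)
  for (f in open) {
    tpc <- eliminate(c(tpc, f))
  }
  tpc <- eliminate(tpc)  # full backward pass

  new_boundary(tpc, provenance = list(dataset = dataset$id,
                                      excluded = sort(excluded)))
}

#' Check minimality of a Markov boundary
#'
#' A boundary is minimal when no single member can be rendered independent
#' of the outcome by conditioning on a subset (size at most `max_k`) of the
#' remaining members.
#'
#' @inheritParams induce_mb
#' @param mb An `mb_boundary` or character vector of feature names.
#' @return Logical.
#' @export
check_minimality <- function(dataset, mb, config = induction_config(),
                             cache = NULL) {
  features <- if (inherits(mb, "mb_boundary")) mb$features else
    as.character(mb)
  if (!length(features)) stop_input("boundary must be non-empty")
  if (is.null(cache)) cache <- new_ci_cache()
  for (m in features) {
    if (separable(dataset, m, setdiff(features, m), config$ci, cache)) {
      return(FALSE)
    }
  }
  TRUE
}
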