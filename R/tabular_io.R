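# Subject-level tabular datasets: typed schema, CSV round trip,
# imputation and equal-frequency discretization.

#' Describe one feature column
#'
#' A feature is `continuous` (numeric), `ordinal` (a small number of ordered
#' levels) or `binary` (exactly two levels). Ordinal and binary features are
#' stored internally as 0-based integer level codes; `levels` holds the
#' ordered labels written to / read from CSV.
#'
#' @param name Feature name (unique within a schema).
#' @param kind One of `"continuous"`, `"ordinal"`, `"binary"`.
#' @param levels Ordered character labels; required for ordinal (>= 2) and
#'   binary (exactly 2) features, must be `NULL` for continuous ones.
#' @return An object of class `mb_feature_schema`.
#' @export
#' @examples
#' feature_schema("pain", "ordinal", levels = c("0", "1", "2"))
feature_schema <- function(name, kind = c("continuous", "ordinal", "binary"),
                           levels = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("feature name must be a non-empty string")
  }
  if (kind == "continuous") {
    if (!is.null(levels)) stop_input("continuous features take no levels")
  } else {
    levels <- as.character(levels)
    if (kind == "binary" && length(levels) != 2L) {
      stop_input("binary feature '", name, "' must have exactly 2 levels")
    }
    if (kind == "ordinal" && length(levels) < 2L) {
      stop_input("ordinal feature '", name, "' must have >= 2 levels")
    }
    if (anyDuplicated(levels)) stop_input("duplicate levels in '", name, "'")
  }
  structure(list(name = name, kind = kind, levels = levels),
            class = "mb_feature_schema")
}

validate_schema <- function(schema) {
  if (!is.list(schema) || length(schema) == 0L) {
    stop_input("schema must be a non-empty list of feature_schema objects")
  }
  ok <- vapply(schema, inherits, logical(1), "mb_feature_schema")
  if (!all(ok)) stop_input("schema entries must be feature_schema objects")
  nms <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_input("feature names must be unique")
  names(schema) <- nms
  schema
}

#' Construct a validated subject-level dataset
#'
#' @param features Data frame, one row per subject. Continuous columns are
#'   numeric; ordinal/binary columns are 0-based integer level codes into
#'   the corresponding schema `levels`. `NA` marks missing values.
#' @param schema List of [feature_schema()] objects, one per column of
#'   `features` (matched by name).
#' @param outcome Integer/numeric vector of 0/1 outcome labels, one per
#'   subject; both classes must be present.
#' @param id Short label for provenance.
#' @return An object of class `mb_dataset`.
#' @export
mb_dataset <- function(features, schema, outcome, id = "dataset") {
  schema <- validate_schema(schema)
  features <- as.data.frame(features)
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop_input("dataset must have n >= 1 rows and p >= 1 feature columns")
  }
  if (!setequal(names(features), names(schema))) {
    stop_input("schema must cover exactly the feature columns")
  }
  features <- features[names(schema)]
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(features)) {
    stop_input("outcome length must equal the number of rows")
  }
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L))) {
    stop_input("outcome must be binary 0/1 with no missing values")
  }
  if (length(unique(outcome)) < 2L) {
    stop_input("outcome must contain both classes")
  }
  for (s in schema) {
    v <- features[[s$name]]
    if (s$kind == "continuous") {
      if (!is.numeric(v)) stop_input("column '", s$name, "' must be numeric")
    } else {
      v <- as.integer(v)
      bad <- !is.na(v) & (v < 0L | v >= length(s$levels))
      if (any(bad)) {
        stop_input("column '", s$name, "' has codes outside its levels")
      }
      features[[s$name]] <- v
    }
  }
  structure(list(features = features, schema = schema,
                 outcome = outcome, id = id),
            class = "mb_dataset")
}

#' @export
print.mb_dataset <- function(x, ...) {
  kinds <- table(vapply(x$schema, `[[`, character(1), "kind"))
  cat("<mb_dataset> '", x$id, "': ", nrow(x$features), " subjects x ",
      ncol(x$features), " features (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "), outcome prevalence ",
      sprintf("%.3f", mean(x$outcome)), "\n", sep = "")
  invisible(x)
}

#' @rdname mb_dataset
#' @param dataset An `mb_dataset`.
#' @export
feature_names <- function(dataset) names(dataset$features)

#' @rdname mb_dataset
#' @export
n_subjects <- function(dataset) nrow(dataset$features)

#' Read and write feature schemas
#'
#' Schemas are stored as a plain YAML map: `name: {kind: ..., levels: [...]}`.
#'
#' @param path File path.
#' @return `read_schema` returns a validated schema list.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_schema(lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    feature_schema(nm, entry$kind, levels = entry$levels)
  }))
}

#' @rdname read_schema
#' @param schema Schema list to write.
#' @export
write_schema <- function(schema, path) {
  schema <- validate_schema(schema)
  out <- lapply(schema, function(s) {
    e <- list(kind = s$kind)
    if (!is.null(s$levels)) e$levels <- as.list(s$levels)
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a subject-level dataset from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a header row, "." decimal
#' separator, and an empty cell marking a missing value. Ordinal/binary
#' cells hold the level labels declared in the schema. Rows with a missing
#' outcome are dropped (a message reports the count).
#'
#' @param path CSV file with one row per subject.
#' @param schema_path YAML schema covering every non-outcome column
#'   (see [read_schema()]).
#' @param outcome_name Name of the binary outcome column; values must parse
#'   to 0/1.
#' @param id Dataset label; defaults to the file name.
#' @return An `mb_dataset`.
#' @export
read_dataset <- function(path, schema_path, outcome_name = "outcome",
                         id = basename(path)) {
  if (!file.exists(path)) stop_input("dataset file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  if (nrow(raw) == 0L) stop_input("empty dataset file: ", path)
  schema <- read_schema(schema_path)
  if (!outcome_name %in% names(raw)) {
    stop_input("outcome column '", outcome_name, "' not found")
  }
  extra <- setdiff(names(schema), setdiff(names(raw), outcome_name))
  if (length(extra)) {
    stop_input("schema names unknown in CSV: ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(setdiff(names(raw), outcome_name), names(schema))
  if (length(missing_cols)) {
    stop_input("columns not covered by schema: ",
               paste(missing_cols, collapse = ", "))
  }

  keep <- !is.na(raw[[outcome_name]])
  if (any(!keep)) {
    message("dropped ", sum(!keep), " row(s) with missing outcome")
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop_input("no rows with observed outcome")
  y <- suppressWarnings(as.numeric(raw[[outcome_name]]))
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop_input("outcome column must be binary 0/1 after parsing")
  }

  features <- raw[names(schema)]
  for (s in schema) {
    v <- features[[s$name]]
    if (s$kind == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        stop_input("non-numeric value in continuous column '", s$name, "'")
      }
      features[[s$name]] <- num
    } else {
      code <- match(v, s$levels) - 1L
      if (any(is.na(code) & !is.na(v))) {
        stop_input("unknown level in column '", s$name, "'")
      }
      features[[s$name]] <- code
    }
  }
  mb_dataset(features, schema, as.integer(y), id = id)
}

#' Write a dataset as CSV plus YAML schema
#'
#' Inverse of [read_dataset()]: level codes are written back as their labels
#' and missing values as empty cells, so a write/read round trip reproduces
#' the dataset exactly.
#'
#' @param dataset An `mb_dataset`.
#' @param path Output CSV path.
#' @param schema_path Output schema path (YAML).
#' @param outcome_name Column name used for the outcome.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, schema_path,
                          outcome_name = "outcome") {
  stopifnot(inherits(dataset, "mb_dataset"))
  out <- dataset$features
  for (s in dataset$schema) {
    if (s$kind != "continuous") {
      out[[s$name]] <- s$levels[out[[s$name]] + 1L]
    } else {
      # fixed significant-digit formatting keeps reruns byte-identical
      out[[s$name]] <- ifelse(is.na(out[[s$name]]), NA,
                              formatC(out[[s$name]], digits = 15,
                                      format = "g"))
    }
  }
  out[[outcome_name]] <- dataset$outcome
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  write_schema(dataset$schema, schema_path)
  invisible(path)
}

#' Impute missing predictor values
#'
#' Deterministic single imputation per feature: median for continuous
#' columns, mode (smallest code on ties) for ordinal/binary columns. The
#' number of imputed cells is reported per column.
#'
#' @param dataset An `mb_dataset`.
#' @return The dataset with no missing feature values.
#' @export
impute_missing <- function(dataset) {
  stopifnot(inherits(dataset, "mb_dataset"))
  for (s in dataset$schema) {
    v <- dataset$features[[s$name]]
    nmiss <- sum(is.na(v))
    if (nmiss == 0L) next
    if (all(is.na(v))) stop_input("column '", s$name, "' entirely missing")
    if (s$kind == "continuous") {
      fill <- stats::median(v, na.rm = TRUE)
    } else {
      tab <- table(v)
      fill <- as.integer(names(tab)[which.max(tab)])
    }
    v[is.na(v)] <- fill
    dataset$features[[s$name]] <- v
    message("imputed ", nmiss, " value(s) in '", s$name, "'")
  }
  dataset
}

#' Equal-frequency discretization of continuous features
#'
#' Replaces every continuous column by an ordinal column with at most
#' `bins` levels, cutting at empirical quantiles so the bins hold roughly
#' equal counts. The mapping is monotone (a larger raw value never gets a
#' smaller level) and depends on the column's values only through their
#' empirical distribution, so it is equivariant under row permutation.
#' Ordinal and binary columns pass through unchanged. Required before
#' running the contingency-based G-squared independence tests on data with
#' continuous measurements.
#'
#' @param dataset An `mb_dataset` (missing values allowed; they stay `NA`).
#' @param bins Target number of bins, >= 2.
#' @param strategy Only `"equal_frequency"` is implemented.
#' @return The dataset with all-discrete features.
#' @export
discretize <- function(dataset, bins = 3L, strategy = "equal_frequency") {
  stopifnot(inherits(dataset, "mb_dataset"))
  strategy <- match.arg(strategy, "equal_frequency")
  bins <- as.integer(bins)
  if (bins < 2L) stop_input("bins must be >= 2")
  for (s in dataset$schema) {
    if (s$kind != "continuous") next
    v <- dataset$features[[s$name]]
    obs <- v[!is.na(v)]
    cuts <- unique(stats::quantile(obs, probs = seq_len(bins - 1L) / bins,
                                   names = FALSE, type = 7))
    code <- findInterval(v, cuts, left.open = TRUE)
    nlev <- length(unique(code[!is.na(code)]))
    # re-index so codes are consecutive 0..nlev-1
    code <- match(code, sort(unique(code[!is.na(code)]))) - 1L
    if (nlev < bins) {
      warning("column '", s$name, "' collapsed to ", nlev,
              " level(s) (too few distinct values)", call. = FALSE)
    }
    dataset$features[[s$name]] <- code
    dataset$schema[[s$name]] <- feature_schema(
      s$name, if (nlev == 2L) "binary" else "ordinal",
      levels = as.character(seq_len(max(nlev, 2L)) - 1L)
    )
  }
  dataset
}

# All-discrete check used by the G2-based induction path.
assert_discrete <- function(dataset, context) {
  cont <- vapply(dataset$schema, function(s) s$kind == "continuous",
                 logical(1))
  if (any(cont)) {
    stop_input(context, " requires discrete features; run discretize() ",
               "on: ", paste(names(dataset$schema)[cont], collapse = ", "))
  }
  invisible(TRUE)
}
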