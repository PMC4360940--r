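# End-to-end pipeline wiring: a plain-text (YAML) run configuration, the
# three analysis entry points (simulate / discover / crossval), and
# provenance-stamped file outputs. A thin command-line wrapper lives at
# inst/cli/mbtie.R.

#' Default run configuration
#'
#' A nested list mirroring the YAML run-configuration file. Every tunable
#' of the pipeline has its package default here; a user file only needs
#' the entries it overrides.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    dataset = NULL,      # list(path=, schema=, outcome=)
    generator = NULL,    # list(n_subjects=, groups=, weights=, n_noise=,
                         #      prevalence=, equivalence_noise=); in YAML
                         #      files use 'n_subjects', not a bare 'n'
                         #      (YAML 1.1 reads 'n' as a boolean)
    discretize = list(bins = 3L),
    ci = list(alpha = 0.05, max_k = 3L, min_avg_cell = 5, engine = "g2"),
    eval = list(kernel = "linear", cost_grid = c(0.01, 0.1, 1, 10),
                internal_folds = 5L, class_weighting = "balanced"),
    criterion = list(kind = "auc_margin", alpha = 0.05, margin = 0.01,
                     n_permutations = 2000L),
    tie = list(budget = 5000L),
    cv = list(repeats = 10L, k = 10L),
    plot = FALSE
  )
}

#' Read a run configuration file
#'
#' @param path YAML file; entries override the defaults of
#'   [default_run_config()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(default_run_config(), user)
}

config_objects <- function(config) {
  list(
    ci = do.call(ci_config, config$ci),
    eval = do.call(eval_config, c(config$eval, list(seed = config$seed))),
    criterion = do.call(equivalence_criterion, config$criterion)
  )
}

generator_from_config <- function(config) {
  g <- config$generator
  if (is.null(g)) stop_input("config has no 'generator' section")
  if (any(names(g) %in% c("TRUE", "FALSE"))) {
    # YAML 1.1 reads a bare key like `n` or `y` as a boolean
    stop_input("generator section has a boolean-mangled key; ",
               "use 'n_subjects' for the sample count in YAML files")
  }
  groups <- lapply(g[["groups"]], function(e) {
    members <- unlist(e[["members"]])
    equivalence_group(members, source = e[["source"]] %||% members[1],
                      transform_kinds = unlist(e[["transform_kinds"]] %||%
                                                 "copy"))
  })
  generator_config(n = g[["n"]] %||% g[["n_subjects"]],
                   groups = groups, weights = unlist(g[["weights"]]),
                   n_noise = g[["n_noise"]] %||% 0L,
                   prevalence = g[["prevalence"]] %||% 0.17,
                   equivalence_noise = g[["equivalence_noise"]] %||% 0,
                   seed = g[["seed"]] %||% config$seed)
}

load_config_dataset <- function(config) {
  if (!is.null(config$dataset)) {
    d <- config$dataset
    if (is.null(d$path) || !file.exists(d$path)) {
      stop_input("dataset path missing or not found: ", d$path %||% "<NULL>")
    }
    read_dataset(d$path, d$schema, outcome_name = d$outcome %||% "outcome")
  } else if (!is.null(config$generator)) {
    generate_dataset(generator_from_config(config))$dataset
  } else {
    stop_input("config needs a 'dataset' or 'generator' section")
  }
}

write_provenance <- function(config, out_dir, command) {
  prov <- list(command = command,
               package_version = as.character(utils::packageVersion("mbtie")),
               seed = config$seed,
               config = config)
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
}

#' Simulate a dataset to files
#'
#' Writes `dataset.csv`, `schema.yaml`, `ground_truth.json` and
#' `provenance.yaml` into the output directory. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config Run-configuration list with a `generator` section (see
#'   [default_run_config()]).
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config) {
  gen_cfg <- generator_from_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_dataset(gen_cfg)
  paths <- c(dataset = file.path(out_dir, "dataset.csv"),
             schema = file.path(out_dir, "schema.yaml"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  write_dataset(sim$dataset, paths[["dataset"]], paths[["schema"]])
  write_ground_truth(sim$ground_truth, paths[["ground_truth"]])
  write_provenance(config, out_dir, "simulate")
  message("simulate: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

prepare_dataset <- function(config) {
  ds <- load_config_dataset(config)
  ds <- impute_missing(ds)
  if (config$ci$engine == "g2") {
    ds <- discretize(ds, bins = config$discretize$bins %||% 3L)
  }
  ds
}

#' Run the equivalence search once on the full dataset
#'
#' Loads (or generates) the configured dataset, imputes and discretizes,
#' runs [run_tie_star()] on all subjects, and writes `pool.csv` (one row
#' per boundary: canonical key, size, AUC), `discover_report.txt` and
#' `provenance.yaml`.
#'
#' @param config Run-configuration list.
#' @return Invisibly, the `mb_pool`.
#' @export
cmd_discover <- function(config) {
  objs <- config_objects(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- prepare_dataset(config)
  pool <- run_tie_star(ds,
                       induction_config(ci = objs$ci, seed = config$seed),
                       objs$eval, objs$criterion,
                       budget = config$tie$budget %||% 5000L)
  tab <- as.data.frame(pool)
  utils::write.csv(tab, file.path(out_dir, "pool.csv"), row.names = FALSE)
  rpt <- c(
    sprintf("dataset: %s (n=%d, p=%d)", ds$id, n_subjects(ds),
            length(feature_names(ds))),
    sprintf("boundaries found: %d%s", length(pool$mbs),
            if (pool$truncated) " (budget truncated)" else ""),
    sprintf("reference AUC (internal CV): %s",
            ifelse(is.na(pool$reference_auc), "NA",
                   sprintf("%.4f", pool$reference_auc))),
    sprintf("mean boundary size: %s",
            ifelse(length(pool$mbs) == 0, "NA",
                   sprintf("%.2f", mean(tab$size))))
  )
  writeLines(rpt, file.path(out_dir, "discover_report.txt"))
  write_provenance(config, out_dir, "discover")
  message("discover: ", length(pool$mbs), " boundaries -> ", out_dir)
  invisible(pool)
}

#' Run the repeated stratified k-fold evaluation
#'
#' Loads (or generates) the configured dataset, runs [run_repeated_cv()]
#' and writes `runs.csv` (one row per boundary per run),
#' `feature_frequency.csv`, `cv_summary.txt`, `provenance.yaml` and
#' (optionally, `plot: true`) a feature-frequency bar chart
#' `feature_frequency.png`.
#'
#' @param config Run-configuration list.
#' @return Invisibly, the `mb_cv_result`.
#' @export
cmd_crossval <- function(config) {
  objs <- config_objects(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- prepare_dataset(config)
  res <- run_repeated_cv(ds,
                         repeats = config$cv$repeats %||% 10L,
                         k = config$cv$k %||% 10L,
                         induction = induction_config(ci = objs$ci,
                                                      seed = config$seed),
                         eval_cfg = objs$eval,
                         criterion = objs$criterion,
                         seed = config$seed,
                         budget = config$tie$budget %||% 5000L)
  utils::write.csv(res$runs_table, file.path(out_dir, "runs.csv"),
                   row.names = FALSE)
  freq <- data.frame(feature = names(res$feature_frequency),
                     frequency = as.numeric(res$feature_frequency))
  utils::write.csv(freq, file.path(out_dir, "feature_frequency.csv"),
                   row.names = FALSE)
  rpt <- c(
    sprintf("runs: %d (%d empty)", res$n_runs, res$n_empty_runs),
    sprintf("mean boundaries per run: %.2f", res$mean_mbs_per_run),
    sprintf("mean test AUC: %.4f", res$mean_auc),
    sprintf("AUC 95%% range: %.4f-%.4f", res$auc_range_95[1],
            res$auc_range_95[2]),
    sprintf("features in >75%% of boundaries: %s",
            paste(robust_features(res$feature_frequency, 0.75),
                  collapse = ", "))
  )
  writeLines(rpt, file.path(out_dir, "cv_summary.txt"))
  if (isTRUE(config$plot)) {
    grDevices::png(file.path(out_dir, "feature_frequency.png"),
                   width = 900, height = 500)
    graphics::barplot(res$feature_frequency, las = 2,
                      ylab = "fraction of boundaries",
                      main = "Feature robustness across boundaries")
    graphics::abline(h = 0.75, lty = 2)
    grDevices::dev.off()
  }
  write_provenance(config, out_dir, "crossval")
  message("crossval: mean AUC ", sprintf("%.3f", res$mean_auc),
          " -> ", out_dir)
  invisible(res)
}
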