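# Tabular I/O, run configuration and report formatting. Datasets are plain
# CSV with a header; configs are YAML (JSON accepted); the per-split trace is
# written as JSON lines so every candidate decision is auditable.

#' Load a mixture dataset from CSV
#'
#' @param path CSV file with a header row.
#' @param outcome Name of the outcome column.
#' @param exposures Character vector of exposure column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A [mixture_dataset()].
#' @export
load_dataset <- function(path, outcome, exposures, covariates = character(0)) {
  if (!file.exists(path)) {
    stop(sprintf("aretree_error_io: file not found: %s", path))
  }
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("aretree_error_io: empty file")
  need <- c(outcome, exposures, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("aretree_error_io: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]))
      stop(sprintf(
        "aretree_error_io: non-numeric value in column '%s' at data row %d",
        cn, if (length(bad)) bad[1] else NA_integer_))
    }
  }
  mixture_dataset(W = df[, covariates, drop = FALSE],
                  A = df[, exposures, drop = FALSE],
                  Y = df[[outcome]])
}

#' Write a mixture dataset as CSV
#' @param data A [mixture_dataset()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- data.frame(data$W, data$A, Y = data$Y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(folds = 10L, max_depth = 3L, min_node = 10L, epsilon = 0.01,
       alpha = 0.05, objective = "max", exhaustive = FALSE,
       threshold_strategy = "rounded", decimals = 1L, q = 20L,
       learners = c("mean", "glm", "glmnet", "ranger", "xgboost"),
       g_min = 0.025, internal_folds = 5L, seed = 1L,
       covariates = character(0), output_dir = ".")
}

#' Read a run configuration file
#'
#' YAML or JSON mapping of column roles and tuning parameters; unset
#' fields take the package defaults.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file values (CLI
#'   flags).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                                 simplifyVector = TRUE)
                else yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  roles <- c(cfg$outcome, cfg$exposures, cfg$covariates)
  if (anyDuplicated(roles)) {
    stop("aretree_error_config: outcome/exposure/covariate roles overlap")
  }
  cfg
}

config_to_tree <- function(cfg) {
  tree_config(d_max = cfg$max_depth, min_node = cfg$min_node,
              epsilon = cfg$epsilon, alpha = cfg$alpha,
              objective = cfg$objective, exhaustive = cfg$exhaustive,
              threshold_strategy = cfg$threshold_strategy,
              decimals = cfg$decimals, q = cfg$q, seed = cfg$seed)
}

config_to_ensemble <- function(cfg) {
  ensemble_config(learners = cfg$learners, v = cfg$internal_folds,
                  g_min = cfg$g_min)
}

#' Run region discovery from a configuration
#'
#' Loads the dataset, runs [aretree()], and writes the fold-specific
#' table, the pooled table, the per-split trace (JSON lines) and an echo
#' of the configuration into the output directory.
#'
#' @param cfg Configuration list from [read_run_config()]; must name
#'   `input`, `outcome` and `exposures`.
#' @return The `aretree_result`, invisibly; its `status` field
#'   distinguishes `"ok"` from `"no_consistent_region"`.
#' @export
run_discover <- function(cfg) {
  data <- load_dataset(cfg$input, cfg$outcome, cfg$exposures, cfg$covariates)
  fit <- aretree(data, K = cfg$folds, tree_cfg = config_to_tree(cfg),
                 ens_cfg = config_to_ensemble(cfg), seed = cfg$seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  ft <- fit$fold_table
  names(ft) <- c("Fold", "ARE", "SE", "Lower CI", "Upper CI", "p-value",
                 "Region")
  utils::write.csv(ft, out("fold_results.csv"), row.names = FALSE)
  if (fit$status == "ok") {
    pt <- fit$pooled$groups
    pt <- data.frame(Solution = pt$signature, ARE = pt$are, SE = pt$se,
                     `Lower CI` = pt$ci_low, `Upper CI` = pt$ci_high,
                     `p-value` = pt$p_value, Region = pt$region,
                     `Prop. folds` = pt$proportion_folds,
                     check.names = FALSE)
    utils::write.csv(pt, out("pooled_results.csv"), row.names = FALSE)
  } else {
    writeLines("no consistent region found", out("pooled_results.csv"))
  }
  con <- file(out("split_trace.jsonl"), "w")
  for (f in fit$fold_results) {
    if (!is.null(f$trace) && nrow(f$trace)) {
      tr <- f$trace
      tr$fold <- f$fold_id
      for (i in seq_len(nrow(tr))) {
        writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                    digits = NA, na = "null"), con)
      }
    }
  }
  close(con)
  yaml::write_yaml(cfg[!vapply(cfg, is.function, logical(1))],
                   out("config_echo.yaml"))
  invisible(fit)
}

#' Simulate a dataset from a named DGP and write it as CSV
#'
#' @param spec_name One of `"discrete"`, `"continuous"`, `"null"`.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param out Output CSV path.
#' @return The generated [mixture_dataset()], invisibly.
#' @export
run_simulate <- function(spec_name = c("discrete", "continuous", "null"),
                         n, seed = 1L, out) {
  spec_name <- match.arg(spec_name)
  spec <- switch(spec_name, discrete = discrete_dgp_spec(),
                 continuous = continuous_dgp_spec(), null = null_dgp_spec())
  d <- generate_mixture(spec, n, seed = seed)
  write_dataset(d, out)
  invisible(d)
}

#' Run the replicate simulation harness from a configuration
#'
#' @param spec_name One of `"discrete"`, `"continuous"`, `"null"`.
#' @param n_grid Sample sizes.
#' @param reps Replicates per size.
#' @param cfg Configuration list (tree/ensemble/seed fields as in
#'   [read_run_config()]).
#' @param out_dir Output directory for `simulation_summary.csv` and
#'   `simulation_replicates.csv`.
#' @param data_adaptive Track the per-replicate data-adaptive truth.
#' @return The `simulation_report`, invisibly.
#' @export
run_evaluate <- function(spec_name = c("discrete", "continuous", "null"),
                         n_grid, reps, cfg = run_config_defaults(),
                         out_dir = ".", data_adaptive = FALSE) {
  spec_name <- match.arg(spec_name)
  spec <- switch(spec_name, discrete = discrete_dgp_spec(),
                 continuous = continuous_dgp_spec(), null = null_dgp_spec())
  oracle <- switch(spec_name,
                   discrete = oracle_region_discrete(spec, seed = cfg$seed)$region,
                   continuous = continuous_oracle_region(),
                   null = NULL)
  rep_out <- run_simulation_study(
    spec, n_grid = n_grid, reps = reps, K = cfg$folds,
    tree_cfg = config_to_tree(cfg), ens_cfg = config_to_ensemble(cfg),
    seed = cfg$seed, oracle_region = oracle, data_adaptive = data_adaptive)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep_out$summary,
                   file.path(out_dir, "simulation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(rep_out$replicates,
                   file.path(out_dir, "simulation_replicates.csv"),
                   row.names = FALSE)
  invisible(rep_out)
}
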