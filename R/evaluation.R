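#' Region-recovery classification metrics
#'
#' Compares membership under the estimated region against membership under
#' the oracle region on the same rows via the standard confusion-matrix
#' ratios.
#'
#' @param true_member Binary vector: oracle-region membership.
#' @param est_member Binary vector: estimated-region membership.
#' @return List with `sensitivity`, `specificity`, `accuracy`; sensitivity
#'   (specificity) is `NA` when the truth has no positives (negatives).
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
classification_metrics <- function(true_member, est_member) {
  if (length(true_member) != length(est_member)) {
    stop("aretree_error_length: membership vectors must have equal length")
  }
  tr <- as.logical(true_member); es <- as.logical(est_member)
  tp <- sum(tr & es); fn <- sum(tr & !es)
  tn <- sum(!tr & !es); fp <- sum(!tr & es)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(tr))
}

#' Replicate-level estimator metrics
#'
#' Aggregates estimates across simulation replicates against a fixed
#' truth: absolute bias `|mean - psi0|`, percent bias
#' `100 (mean - psi0) / psi0` (flagged undefined at psi0 = 0), the MSE
#' decomposition `(mean - psi0)^2 + sample variance` (n - 1 denominator),
#' and empirical CI coverage.
#'
#' @param estimates Numeric vector of replicate estimates.
#' @param ci_low,ci_high Numeric vectors of per-replicate interval
#'   endpoints (may be `NULL`, in which case coverage is `NA`).
#' @param psi0 True parameter value. May be a vector of per-replicate
#'   truths (data-adaptive parameters), in which case bias, MSE and
#'   coverage are computed on the per-replicate errors.
#' @return List with `abs_bias`, `percent_bias`, `mse`, `coverage`,
#'   `n_reps`.
#' @export
estimator_metrics <- function(estimates, ci_low = NULL, ci_high = NULL,
                              psi0) {
  keep <- is.finite(estimates)
  estimates <- estimates[keep]
  if (length(psi0) > 1L) psi0 <- psi0[keep]
  if (length(estimates) < 2L) {
    stop("aretree_error_reps: need >= 2 replicates for the variance term")
  }
  err <- estimates - psi0
  bias <- mean(err)
  mse <- bias^2 + stats::var(estimates - (if (length(psi0) > 1L) psi0 else 0))
  coverage <- NA_real_
  if (!is.null(ci_low) && !is.null(ci_high)) {
    lo <- ci_low[keep]; hi <- ci_high[keep]
    coverage <- mean(lo <= psi0 & psi0 <= hi)
  }
  pb <- if (all(psi0 == 0)) NA_real_ else 100 * bias / mean(psi0)
  list(abs_bias = abs(bias), percent_bias = pb, mse = mse,
       coverage = coverage, n_reps = length(estimates))
}

# consensus region of a replicate: the largest region group's rules with
# mean cutpoints across that group's folds (ties broken by first group)
consensus_region <- function(result) {
  if (result$status != "ok") return(NULL)
  sigs <- vapply(result$fold_results, function(f) region_signature(f$region),
                 character(1))
  top <- names(sort(table(sigs), decreasing = TRUE))[1]
  in_g <- result$fold_results[sigs == top]
  cp <- summarize_cutpoints(lapply(in_g, `[[`, "region"))
  cons <- tryCatch(
    region_from_frame(data.frame(exposure = cp$exposure,
                                 operator = cp$operator,
                                 cutpoint = cp$mean)),
    error = function(e) NULL)
  # mean cutpoints can imply an empty interval when folds disagree on the
  # operator mix for an exposure; fall back to the first fold of the group
  if (is.null(cons)) cons <- in_g[[1]]$region
  cons
}

#' Replicate simulation harness
#'
#' Repeats the full pipeline (generate data, K-fold region discovery and
#' CV-TMLE estimation) and aggregates discovery rate, bias, MSE, coverage
#' and region-recovery classification metrics per sample size. Two truths
#' are tracked when requested: the fixed oracle-region ARE, and the
#' data-adaptive truth (the true ARE of each replicate's own discovered
#' rule under the generating distribution). Replicates without a
#' discovered region count toward the discovery rate but are excluded
#' from bias/MSE (no estimate exists); the exclusion count is reported.
#'
#' @param spec A `dgp_spec`.
#' @param n_grid Integer vector of sample sizes.
#' @param reps Replicates per sample size (>= 1).
#' @param K Cross-estimation folds (default 2 for simulation speed).
#' @param tree_cfg,ens_cfg Search and ensemble configurations.
#' @param seed Master seed; replicate r at size n uses a derived stream.
#' @param oracle_region Optional fixed [region()] used for the oracle
#'   truth and classification metrics (e.g. [continuous_oracle_region()]
#'   or the output of [oracle_region_discrete()]).
#' @param data_adaptive If `TRUE`, compute the per-replicate true ARE of
#'   the discovered consensus rule by Monte Carlo.
#' @param n_mc_truth Monte Carlo size for per-replicate truths.
#' @return List of class `simulation_report`: `summary` (one row per n)
#'   and `replicates` (per-replicate records).
#' @export
run_simulation_study <- function(spec, n_grid, reps, K = 2L,
                                 tree_cfg = tree_config(),
                                 ens_cfg = ensemble_config(c("mean", "glm")),
                                 seed = 1L, oracle_region = NULL,
                                 data_adaptive = FALSE,
                                 n_mc_truth = 20000L) {
  stopifnot(reps >= 1)
  psi0_oracle <- NA_real_
  if (!is.null(oracle_region)) {
    tr <- true_are(spec, oracle_region, n_mc = 100000L, seed = seed,
                   n_inner = 200L)
    psi0_oracle <- tr$are
  }
  rows <- list()
  for (n in n_grid) {
    for (r in seq_len(reps)) {
      rs <- as.integer(seed + 100003 * r + n)
      rec <- list(n = n, rep = r, seed = rs, discovered = FALSE,
                  any_split = FALSE, are = NA_real_, se = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  psi0_adaptive = NA_real_, sensitivity = NA_real_,
                  specificity = NA_real_, accuracy = NA_real_,
                  region = NA_character_, error = NA_character_)
      res <- tryCatch({
        d <- generate_mixture(spec, n, seed = rs)
        fit <- aretree(d, K = K, tree_cfg = tree_cfg, ens_cfg = ens_cfg,
                       seed = rs)
        rec$any_split <- any(vapply(fit$fold_results,
                                    function(f) !is.null(f$region),
                                    logical(1)))
        if (fit$status == "ok") {
          rec$discovered <- TRUE
          rec$are <- fit$pooled$omnibus$psi
          rec$se <- fit$pooled$omnibus$se
          rec$ci_low <- fit$pooled$omnibus$ci_low
          rec$ci_high <- fit$pooled$omnibus$ci_high
          cons <- consensus_region(fit)
          rec$region <- format(cons)
          if (!is.null(oracle_region)) {
            cm <- classification_metrics(
              region_membership(oracle_region, d$A),
              region_membership(cons, d$A))
            rec$sensitivity <- cm$sensitivity
            rec$specificity <- cm$specificity
            rec$accuracy <- cm$accuracy
          }
          if (data_adaptive) {
            tr <- tryCatch(
              true_are(spec, cons, n_mc = n_mc_truth, seed = rs + 1L,
                       n_inner = 100L),
              error = function(e) NULL)
            rec$psi0_adaptive <- if (is.null(tr)) NA_real_ else tr$are
          }
        }
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      rows[[length(rows) + 1L]] <- as.data.frame(res,
                                                 stringsAsFactors = FALSE)
    }
  }
  reps_tab <- do.call(rbind, rows)
  summary_tab <- do.call(rbind, lapply(unique(reps_tab$n), function(nn) {
    d <- reps_tab[reps_tab$n == nn, ]
    ok <- d$discovered & is.finite(d$are)
    out <- data.frame(
      n = nn, reps = nrow(d),
      discovery_rate = mean(d$discovered),
      any_split_rate = mean(d$any_split),
      n_excluded = sum(!ok),
      mean_are = if (any(ok)) mean(d$are[ok]) else NA_real_,
      abs_bias_oracle = NA_real_, mse_oracle = NA_real_,
      coverage_oracle = NA_real_,
      abs_bias_adaptive = NA_real_, mse_adaptive = NA_real_,
      coverage_adaptive = NA_real_,
      sensitivity = mean(d$sensitivity[ok]),
      specificity = mean(d$specificity[ok]),
      accuracy = mean(d$accuracy[ok]))
    if (sum(ok) >= 2 && is.finite(psi0_oracle)) {
      m <- estimator_metrics(d$are[ok], d$ci_low[ok], d$ci_high[ok],
                             psi0_oracle)
      out$abs_bias_oracle <- m$abs_bias
      out$mse_oracle <- m$mse
      out$coverage_oracle <- m$coverage
    }
    ok_ad <- ok & is.finite(d$psi0_adaptive)
    if (sum(ok_ad) >= 2) {
      m <- estimator_metrics(d$are[ok_ad], d$ci_low[ok_ad], d$ci_high[ok_ad],
                             d$psi0_adaptive[ok_ad])
      out$abs_bias_adaptive <- m$abs_bias
      out$mse_adaptive <- m$mse
      out$coverage_adaptive <- m$coverage
    }
    out
  }))
  structure(list(summary = summary_tab, replicates = reps_tab,
                 psi0_oracle = psi0_oracle, seed = seed),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("simulation report\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
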