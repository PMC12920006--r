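#' Balanced cross-validation fold assignment
#'
#' @param n Number of observations.
#' @param K Number of folds (2 <= K <= n).
#' @param seed Integer seed; the assignment is deterministic given
#'   `(n, K, seed)`.
#' @return Integer vector of fold labels in `1:K` with sizes differing by
#'   at most one.
#' @export
make_folds <- function(n, K, seed = 1L) {
  K <- as.integer(K)
  if (K < 2 || K > n) {
    stop("aretree_error_folds: need 2 <= K <= n")
  }
  set.seed(as.integer(seed))
  sample(rep(seq_len(K), length.out = n))
}

subset_rows <- function(data, idx) {
  mixture_dataset(W = data$W[idx, , drop = FALSE],
                  A = data$A[idx, , drop = FALSE],
                  Y = data$Y[idx])
}

#' Fit one cross-estimation fold
#'
#' Discovers a region on the parameter-generating sample (all folds except
#' `k`), trains the full super-learner nuisances there with T defined by
#' that region, applies them to the held-out estimation sample, and runs a
#' fold-level TMLE for the ARE on the held-out sample alone. Validation
#' predictions are retained for the pooled update.
#'
#' @param data A [mixture_dataset()].
#' @param assignment Fold assignment from [make_folds()].
#' @param k Fold index to hold out.
#' @param tree_cfg A [tree_config()].
#' @param ens_cfg An [ensemble_config()].
#' @param record Global outcome-scaling record (from [scale_outcome()] on
#'   the full outcome) so fold and pooled updates share one scale.
#' @param seed Integer seed for the fold's nuisance fits.
#' @return Object of class `fold_result`: `fold_id`, `region` (or `NULL`),
#'   `available` (logical: fold-level estimate computable), `fit`
#'   (`tmle_fit` or `NULL`), and `pred` (validation-sample `Q1`, `QT`, `g`,
#'   `T`, `Y_scaled`, row indices).
#' @export
fit_fold <- function(data, assignment, k, tree_cfg = tree_config(),
                     ens_cfg = ensemble_config(), record = NULL,
                     seed = 1L) {
  valid_idx <- which(assignment == k)
  train_idx <- which(assignment != k)
  if (!length(valid_idx)) stop("aretree_error_folds: empty fold")
  if (is.null(record)) record <- scale_outcome(data$Y)$record
  train <- subset_rows(data, train_idx)
  tree <- build_tree_greedy(train, tree_cfg)
  ex <- if (tree_cfg$exhaustive) search_exhaustive(train, tree_cfg)
        else extract_region(tree)
  res <- list(fold_id = k, region = NULL, available = FALSE, fit = NULL,
              pred = NULL, n_valid = length(valid_idx), trace = tree$trace)
  class(res) <- "fold_result"
  if (!ex$found) return(res)
  res$region <- ex$region
  T_train <- region_membership(ex$region, train$A)
  T_valid <- region_membership(ex$region, data$A[valid_idx, , drop = FALSE])
  if (length(unique(T_train)) < 2) return(res)
  Ys <- if (record$range > 0) (data$Y - record$min) / record$range
        else rep(0.5, data$n)
  Q_fit <- fit_outcome_ensemble(T_train, train$W, Ys[train_idx], ens_cfg,
                                seed = seed)
  g_fit <- fit_propensity_ensemble(T_train, train$W, ens_cfg,
                                   seed = seed + 1L)
  W_valid <- data$W[valid_idx, , drop = FALSE]
  Q1 <- clip01(Q_fit$predict(1, W_valid))
  Q0 <- clip01(Q_fit$predict(0, W_valid))
  QT <- ifelse(T_valid == 1, Q1, Q0)
  g <- g_fit$predict(W_valid)
  res$pred <- list(Q1 = Q1, QT = QT, g = g, T = T_valid,
                   Y_scaled = Ys[valid_idx], idx = valid_idx)
  if (length(unique(T_valid)) < 2 || sum(T_valid) == 0) {
    return(res)  # region found, estimate unavailable in this fold
  }
  upd <- tryCatch(
    tmle_treated_mean(list(Q1 = Q1, QT = QT, g = g), T_valid, Ys[valid_idx]),
    error = function(e) NULL)
  if (is.null(upd)) return(res)
  res$available <- TRUE
  res$fit <- estimate_are(upd$Qstar1, upd$QstarT, T_valid, g, Ys[valid_idx],
                          record, upd$eps_fluct)
  res
}

#' Summarize cutpoints across folds for one region group
#'
#' For folds whose regions share an exposure-name signature, reports the
#' per-rule arithmetic mean cutpoint and (min, max) range across folds,
#' formatted as `"name op mean (min, max)"`. Rules with different
#' operators on the same exposure are reported separately per operator.
#'
#' @param regions List of `region` objects with a shared variable
#'   signature.
#' @return Data frame with `exposure`, `operator`, `mean`, `min`, `max`,
#'   `label`.
#' @export
summarize_cutpoints <- function(regions) {
  if (!length(regions)) stop("aretree_error_group: empty region group")
  frames <- do.call(rbind, lapply(regions, region_to_frame))
  if (!nrow(frames)) stop("aretree_error_group: full-space regions in group")
  key <- paste(frames$exposure, frames$operator)
  out <- do.call(rbind, lapply(split(frames, key), function(d) {
    data.frame(exposure = d$exposure[1], operator = d$operator[1],
               mean = mean(d$cutpoint), min = min(d$cutpoint),
               max = max(d$cutpoint), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  op <- ifelse(out$operator == "LE", "<=", ">")
  fmt <- function(x) format(x, digits = 4, trim = TRUE)
  out$label <- paste0(out$exposure, " ", op, " ", fmt(out$mean),
                      " (", fmt(out$min), ", ", fmt(out$max), ")")
  out
}

# One pooled fluctuation over stacked validation predictions from a set of
# folds; psi is the K-average of fold-level plug-in means (the CV formula),
# se from the EIF over the stacked sample.
pooled_update <- function(fold_results, record) {
  preds <- lapply(fold_results, `[[`, "pred")
  Q1 <- unlist(lapply(preds, `[[`, "Q1"))
  QT <- unlist(lapply(preds, `[[`, "QT"))
  g <- unlist(lapply(preds, `[[`, "g"))
  T_all <- unlist(lapply(preds, `[[`, "T"))
  Y_all <- unlist(lapply(preds, `[[`, "Y_scaled"))
  fold_of <- rep(seq_along(preds),
                 vapply(preds, function(p) length(p$Y_scaled), integer(1)))
  if (sum(T_all) == 0) {
    return(list(psi = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_,
                eps_fluct = NA_real_, eif = NULL, n = length(Y_all)))
  }
  upd <- tmle_treated_mean(list(Q1 = Q1, QT = QT, g = g), T_all, Y_all)
  per_fold <- vapply(split(upd$Qstar1 - Y_all, fold_of), mean, numeric(1))
  psi_s <- mean(per_fold)
  psi <- unscale_estimate(psi_s, record, "difference")
  eif_s <- (T_all / g) * (Y_all - upd$QstarT) + upd$Qstar1 - Y_all - psi_s
  eif <- unscale_estimate(eif_s, record, "difference")
  n <- length(Y_all)
  se <- sqrt(stats::var(eif) / n)
  z <- if (se > 0) psi / se else 0
  list(psi = psi, se = se, ci_low = psi - 1.96 * se, ci_high = psi + 1.96 * se,
       p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(psi == 0),
       eps_fluct = upd$eps_fluct, eif = eif, n = n)
}

#' Pooled cross-validated TMLE over fold results
#'
#' Stacks the validation-sample nuisance predictions from all folds, runs a
#' single fluctuation on the stacked data, and computes the cross-validated
#' ARE as the K-fold average of fold-level plug-in means, with an
#' efficient-influence-function standard error over all n. If any fold
#' found no region (or its validation predictions are unusable) the result
#' is flagged `no_consistent_region` and no estimate is produced.
#' Additionally, per region group (folds sharing an exposure-name
#' signature) the same pooled update is run on that group's folds alone,
#' with the selection proportion and a cutpoint summary.
#'
#' @param fold_results List of `fold_result` objects from [fit_fold()].
#' @param record Global outcome-scaling record.
#' @return Object of class `pooled_result`: `status`
#'   (`"ok"`/`"no_consistent_region"`), `omnibus` (pooled estimate list),
#'   and `groups` (data frame with one row per region group: signature,
#'   ARE, SE, CI, p, proportion of folds, cutpoint summary label).
#' @export
pool_tmle <- function(fold_results, record) {
  K <- length(fold_results)
  usable <- vapply(fold_results,
                   function(f) !is.null(f$region) && !is.null(f$pred),
                   logical(1))
  if (!all(usable)) {
    return(structure(list(status = "no_consistent_region", omnibus = NULL,
                          groups = NULL, K = K), class = "pooled_result"))
  }
  omni <- pooled_update(fold_results, record)
  sigs <- vapply(fold_results, function(f) region_signature(f$region),
                 character(1))
  groups <- do.call(rbind, lapply(unique(sigs), function(sg) {
    in_g <- fold_results[sigs == sg]
    gu <- pooled_update(in_g, record)
    cp <- summarize_cutpoints(lapply(in_g, `[[`, "region"))
    data.frame(signature = sg, are = gu$psi, se = gu$se,
               ci_low = gu$ci_low, ci_high = gu$ci_high,
               p_value = gu$p_value,
               proportion_folds = length(in_g) / K,
               region = paste(cp$label, collapse = " & "),
               stringsAsFactors = FALSE)
  }))
  structure(list(status = "ok", omnibus = omni, groups = groups, K = K),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("no consistent region found (a fold returned the full space)\n")
    return(invisible(x))
  }
  cat(sprintf("pooled CV-TMLE ARE = %.4g (SE %.4g, 95%% CI [%.4g, %.4g], p = %.3g)\n",
              x$omnibus$psi, x$omnibus$se, x$omnibus$ci_low,
              x$omnibus$ci_high, x$omnibus$p_value))
  cat("region groups:\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Cross-validated discovery and estimation of an exposure threshold region
#'
#' The main entry point: runs K-fold cross-estimation in which each fold's
#' parameter-generating sample discovers a threshold region with the
#' significance-filtered tree and trains super-learner nuisances, and the
#' held-out estimation sample provides a fold-level targeted ARE estimate;
#' a pooled TMLE update over the stacked held-out predictions gives the
#' omnibus cross-validated ARE. If any fold finds no region the procedure
#' reports "no consistent region found".
#'
#' @param data A [mixture_dataset()].
#' @param K Number of cross-estimation folds (default 10; 2 is common for
#'   simulation work).
#' @param tree_cfg A [tree_config()].
#' @param ens_cfg An [ensemble_config()].
#' @param seed Integer master seed; fold assignment and per-fold learner
#'   seeds all derive from it.
#' @return Object of class `aretree_result`: `status`, `fold_table` (one
#'   row per fold: ARE, SE, CI, p-value, region string), `pooled`
#'   (a `pooled_result`), `fold_results`, `folds`, `record`.
#' @examples
#' \donttest{
#' d <- generate_mixture(continuous_dgp_spec(), n = 400, seed = 7)
#' fit <- aretree(d, K = 2, tree_cfg = tree_config(d_max = 2),
#'                ens_cfg = ensemble_config(c("mean", "glm")), seed = 7)
#' print(fit)
#' }
#' @export
aretree <- function(data, K = 10L, tree_cfg = tree_config(),
                    ens_cfg = ensemble_config(), seed = 1L) {
  stopifnot(inherits(data, "mixture_dataset"))
  seed <- as.integer(seed)
  record <- scale_outcome(data$Y)$record
  folds <- make_folds(data$n, K, seed = seed)
  fold_results <- lapply(seq_len(K), function(k) {
    fit_fold(data, folds, k, tree_cfg, ens_cfg, record,
             seed = seed + 1009L * k)
  })
  pooled <- pool_tmle(fold_results, record)
  fold_table <- do.call(rbind, lapply(fold_results, function(f) {
    data.frame(
      fold = f$fold_id,
      are = if (f$available) f$fit$psi_hat else NA_real_,
      se = if (f$available) f$fit$se else NA_real_,
      ci_low = if (f$available) f$fit$ci_low else NA_real_,
      ci_high = if (f$available) f$fit$ci_high else NA_real_,
      p_value = if (f$available) f$fit$p_value else NA_real_,
      region = if (is.null(f$region)) "<none>" else format(f$region),
      stringsAsFactors = FALSE)
  }))
  structure(list(status = pooled$status, fold_table = fold_table,
                 pooled = pooled, fold_results = fold_results,
                 folds = folds, record = record, K = K, seed = seed),
            class = "aretree_result")
}

#' @export
print.aretree_result <- function(x, ...) {
  cat(sprintf("aretree: %d-fold cross-estimated threshold region\n", x$K))
  cat("fold-specific results:\n")
  print(x$fold_table, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$pooled)
  invisible(x)
}
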