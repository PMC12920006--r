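test_that("make_folds: balance, determinism, preconditions", {
  f <- make_folds(10, 5, seed = 3)
  expect_equal(as.numeric(table(f)), rep(2, 5))
  expect_identical(make_folds(101, 7, seed = 9), make_folds(101, 7, seed = 9))
  expect_error(make_folds(10, 1, seed = 1), "folds")
  expect_error(make_folds(10, 11, seed = 1), "folds")
})

test_that("fit_fold separates discovery from estimation and handles no-region", {
  d <- step_dataset(n = 400, effect = 10, sd = 0.1, seed = 21)
  assign <- make_folds(d$n, 2, seed = 21)
  rec <- scale_outcome(d$Y)$record
  for (k in 1:2) {
    fr <- fit_fold(d, assign, k, tree_config(objective = "max"), fast_ens(),
                   rec, seed = k)
    expect_false(is.null(fr$region))
    expect_true(fr$available)
    expect_gt(fr$fit$psi_hat, 0)
    fs <- region_to_frame(fr$region)
    expect_true(any(fs$exposure == "A1" & fs$operator == "LE"))
    # validation indices are exactly the held-out fold
    expect_identical(fr$pred$idx, which(assign == k))
  }
  # null data: regions rare; absent region leaves estimate fields empty
  dn <- noise_dataset(n = 300, seed = 22)
  an <- make_folds(dn$n, 2, seed = 22)
  frn <- fit_fold(dn, an, 1, tree_config(alpha = 1e-8), fast_ens(),
                  scale_outcome(dn$Y)$record, seed = 1)
  expect_null(frn$region)
  expect_false(frn$available)
  expect_null(frn$fit)
})

test_that("pool_tmle: no_consistent_region when any fold lacks a region", {
  d <- step_dataset(n = 300, effect = 10, seed = 23)
  assign <- make_folds(d$n, 2, seed = 23)
  rec <- scale_outcome(d$Y)$record
  f1 <- fit_fold(d, assign, 1, tree_config(), fast_ens(), rec, seed = 1)
  f2 <- fit_fold(d, assign, 2, tree_config(), fast_ens(), rec, seed = 2)
  f2$region <- NULL; f2$pred <- NULL
  out <- pool_tmle(list(f1, f2), rec)
  expect_equal(out$status, "no_consistent_region")
  expect_null(out$omnibus)
})

test_that("pooled ARE with zero stacked fluctuation equals the K-fold average", {
  # build synthetic fold predictions for which the stacked score is already
  # solved (Q* = Q, eps = 0): pooled psi must equal the average of fold
  # plug-in means exactly
  set.seed(24)
  rec <- list(min = 0, range = 1)
  folds <- lapply(1:2, function(k) {
    n <- 40
    T_ind <- rep(c(1, 0), each = n / 2)
    Y <- runif(n)
    Q <- Y                      # residuals zero => score solved at eps = 0
    f <- list(fold_id = k, region = region(list(threshold_rule("A1", "LE", 1))),
              available = TRUE, fit = NULL,
              pred = list(Q1 = Q, QT = Q, g = rep(0.5, n), T = T_ind,
                          Y_scaled = Y, idx = seq_len(n) + (k - 1) * n))
    class(f) <- "fold_result"
    f
  })
  out <- pool_tmle(folds, rec)
  expect_equal(out$status, "ok")
  manual <- mean(vapply(folds, function(f) mean(f$pred$Q1 - f$pred$Y_scaled),
                        numeric(1)))
  expect_equal(out$omnibus$psi, manual, tolerance = 1e-5)
  expect_lt(abs(out$omnibus$eps_fluct), 1e-3)
  expect_lt(abs(mean(out$omnibus$eif)), 1e-8)
})

test_that("fold grouping proportions mirror the variable-signature split", {
  set.seed(25)
  rec <- list(min = 0, range = 1)
  mk <- function(k, rules) {
    n <- 30
    Y <- runif(n)
    f <- list(fold_id = k, region = region(rules), available = TRUE,
              fit = NULL,
              pred = list(Q1 = Y, QT = Y, g = rep(0.5, n),
                          T = rep(c(1, 0), 15), Y_scaled = Y,
                          idx = seq_len(n)))
    class(f) <- "fold_result"
    f
  }
  folds <- c(
    lapply(1:7, function(k) mk(k, list(threshold_rule("X5", "GT", 1.9 + 0.01 * k)))),
    lapply(8:9, function(k) mk(k, list(threshold_rule("X7", "LE", 0.3)))),
    list(mk(10, list(threshold_rule("X7", "LE", 0.4),
                     threshold_rule("X1", "LE", 0.6)))))
  out <- pool_tmle(folds, rec)
  props <- sort(out$groups$proportion_folds, decreasing = TRUE)
  expect_equal(props, c(0.7, 0.2, 0.1))
  expect_equal(sum(out$groups$proportion_folds), 1)
})

test_that("cutpoint summaries average and range across folds", {
  regs <- lapply(c(1.9, 2.0, 2.0), function(s) {
    region(list(threshold_rule("X5", "GT", s)))
  })
  cp <- summarize_cutpoints(regs)
  expect_equal(cp$mean, mean(c(1.9, 2, 2)), tolerance = 1e-12)
  expect_equal(c(cp$min, cp$max), c(1.9, 2.0))
  single <- summarize_cutpoints(regs[1])
  expect_equal(c(single$mean, single$min, single$max), c(1.9, 1.9, 1.9))
  # ten fold-specific molybdenum thresholds pool to 103.8 (96.7, 112.4)
  moly <- c(102.9, 103.6, 104.5, 112.4, 107.3, 102.9, 104.9, 96.7, 100.2,
            102.5)
  cpm <- summarize_cutpoints(lapply(moly, function(s) {
    region(list(threshold_rule("molybdenum", "LE", s)))
  }))
  expect_equal(round(cpm$mean, 1), 103.8)
  expect_equal(c(cpm$min, cpm$max), c(96.7, 112.4))
  expect_match(cpm$label, "molybdenum <= 103.8 (96.7, 112.4)", fixed = TRUE)
})

test_that("end-to-end cross-estimation on a step signal is reproducible", {
  d <- step_dataset(n = 400, effect = 10, sd = 0.1, seed = 26)
  fit1 <- aretree(d, K = 2, tree_cfg = tree_config(objective = "max"),
                  ens_cfg = fast_ens(), seed = 5)
  fit2 <- aretree(d, K = 2, tree_cfg = tree_config(objective = "max"),
                  ens_cfg = fast_ens(), seed = 5)
  expect_equal(fit1$status, "ok")
  expect_identical(fit1$fold_table, fit2$fold_table)
  expect_equal(fit1$pooled$omnibus$psi, fit2$pooled$omnibus$psi)
  # discovery/training rows never appear in the fold's validation set
  for (f in fit1$fold_results) {
    expect_length(intersect(f$pred$idx, which(fit1$folds != f$fold_id)), 0)
  }
  # the step effect is strongly positive and covered by the pooled CI
  expect_gt(fit1$pooled$omnibus$psi, 5)
  expect_lt(abs(mean(fit1$pooled$omnibus$eif)), 1e-8)
})

test_that("all-fold spurious discovery under a strict null is rare", {
  hits <- vapply(1:25, function(s) {
    d <- noise_dataset(n = 300, seed = 5000 + s)
    fit <- aretree(d, K = 2, tree_cfg = tree_config(), ens_cfg = fast_ens(),
                   seed = 5000 + s)
    fit$status == "ok"
  }, logical(1))
  # alpha^K with a loose allowance for correlated candidate tests
  expect_lte(sum(hits), 3)
})
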