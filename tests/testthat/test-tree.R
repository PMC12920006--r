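test_that("enumerate_thresholds: constants, max exclusion, quantile oracle", {
  expect_equal(enumerate_thresholds(rep(2, 10), "unique"), numeric(0))
  expect_equal(enumerate_thresholds(c(1, 2, 3, 4, 5), "unique"), 1:4)
  set.seed(1)
  v <- runif(1000)
  cuts <- enumerate_thresholds(v, "quantile", q = 20)
  oracle <- unique(as.numeric(quantile(v, (1:20) / 21, names = FALSE)))
  oracle <- sort(oracle[oracle < max(v)])
  expect_equal(cuts, oracle)
  expect_lte(length(cuts), 20)
  # rounded strategy rounds before deduplicating
  expect_equal(enumerate_thresholds(c(0.11, 0.14, 0.52), "rounded",
                                    decimals = 1), c(0.1))
})

test_that("check_positivity: degenerate T, generated propensities, epsilon bounds", {
  set.seed(2)
  n <- 2000
  W <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "W1"))
  expect_false(check_positivity(rep(1, n), W, 0.05)$pass)
  # true propensities in about [0.2, 0.8]: should pass most seeds
  passes <- vapply(1:10, function(s) {
    set.seed(100 + s)
    T_ind <- rbinom(n, 1, plogis(0.5 * W[, 1]))
    check_positivity(T_ind, W, 0.05)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.9)
  # epsilon = 0.49: passes when the true propensity is 0.5 (n large enough
  # that the estimate sits inside the narrow band), fails at 0.3
  set.seed(3)
  nl <- 20000
  Wl <- matrix(rnorm(nl), nl, 1, dimnames = list(NULL, "W1"))
  T5 <- rbinom(nl, 1, 0.5)
  expect_true(check_positivity(T5, Wl, 0.49)$pass)
  T3 <- rbinom(nl, 1, 0.3)
  expect_false(check_positivity(T3, Wl, 0.49)$pass)
})

test_that("evaluate_split detects a strong step and enforces min_node", {
  d <- step_dataset(n = 500, effect = 10, sd = 0.1, seed = 4)
  sc <- scale_outcome(d$Y)
  cfg <- tree_config(objective = "max")
  cand <- evaluate_split(d$A[, "A1"], d$W, sc$Y_scaled, 2, mean(sc$Y_scaled),
                         cfg, "A1")
  expect_true(cand$valid)
  expect_equal(cand$improving, "left")
  diff_outcome <- unscale_estimate(cand$theta_left - cand$theta_right,
                                   sc$record, "difference")
  expect_equal(diff_outcome, 10, tolerance = 0.2)
  expect_lt(cand$p_left, 1e-6)
  # min_node filter
  cfgN <- tree_config(min_node = 200, objective = "max")
  candN <- evaluate_split(d$A[, "A1"], d$W, sc$Y_scaled, 1, mean(sc$Y_scaled),
                          cfgN, "A1")
  expect_false(candN$valid)
  expect_equal(candN$reason, "min_node")
})

test_that("under the null, split validity is controlled near alpha", {
  # fraction of null folds whose root has any valid split stays modest
  hits <- vapply(1:40, function(s) {
    d <- noise_dataset(n = 300, seed = 2000 + s)
    tree <- build_tree_greedy(d, tree_config(d_max = 1))
    !is.null(tree$root$split)
  }, logical(1))
  # many correlated candidate tests per node: allow a loose multiple of alpha
  expect_lte(mean(hits), 0.3)
})

test_that("greedy tree recovers a step region and respects d_max", {
  d <- step_dataset(n = 600, effect = 10, sd = 0.1, seed = 6)
  tree <- build_tree_greedy(d, tree_config(d_max = 2, objective = "max"))
  ex <- extract_region(tree)
  expect_true(ex$found)
  fr <- region_to_frame(ex$region)
  expect_true(any(fr$exposure == "A1" & fr$operator == "LE" &
                    fr$cutpoint == 2))
  depth <- function(node) {
    if (is.null(node$children)) return(node$depth)
    max(depth(node$children$left), depth(node$children$right))
  }
  expect_lte(depth(tree$root), 2)
  # per-split trace records decisions and reasons
  expect_true(all(c("exposure", "cutpoint", "valid", "reason") %in%
                    names(tree$trace)))
  expect_gt(nrow(tree$trace), 0)
})

test_that("objective = min on Y mirrors objective = max on -Y", {
  d <- step_dataset(n = 600, effect = 10, sd = 0.1, seed = 7)
  dm <- mixture_dataset(W = d$W, A = d$A, Y = -d$Y)
  ex_min <- extract_region(build_tree_greedy(d, tree_config(objective = "min")))
  ex_max <- extract_region(build_tree_greedy(dm, tree_config(objective = "max")))
  expect_region_equal(ex_min$region, ex_max$region)
})

test_that("greedy and exhaustive agree at depth 1", {
  for (s in 1:3) {
    d <- step_dataset(n = 400, effect = 8, sd = 0.2, seed = 30 + s)
    cfg <- tree_config(d_max = 1, objective = "max")
    g <- extract_region(build_tree_greedy(d, cfg))
    e <- search_exhaustive(d, cfg)
    expect_region_equal(g$region, e$region)
    expect_equal(g$estimate, e$estimate, tolerance = 1e-10)
  }
})

test_that("exhaustive search matches brute-force region enumeration", {
  # two exposures on small grids, strong additive signal, depth 2
  set.seed(9)
  n <- 1500
  A1 <- sample(1:4, n, replace = TRUE)
  A2 <- sample(1:4, n, replace = TRUE)
  Y <- 5 * (A1 >= 3) + 3 * (A2 <= 2) + rnorm(n, 0, 0.2)
  d <- mixture_dataset(W = data.frame(W1 = rnorm(n)),
                       A = data.frame(A1 = A1, A2 = A2), Y = Y)
  cfg <- tree_config(d_max = 2, objective = "max", threshold_strategy = "unique")
  e <- search_exhaustive(d, cfg)
  # brute force: all depth-<=2 rule conjunctions, scored by plug-in means
  best_mean <- -Inf; best <- NULL
  cuts <- list(A1 = 1:3, A2 = 1:3)
  cand_rules <- list(list())
  for (ex in c("A1", "A2")) for (s in cuts[[ex]]) for (op in c("LE", "GT")) {
    cand_rules <- c(cand_rules, list(list(threshold_rule(ex, op, s))))
  }
  singles <- cand_rules[-1]
  pairs <- list()
  for (i in seq_along(singles)) for (j in seq_along(singles)) {
    if (i < j) pairs <- c(pairs, list(c(singles[[i]], singles[[j]])))
  }
  for (rl in c(cand_rules, pairs)) {
    r <- tryCatch(region(rl), error = function(e) NULL)
    if (is.null(r)) next
    m <- region_membership(r, d$A) == 1
    if (sum(m) < 50) next
    if (mean(Y[m]) > best_mean) { best_mean <- mean(Y[m]); best <- r }
  }
  # the exhaustive leaf attains the brute-force optimum (plug-in scale)
  m_ex <- region_membership(e$region, d$A) == 1
  expect_equal(mean(Y[m_ex]), best_mean, tolerance = 0.05)
})

test_that("single-leaf trees yield the full space flagged as not found", {
  d <- noise_dataset(n = 200, seed = 77)
  cfg <- tree_config(alpha = 1e-6)
  ex <- extract_region(build_tree_greedy(d, cfg))
  expect_false(ex$found)
  expect_true(is_full_space(ex$region))
  e <- search_exhaustive(d, cfg)
  expect_true(is_full_space(e$region))
})

test_that("same-exposure cuts along a path normalize to the tightest rule", {
  r <- normalize_region(list(threshold_rule("A1", "LE", 4),
                             threshold_rule("A1", "LE", 2)))
  expect_equal(region_to_frame(r)$cutpoint, 2)
  r2 <- normalize_region(list(threshold_rule("A1", "LE", 2),
                              threshold_rule("A2", "GT", 3)))
  expect_equal(region_signature(r2), "A1&A2")
})

test_that("tree_config validates tuning parameters", {
  expect_error(tree_config(d_max = 0), "d_max")
  expect_error(tree_config(min_node = 1), "min_node")
  expect_error(tree_config(epsilon = 0.7), "epsilon")
  expect_error(tree_config(alpha = 0), "alpha")
})
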