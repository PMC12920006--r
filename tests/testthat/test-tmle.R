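test_that("outcome scaling: affine map, round trip, degenerate range", {
  sc <- scale_outcome(c(0, 5, 10))
  expect_equal(sc$Y_scaled, c(0, 0.5, 1))
  set.seed(1)
  psi <- rnorm(5)
  expect_equal(unscale_estimate(psi / sc$record$range, sc$record, "difference"),
               psi)
  const <- scale_outcome(rep(7, 4))
  expect_equal(const$Y_scaled, rep(0.5, 4))
  expect_equal(unscale_estimate(0.123, const$record, "mean"), 7)
  expect_equal(unscale_estimate(0.2, const$record, "se"), 0)
})

test_that("saturated stratum fits give zero fluctuation", {
  set.seed(5)
  n <- 200
  Wb <- rbinom(n, 1, 0.5)
  T_ind <- rbinom(n, 1, ifelse(Wb == 1, 0.7, 0.3))
  Y <- plogis(rnorm(n))  # already in (0,1)
  # saturated Q: empirical stratum-by-arm means; g: stratum frequencies
  Q <- Y
  for (w in 0:1) for (t in 0:1) {
    m <- Wb == w & T_ind == t
    Q[m] <- mean(Y[m])
  }
  Q1 <- ifelse(Wb == 1, mean(Y[Wb == 1 & T_ind == 1]),
               mean(Y[Wb == 0 & T_ind == 1]))
  g <- ifelse(Wb == 1, mean(T_ind[Wb == 1]), mean(T_ind[Wb == 0]))
  fit <- tmle_treated_mean(list(Q1 = Q1, QT = Q, g = g), T_ind, Y)
  expect_lt(abs(fit$eps_fluct), 1e-6)
  expect_equal(fit$QstarT, Q, tolerance = 1e-6)
})

test_that("fluctuation coefficient matches a bisection oracle on a micro input", {
  # fixed 6-row input with hand-chosen nuisances
  Q <- c(0.2, 0.8, 0.5, 0.4, 0.6, 0.3)
  Q1 <- c(0.3, 0.7, 0.55, 0.45, 0.65, 0.35)
  g <- c(0.3, 0.6, 0.5, 0.4, 0.7, 0.2)
  T_ind <- c(1, 0, 1, 1, 0, 1)
  Y <- c(0.9, 0.1, 0.7, 0.2, 0.5, 0.8)
  H <- T_ind / g
  score <- function(eps) mean(H * (Y - plogis(qlogis(Q) + eps * H)))
  # independent oracle: plain bisection
  lo <- -10; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) lo <- mid else hi <- mid
  }
  eps_oracle <- (lo + hi) / 2
  fit <- tmle_treated_mean(list(Q1 = Q1, QT = Q, g = g), T_ind, Y)
  expect_equal(fit$eps_fluct, eps_oracle, tolerance = 1e-5)
  # score equation solved at the returned eps
  expect_lt(abs(score(fit$eps_fluct)), 1e-6)
})

test_that("tmle_treated_mean requires treated observations", {
  expect_error(
    tmle_treated_mean(list(Q1 = c(0.5, 0.5), QT = c(0.5, 0.5),
                           g = c(0.5, 0.5)), c(0, 0), c(0.4, 0.6)),
    "no_treated")
})

test_that("estimate_are: identity, hand arithmetic, EIF centering", {
  rec <- list(min = 0, range = 1)
  Y <- c(0.2, 0.5, 0.7, 0.4)
  fit0 <- estimate_are(Y, Y, c(1, 0, 1, 0), rep(0.5, 4), Y, rec)
  expect_equal(fit0$psi_hat, 0)
  # psi is the average of Q*(1, W) - Y: ((2-1)+(4-1)+(6-1)+(8-1))/4 = 4
  fit <- estimate_are(c(2, 4, 6, 8), c(2, 4, 6, 8), c(1, 1, 0, 0),
                      rep(0.5, 4), c(1, 1, 1, 1), rec)
  expect_equal(fit$psi_hat, 4)
  set.seed(8)
  fit2 <- estimate_are(runif(50), runif(50), rbinom(50, 1, 0.5),
                       runif(50, 0.2, 0.8), runif(50), rec)
  expect_lt(abs(mean(fit2$eif)), 1e-8)
  expect_true(fit2$ci_low <= fit2$psi_hat && fit2$psi_hat <= fit2$ci_high)
  expect_error(estimate_are(1, 1, 1, 0.5, 1, rec), "aretree_error_n")
})

test_that("tmle_node_mean: exchangeable null, degenerate outcome, empty arm", {
  set.seed(9)
  n <- 2000
  T_ind <- rbinom(n, 1, 0.5)
  Y <- runif(n)
  fits <- function(arm) list(Qarm = rep(mean(Y), n), QT = rep(mean(Y), n),
                             g = rep(0.5, n))
  tr <- tmle_node_mean(fits(1), T_ind, Y, "treated")
  ct <- tmle_node_mean(fits(0), T_ind, Y, "control")
  expect_lt(abs(tr$theta - mean(Y)), 3 * tr$se)
  expect_lt(abs(ct$theta - mean(Y)), 3 * ct$se)
  expect_lt(abs(mean(tr$eif)), 1e-8)
  # deterministic outcome by arm: the update drives the treated mean to 1
  Yd <- as.numeric(T_ind)
  fit <- tmle_node_mean(list(Qarm = rep(0.9, n),
                             QT = ifelse(T_ind == 1, 0.9, 0.1),
                             g = rep(0.5, n)), T_ind, Yd, "treated")
  expect_equal(fit$theta, 1, tolerance = 1e-6)
  expect_error(tmle_node_mean(fits(1), rep(1, n), Y, "control"), "empty_arm")
})

test_that("TMLE is doubly robust: correct g rescues a constant (wrong) Q", {
  set.seed(12)
  n <- 5000
  W1 <- rnorm(n)
  g_true <- plogis(0.8 * W1)
  T_ind <- rbinom(n, 1, g_true)
  Y <- 1 + 2 * T_ind + W1 + rnorm(n, 0, 0.5)
  # truth: E[Y | T = 1 set for everyone] - E[Y]
  psi0 <- (1 + 2 + 0) - mean(Y)
  sc <- scale_outcome(Y)
  Qc <- rep(mean(sc$Y_scaled), n)      # deliberately misspecified, constant
  g <- pmin(pmax(g_true, 0.025), 0.975)
  upd <- tmle_treated_mean(list(Q1 = Qc, QT = Qc, g = g), T_ind, sc$Y_scaled)
  fit <- estimate_are(upd$Qstar1, upd$QstarT, T_ind, g, sc$Y_scaled,
                      sc$record)
  expect_lt(abs(fit$psi_hat - psi0), 3 * fit$se + 0.05)
})

test_that("affine transforms of Y rescale psi and se by the slope", {
  set.seed(10)
  n <- 300
  W <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "W1"))
  T_ind <- rbinom(n, 1, 0.5)
  Y <- 1 + T_ind + 0.3 * W[, 1] + rnorm(n, 0, 0.3)
  run <- function(Yv) {
    sc <- scale_outcome(Yv)
    Qf <- fit_outcome_ensemble(T_ind, W, sc$Y_scaled, fast_ens(), seed = 2)
    g <- rep(mean(T_ind), n)
    Q1 <- Qf$predict(1, W); QT <- ifelse(T_ind == 1, Q1, Qf$predict(0, W))
    upd <- tmle_treated_mean(list(Q1 = Q1, QT = QT, g = g), T_ind, sc$Y_scaled)
    estimate_are(upd$Qstar1, upd$QstarT, T_ind, g, sc$Y_scaled, sc$record)
  }
  f1 <- run(Y)
  f2 <- run(5 * Y - 3)
  expect_equal(f2$psi_hat, 5 * f1$psi_hat, tolerance = 1e-6)
  expect_equal(f2$se, 5 * f1$se, tolerance = 1e-6)
})
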