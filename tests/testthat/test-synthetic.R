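test_that("generation is deterministic and matches the stated laws", {
  spec <- null_dgp_spec()
  d1 <- generate_mixture(spec, 2000, seed = 1)
  d2 <- generate_mixture(spec, 2000, seed = 1)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$A, d2$A)
  big <- generate_mixture(spec, 100000, seed = 2)
  # exposure noise correlation 0.5 after removing the linear W signal
  r1 <- resid(lm(big$A[, 1] ~ big$W))
  r2 <- resid(lm(big$A[, 2] ~ big$W))
  expect_equal(cor(r1, r2), 0.5, tolerance = 0.02)
  # outcome decoupled from the exposures
  expect_lt(abs(cor(big$Y, big$A[, 1])), 0.02)
  expect_lt(abs(cor(big$Y, big$A[, 2])), 0.02)
  expect_equal(mean(big$W[, "W1"]), 50, tolerance = 0.2)
})

test_that("discrete grid: every cell occupied and positivity floor holds", {
  spec <- discrete_dgp_spec()
  d <- generate_mixture(spec, 10000, seed = 3)
  expect_equal(length(unique(paste(d$A[, 1], d$A[, 2]))), 25)
  # the positivity floor is enforced on the constructor's reference sample;
  # an independent draw stays within an order of magnitude of it
  W <- aretree:::draw_covariates_standard(2000)
  p <- aretree:::cell_probs(spec$beta, W)
  expect_gte(min(p), 1e-5)
  expect_equal(rowSums(p), rep(1, 2000), tolerance = 1e-12)
})

test_that("continuous DGP mean outcome matches the analytic normal oracle", {
  spec <- continuous_dgp_spec()
  big <- generate_mixture(spec, 100000, seed = 4)
  # A1 = 0.1 z1 + 0.1 z2 + 0.1 z3 + e1: var 1.03; indicator on the rounded
  # value A1r > 0.5 is A1 >= 0.55; A2 (var 1.02) rounded < -0.2 is A2 < -0.25
  p1 <- 1 - pnorm(0.55 / sqrt(1.03))
  p2 <- pnorm(-0.25 / sqrt(1.02))
  expect_equal(mean(big$Y), 15.4 + 3 * p1 + 2 * p2, tolerance = 0.05)
})

test_that("true regional mean: full space, constant surface, analytic region", {
  for (mk in list(continuous_dgp_spec, null_dgp_spec, discrete_dgp_spec)) {
    spec <- mk()
    ey <- aretree:::expected_outcome(spec, n_mc = 50000, seed = 5)
    full <- true_regional_mean(spec, region(), n_mc = 10000, seed = 6,
                               n_inner = 50)
    expect_lt(abs(full$value - ey$value),
              3 * sqrt(full$mc_se^2 + ey$mc_se^2) + 0.02)
  }
  # constant-surface hook: the selection weighting cancels exactly
  spec_c <- discrete_dgp_spec()
  spec_c$mu0 <- function(a1, a2, W) rep(4.2, nrow(W))
  r <- region(list(threshold_rule("A1", "GT", 3)))
  expect_equal(true_regional_mean(spec_c, r, n_mc = 2000, seed = 7)$value, 4.2)
  # analytic value inside the continuous oracle region: both effects active
  spec <- continuous_dgp_spec()
  reg <- true_regional_mean(spec, continuous_oracle_region(), n_mc = 4000,
                            seed = 8, n_inner = 100)
  expect_equal(reg$value, 20.4, tolerance = 3 * reg$mc_se + 0.02)
})

test_that("true ARE: full space zero, analytic continuous oracle, brute force", {
  spec <- continuous_dgp_spec()
  full <- true_are(spec, region(), n_mc = 50000, seed = 9, n_inner = 50)
  expect_lt(abs(full$are), 3 * full$mc_se_are + 0.02)
  orc <- true_are(spec, continuous_oracle_region(), n_mc = 50000, seed = 10,
                  n_inner = 100)
  p1 <- 1 - pnorm(0.55 / sqrt(1.03))
  p2 <- pnorm(-0.25 / sqrt(1.02))
  expect_equal(orc$are, 5 - 3 * p1 - 2 * p2, tolerance = 3 * orc$mc_se_are + 0.02)
  # discrete corner cell vs an independent brute-force integrator
  dspec <- discrete_dgp_spec()
  corner <- region(list(threshold_rule("A1", "GT", 4),
                        threshold_rule("A2", "GT", 4)))
  got <- true_are(dspec, corner, n_mc = 30000, seed = 11)
  set.seed(991)
  W <- aretree:::draw_covariates_standard(30000)
  p <- aretree:::cell_probs(dspec$beta, W)
  mu <- sapply(1:25, function(k) {
    dspec$mu0(dspec$cells$a1[k], dspec$cells$a2[k], W)
  })
  inside <- dspec$cells$a1 == 5 & dspec$cells$a2 == 5
  q_bf <- mean(mu[, inside] )  # single cell: weights cancel
  ey_bf <- mean(rowSums(p * mu))
  expect_equal(got$are, q_bf - ey_bf, tolerance = 0.1)
})

test_that("oracle region search returns the high corner and matches brute force", {
  spec <- discrete_dgp_spec()
  orc <- oracle_region_discrete(spec, n_mc = 10000, seed = 12)
  expect_region_equal(orc$region,
                      region(list(threshold_rule("A1", "GT", 4),
                                  threshold_rule("A2", "GT", 4))))
  # independent double-loop brute force over all 225 rectangles
  set.seed(12)
  W <- aretree:::draw_covariates_standard(10000)
  p <- aretree:::cell_probs(spec$beta, W)
  mu <- sapply(1:25, function(k) {
    spec$mu0(spec$cells$a1[k], spec$cells$a2[k], W)
  })
  best_val <- -Inf; best_rect <- NULL
  for (l1 in 1:5) for (u1 in l1:5) for (l2 in 1:5) for (u2 in l2:5) {
    inside <- spec$cells$a1 >= l1 & spec$cells$a1 <= u1 &
      spec$cells$a2 >= l2 & spec$cells$a2 <= u2
    pi_w <- rowSums(p[, inside, drop = FALSE])
    if (mean(pi_w) < 0.001) next
    val <- mean(rowSums(p[, inside, drop = FALSE] *
                          mu[, inside, drop = FALSE]) / pi_w)
    if (val > best_val) { best_val <- val; best_rect <- c(l1, u1, l2, u2) }
  }
  expect_equal(best_rect, c(5, 5, 5, 5))
  expect_equal(orc$regional_mean, best_val, tolerance = 1e-6)
  # monotone-decreasing surface hook sends the maximizer to the low corner
  spec_dec <- spec
  spec_dec$mu0 <- function(a1, a2, W) -(a1 + a2) + 0 * W[, 1]
  orc_dec <- oracle_region_discrete(spec_dec, n_mc = 4000, seed = 13)
  expect_region_equal(orc_dec$region,
                      region(list(threshold_rule("A1", "LE", 1),
                                  threshold_rule("A2", "LE", 1))))
})

test_that("Monte Carlo standard errors shrink like 1/sqrt(2) when doubled", {
  spec <- continuous_dgp_spec()
  r <- continuous_oracle_region()
  se1 <- true_regional_mean(spec, r, n_mc = 2000, seed = 14, n_inner = 50)$mc_se
  se2 <- true_regional_mean(spec, r, n_mc = 4000, seed = 15, n_inner = 50)$mc_se
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.25)
})

test_that("near-zero-probability regions are rejected", {
  spec <- continuous_dgp_spec()
  far <- region(list(threshold_rule("A1", "GT", 25)))
  expect_error(true_regional_mean(spec, far, n_mc = 500, seed = 16,
                                  n_inner = 20), "zero_region")
})
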