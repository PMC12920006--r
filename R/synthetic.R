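# Synthetic data-generating processes used throughout the test-bench: a
# discrete confounded 5x5 exposure grid with a quadratic/interaction outcome,
# correlated continuous exposures with a threshold-effect outcome, and a
# strict null in which the outcome is independent of the exposures. Each spec
# carries its own ground-truth machinery (Monte Carlo oracle integrators).

COV_SDS <- c(W1 = 3, W2 = 1, W3 = 0.5)
COV_MEANS <- c(W1 = 37, W2 = 20, W3 = 0.5)

#' Discrete 5x5 confounded exposure grid DGP
#'
#' Two exposures quantized to levels 1..5 are drawn from a multinomial
#' logistic model over the 25 grid cells whose coefficients act on
#' standardized covariates; the coefficients are drawn once from
#' N(0, sigma_coef) under a fixed internal seed and re-drawn until every
#' cell probability exceeds `min_cell_prob` over a reference covariate
#' sample, so full-population positivity holds by construction. The
#' outcome has quadratic main effects and a strong exposure interaction,
#' confounded by W1 and W3:
#' `Y = 0.2 A1^2 + 0.5 A1 A2 + 0.5 A2^2 + 0.2 W1 + 0.4 W3 + N(0, 0.1^2)`,
#' with `W1 ~ N(37, 3)`, `W2 ~ N(20, 1)`, `W3 ~ Bernoulli(0.5)`.
#'
#' @param sigma_coef Standard deviation of the multinomial-logit
#'   coefficients (default 0.5).
#' @param min_cell_prob Positivity floor enforced on every cell
#'   probability in the reference sample (default 1e-4).
#' @param noise_sd Outcome noise standard deviation (default 0.1).
#' @return Object of class `dgp_spec` (subtype `"discrete"`).
#' @export
discrete_dgp_spec <- function(sigma_coef = 0.5, min_cell_prob = 1e-4,
                              noise_sd = 0.1) {
  cells <- expand.grid(a1 = 1:5, a2 = 1:5)
  # coefficients drawn once under a fixed internal seed; re-draw until the
  # reference-sample positivity floor holds
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(411L)
  Wref <- draw_covariates_standard(5000L)
  repeat {
    beta <- matrix(stats::rnorm(25L * 4L, 0, sigma_coef), nrow = 25L)
    pr <- cell_probs(beta, Wref)
    if (min(pr) >= min_cell_prob) break
  }
  spec <- list(
    type = "discrete", cells = cells, beta = beta, noise_sd = noise_sd,
    mu0 = function(a1, a2, W) {
      0.2 * a1^2 + 0.5 * a1 * a2 + 0.5 * a2^2 +
        0.2 * W[, "W1"] + 0.4 * W[, "W3"]
    })
  class(spec) <- c("dgp_spec")
  spec
}

draw_covariates_standard <- function(n) {
  cbind(W1 = stats::rnorm(n, 37, 3), W2 = stats::rnorm(n, 20, 1),
        W3 = stats::rbinom(n, 1, 0.5))
}

standardize_covariates <- function(W) {
  cbind((W[, "W1"] - COV_MEANS["W1"]) / COV_SDS["W1"],
        (W[, "W2"] - COV_MEANS["W2"]) / COV_SDS["W2"],
        (W[, "W3"] - COV_MEANS["W3"]) / COV_SDS["W3"])
}

# n x 25 cell probabilities under the multinomial logit: softmax over
# beta0_c + beta_c . z(w)
cell_probs <- function(beta, W) {
  Z <- cbind(1, standardize_covariates(W))
  eta <- Z %*% t(beta)                 # n x 25
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Correlated continuous exposures with a threshold-effect outcome
#'
#' Two continuous exposures confounded by the covariates: conditional
#' means are small linear functions of the standardized covariates
#' (coefficients 0.1, 0.1, 0.1 for A1 and 0.1, -0.1, 0 for A2; zero
#' intercepts) with unit-variance bivariate Gaussian noise correlated at
#' 0.5, so marginals are approximately standard normal and the generating
#' thresholds stay interior. Exposures are rounded to one decimal (on this
#' grid the outcome thresholds are exactly representable) and the outcome
#' is `Y = 3 * 1{A1 > 0.5} + 2 * 1{A2 < -0.2} + 0.2 W1 + 0.4 W2 +
#' N(0, 0.1^2)`. The oracle region is `{A1 > 0.5, A2 <= -0.2}`.
#'
#' @param noise_sd Outcome noise standard deviation (default 0.1).
#' @return Object of class `dgp_spec` (subtype `"continuous"`).
#' @export
continuous_dgp_spec <- function(noise_sd = 0.1) {
  spec <- list(
    type = "continuous", noise_sd = noise_sd, round_decimals = 1L,
    alpha = rbind(A1 = c(0.1, 0.1, 0.1), A2 = c(0.1, -0.1, 0)),
    Sigma = matrix(c(1, 0.5, 0.5, 1), 2L),
    draw_W = draw_covariates_standard,
    exposure_mean = function(spec, W) standardize_covariates(W) %*% t(spec$alpha),
    mu0 = function(a1, a2, W) {
      3 * (a1 > 0.5) + 2 * (a2 < -0.2) + 0.2 * W[, "W1"] + 0.4 * W[, "W2"]
    })
  class(spec) <- "dgp_spec"
  spec
}

#' Oracle region of the continuous threshold DGP
#'
#' The outcome gains 3 units when `A1 > 0.5` and 2 units when
#' `A2 < -0.2`. Exposures live on a 0.1 grid, so the strict inequality
#' `A2 < -0.2` is exactly the grid rule `A2 <= -0.3`.
#'
#' @return A [region()]: `{A1 > 0.5, A2 <= -0.3}`.
#' @export
continuous_oracle_region <- function() {
  region(list(threshold_rule("A1", "GT", 0.5),
              threshold_rule("A2", "LE", -0.3)))
}

#' Strict null DGP: outcome independent of the exposures
#'
#' Covariates `W1 ~ N(50, 10)`, `W2 ~ N(25, 3)`, `W3 ~ Bernoulli(0.5)`;
#' correlated continuous exposures with conditional means
#' `mu1 = 0.3 W1 + 0.1 W2 + 0.2 W3` and `mu2 = -0.1 W1 + 0.2 W2`,
#' correlation 0.5, rounded to one decimal. The outcome
#' `Y ~ N(0.2 W3, 5^2)` depends mildly on W3 but not at all on the
#' exposures, so any discovered region is spurious.
#'
#' @return Object of class `dgp_spec` (subtype `"null"`).
#' @export
null_dgp_spec <- function() {
  spec <- list(
    type = "null", noise_sd = 5, round_decimals = 1L,
    Sigma = matrix(c(1, 0.5, 0.5, 1), 2L),
    draw_W = function(n) {
      cbind(W1 = stats::rnorm(n, 50, 10), W2 = stats::rnorm(n, 25, 3),
            W3 = stats::rbinom(n, 1, 0.5))
    },
    exposure_mean = function(spec, W) {
      cbind(0.3 * W[, "W1"] + 0.1 * W[, "W2"] + 0.2 * W[, "W3"],
            -0.1 * W[, "W1"] + 0.2 * W[, "W2"])
    },
    mu0 = function(a1, a2, W) 0.2 * W[, "W3"])
  class(spec) <- "dgp_spec"
  spec
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat("dgp_spec:", x$type, "\n")
  invisible(x)
}

#' Generate a dataset from a DGP specification
#'
#' @param spec A `dgp_spec` from [discrete_dgp_spec()],
#'   [continuous_dgp_spec()] or [null_dgp_spec()].
#' @param n Number of i.i.d. observations (>= 1).
#' @param seed Integer seed; draws are deterministic given `(spec, n,
#'   seed)`.
#' @return A [mixture_dataset()] with covariates `W1, W2, W3`, exposures
#'   `A1, A2`, and outcome `Y`.
#' @export
generate_mixture <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "dgp_spec"), n >= 1)
  set.seed(as.integer(seed))
  if (spec$type == "discrete") {
    W <- draw_covariates_standard(n)
    p <- cell_probs(spec$beta, W)
    # Gumbel-max trick: exact categorical sampling, vectorized over rows
    gumbel <- -log(-log(matrix(stats::runif(n * 25L), n, 25L)))
    cell <- max.col(log(p) + gumbel)
    A <- cbind(A1 = spec$cells$a1[cell], A2 = spec$cells$a2[cell])
  } else {
    W <- spec$draw_W(n)
    mu <- spec$exposure_mean(spec, W)
    L <- chol(spec$Sigma)
    eps <- matrix(stats::rnorm(2L * n), n, 2L) %*% L
    A <- round(mu + eps, spec$round_decimals)
    colnames(A) <- c("A1", "A2")
  }
  Y <- spec$mu0(A[, "A1"], A[, "A2"], W) + stats::rnorm(n, 0, spec$noise_sd)
  mixture_dataset(W = W, A = A, Y = Y)
}

# membership of the 25 grid cells in a region (discrete specs)
cell_membership <- function(spec, region) {
  Acells <- cbind(A1 = spec$cells$a1, A2 = spec$cells$a2)
  region_membership(region, Acells) == 1L
}

#' True regional mean E[Q_A(1, W)] under a DGP
#'
#' The population mean outcome if everyone were forced to self-select
#' within the region: for each covariate draw w, the within-region
#' selection-weighted average of the true conditional mean,
#' `Q_A(1, w) = sum_{a in A} mu0(a, w) p(a|w) / sum_{a in A} p(a|w)`,
#' integrated over the covariate law by Monte Carlo. Discrete specs
#' enumerate the grid cells exactly (Monte Carlo only over W); continuous
#' specs use nested Monte Carlo with rejection of exposure draws outside
#' the region.
#'
#' @param spec A `dgp_spec`.
#' @param region A [region()].
#' @param n_mc Monte Carlo size over the covariate law (default 20000).
#' @param seed Integer seed.
#' @param n_inner Inner exposure draws per covariate draw for continuous
#'   specs (default 200).
#' @return List with `value`, `mc_se`, and `region_prob` (the marginal
#'   probability of the region).
#' @export
true_regional_mean <- function(spec, region, n_mc = 20000L, seed = 1L,
                               n_inner = 200L) {
  stopifnot(inherits(spec, "dgp_spec"), inherits(region, "region"))
  set.seed(as.integer(seed))
  if (spec$type == "discrete") {
    W <- draw_covariates_standard(n_mc)
    inside <- cell_membership(spec, region)
    if (!any(inside)) {
      stop("aretree_error_zero_region: region contains no grid cells")
    }
    p <- cell_probs(spec$beta, W)
    mu_cells <- sapply(which(inside), function(k) {
      spec$mu0(spec$cells$a1[k], spec$cells$a2[k], W)
    })
    p_in <- p[, inside, drop = FALSE]
    pi_w <- rowSums(p_in)
    if (mean(pi_w) < 1e-6) {
      stop("aretree_error_zero_region: region has near-zero probability")
    }
    Qw <- rowSums(p_in * mu_cells) / pi_w
    return(list(value = mean(Qw), mc_se = stats::sd(Qw) / sqrt(n_mc),
                region_prob = mean(pi_w)))
  }
  # continuous / null: nested MC with rejection inside each covariate draw
  W <- spec$draw_W(n_mc)
  mu <- spec$exposure_mean(spec, W)
  L <- chol(spec$Sigma)
  num <- numeric(n_mc); den <- numeric(n_mc)
  for (r in seq_len(n_inner)) {
    eps <- matrix(stats::rnorm(2L * n_mc), n_mc, 2L) %*% L
    A <- round(mu + eps, spec$round_decimals)
    colnames(A) <- c("A1", "A2")
    inA <- region_membership(region, A) == 1L
    m <- spec$mu0(A[, "A1"], A[, "A2"], W)
    num <- num + ifelse(inA, m, 0)
    den <- den + inA
  }
  keep <- den > 0
  if (mean(den / n_inner) < 1e-4 || mean(keep) < 0.5) {
    stop("aretree_error_zero_region: region has near-zero probability")
  }
  Qw <- num[keep] / den[keep]
  list(value = mean(Qw), mc_se = stats::sd(Qw) / sqrt(sum(keep)),
       region_prob = mean(den / n_inner))
}

#' True ARE of a region under a DGP
#'
#' `ARE(A) = E[Q_A(1, W)] - E[Y]`, both terms by Monte Carlo under the
#' generating distribution (the outcome noise is mean zero, so E[Y] is the
#' mean of the true conditional-mean surface over joint draws).
#'
#' @inheritParams true_regional_mean
#' @param n_mc Monte Carlo size (default 200000 for E[Y]; the regional
#'   mean uses the same budget over W).
#' @return List of class `ground_truth` with `are`, `regional_mean`,
#'   `ey`, and Monte Carlo standard errors `mc_se_are`, `mc_se_regional`,
#'   `mc_se_ey`.
#' @export
true_are <- function(spec, region, n_mc = 200000L, seed = 1L,
                     n_inner = 200L) {
  reg <- true_regional_mean(spec, region,
                            n_mc = if (spec$type == "discrete") n_mc
                                   else min(n_mc, 20000L),
                            seed = seed, n_inner = n_inner)
  ey <- expected_outcome(spec, n_mc = n_mc, seed = seed + 1L)
  structure(list(are = reg$value - ey$value, regional_mean = reg$value,
                 ey = ey$value,
                 mc_se_regional = reg$mc_se, mc_se_ey = ey$mc_se,
                 mc_se_are = sqrt(reg$mc_se^2 + ey$mc_se^2),
                 region_prob = reg$region_prob),
            class = "ground_truth")
}

# E[Y] by Monte Carlo over the joint (W, A) law; noise is mean zero
expected_outcome <- function(spec, n_mc = 200000L, seed = 1L) {
  set.seed(as.integer(seed))
  if (spec$type == "discrete") {
    W <- draw_covariates_standard(n_mc)
    p <- cell_probs(spec$beta, W)
    mu_cells <- sapply(seq_len(25L), function(k) {
      spec$mu0(spec$cells$a1[k], spec$cells$a2[k], W)
    })
    vals <- rowSums(p * mu_cells)
    return(list(value = mean(vals), mc_se = stats::sd(vals) / sqrt(n_mc)))
  }
  W <- spec$draw_W(n_mc)
  mu <- spec$exposure_mean(spec, W)
  L <- chol(spec$Sigma)
  eps <- matrix(stats::rnorm(2L * n_mc), n_mc, 2L) %*% L
  A <- round(mu + eps, spec$round_decimals)
  colnames(A) <- c("A1", "A2")
  vals <- spec$mu0(A[, "A1"], A[, "A2"], W)
  list(value = mean(vals), mc_se = stats::sd(vals) / sqrt(n_mc))
}

#' Oracle region search for the discrete DGP
#'
#' Enumerates every contiguous level rectangle `{A1 in [l1, u1]} x
#' {A2 in [l2, u2]}` (1 <= l <= u <= 5; 225 candidates), computes each
#' candidate's true ARE with the exact-enumeration integrator, discards
#' rectangles with marginal probability below `min_region_prob`, and
#' returns the maximizing (or minimizing) one.
#'
#' @param spec A discrete `dgp_spec`.
#' @param n_mc Monte Carlo size over the covariate law (default 20000).
#' @param seed Integer seed (shared across candidates so the comparison is
#'   common-random-number exact).
#' @param min_region_prob Minimum marginal region probability (default
#'   0.001).
#' @param objective `"max"` or `"min"`.
#' @return List with `region`, `are`, `regional_mean`, `region_prob`, and
#'   the full candidate `table`.
#' @export
oracle_region_discrete <- function(spec, n_mc = 20000L, seed = 1L,
                                   min_region_prob = 0.001,
                                   objective = c("max", "min")) {
  stopifnot(spec$type == "discrete")
  objective <- match.arg(objective)
  set.seed(as.integer(seed))
  W <- draw_covariates_standard(n_mc)
  p <- cell_probs(spec$beta, W)
  mu_cells <- sapply(seq_len(25L), function(k) {
    spec$mu0(spec$cells$a1[k], spec$cells$a2[k], W)
  })
  ey <- mean(rowSums(p * mu_cells))
  rows <- list()
  for (l1 in 1:5) for (u1 in l1:5) for (l2 in 1:5) for (u2 in l2:5) {
    inside <- spec$cells$a1 >= l1 & spec$cells$a1 <= u1 &
      spec$cells$a2 >= l2 & spec$cells$a2 <= u2
    p_in <- p[, inside, drop = FALSE]
    pi_w <- rowSums(p_in)
    Qw <- rowSums(p_in * mu_cells[, inside, drop = FALSE]) / pi_w
    rows[[length(rows) + 1L]] <- data.frame(
      l1 = l1, u1 = u1, l2 = l2, u2 = u2,
      regional_mean = mean(Qw), region_prob = mean(pi_w),
      are = mean(Qw) - ey)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$region_prob >= min_region_prob
  cand <- tab[ok, ]
  best <- if (objective == "max") cand[which.max(cand$regional_mean), ]
          else cand[which.min(cand$regional_mean), ]
  rules <- list()
  if (best$l1 > 1) rules <- c(rules, list(threshold_rule("A1", "GT", best$l1 - 1)))
  if (best$u1 < 5) rules <- c(rules, list(threshold_rule("A1", "LE", best$u1)))
  if (best$l2 > 1) rules <- c(rules, list(threshold_rule("A2", "GT", best$l2 - 1)))
  if (best$u2 < 5) rules <- c(rules, list(threshold_rule("A2", "LE", best$u2)))
  list(region = region(rules), are = best$are,
       regional_mean = best$regional_mean, region_prob = best$region_prob,
       ey = ey, table = tab)
}
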