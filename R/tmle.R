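#' Scale an outcome to the unit interval
#'
#' Targeted updates use a logistic fluctuation, which requires the outcome
#' in [0, 1]. This applies the affine min-max map and records the transform
#' so estimates and standard errors can be mapped back. A constant outcome
#' has zero range; by convention it is mapped to 0.5 everywhere and the
#' back-transform returns estimates exactly with zero standard error.
#'
#' @param Y Numeric outcome vector.
#' @return List with `Y_scaled` and `record` (a list with `min` and
#'   `range`).
#' @export
scale_outcome <- function(Y) {
  Y <- as.numeric(Y)
  if (anyNA(Y) || !all(is.finite(Y))) {
    stop("aretree_error_missing: Y must be finite")
  }
  rng <- max(Y) - min(Y)
  if (rng == 0) {
    return(list(Y_scaled = rep(0.5, length(Y)),
                record = list(min = min(Y), range = 0)))
  }
  list(Y_scaled = (Y - min(Y)) / rng,
       record = list(min = min(Y), range = rng))
}

#' Map a scaled estimate back to outcome units
#'
#' @param value Numeric value(s) on the scaled [0, 1] scale.
#' @param record Transform record from [scale_outcome()].
#' @param type `"mean"` for location estimates (slope and intercept),
#'   `"difference"` or `"se"` for contrasts and standard errors (slope
#'   only).
#' @return Numeric value(s) in original outcome units.
#' @export
unscale_estimate <- function(value, record, type = c("mean", "difference", "se")) {
  type <- match.arg(type)
  if (record$range == 0) {
    # degenerate range: scaled scale is a point mass at 0.5
    if (type == "mean") return(rep(record$min, length(value)))
    return(value * 0)
  }
  if (type == "mean") value * record$range + record$min
  else value * record$range
}

# Clip scaled outcome-regression values away from {0,1} before logit.
QBOUND <- 1e-4

clip01 <- function(p, lo = QBOUND) pmin(pmax(p, lo), 1 - lo)

# Solve the one-dimensional logistic fluctuation: find eps in [-10, 10] with
# mean(H * (Y - expit(logit(Q) + eps * H))) = 0. The score is monotone
# decreasing in eps, so bisection via uniroot is robust; if the score does
# not change sign on the interval the boundary with the smaller |score| is
# returned (score magnitude reported for diagnostics).
solve_fluctuation <- function(offset, H, Y, bound = 10, tol = 1e-10) {
  score <- function(eps) mean(H * (Y - stats::plogis(offset + eps * H)))
  s_lo <- score(-bound); s_hi <- score(bound)
  if (is.na(s_lo) || is.na(s_hi)) {
    stop("aretree_error_fluctuation: non-finite score in fluctuation solve")
  }
  if (s_lo < 0 && s_hi < 0) return(list(eps = -bound, score = s_lo))
  if (s_lo > 0 && s_hi > 0) return(list(eps = bound, score = s_hi))
  root <- stats::uniroot(score, c(-bound, bound), tol = tol)
  list(eps = root$root, score = root$f.root)
}

#' Targeted update of the outcome regression for the treated mean
#'
#' Performs the TMLE fluctuation step for the parameter E[Q(1, W)] using
#' the clever covariate H(T, W) = T / g(W): the initial fit is updated on
#' the logit scale, `Q* = expit(logit(Q) + eps * H)`, with `eps` solving
#' the efficient-score equation `(1/n) sum H_i (Y_i - Q*(T_i, W_i)) = 0`.
#'
#' @param fits List with numeric vectors `Q1` (predictions at T = 1), `QT`
#'   (predictions at the observed T), and `g` (propensity P(T=1|W), already
#'   bounded away from 0 and 1), all on the scaled outcome scale.
#' @param T_ind Binary vector of region membership.
#' @param Y_scaled Outcome scaled to [0, 1].
#' @return List with `Qstar1`, `QstarT`, `eps_fluct`, `score` (residual
#'   score value).
#' @export
tmle_treated_mean <- function(fits, T_ind, Y_scaled) {
  T_ind <- as.numeric(T_ind)
  if (sum(T_ind) == 0) {
    stop("aretree_error_no_treated: no observations with T = 1")
  }
  H <- T_ind / fits$g
  off <- stats::qlogis(clip01(fits$QT))
  sol <- solve_fluctuation(off, H, Y_scaled)
  if (abs(sol$score) > 1e-6) {
    stop(sprintf(
      "aretree_error_fluctuation: score equation not solved (|score| = %.3g, eps = %.3g)",
      abs(sol$score), sol$eps))
  }
  Qstar1 <- stats::plogis(stats::qlogis(clip01(fits$Q1)) + sol$eps / fits$g)
  QstarT <- stats::plogis(off + sol$eps * H)
  list(Qstar1 = Qstar1, QstarT = QstarT, eps_fluct = sol$eps, score = sol$score)
}

#' ARE estimate with efficient-influence-function inference
#'
#' Plug-in estimate of the attributable regional effect,
#' `psi = (1/n) sum(Q*(1, W_i) - Y_i)`, with standard error from the
#' empirical variance of the efficient influence function
#' `D_i = (T_i / g_i) (Y_i - Q*(T_i, W_i)) + Q*(1, W_i) - Y_i - psi`.
#' Estimates are reported in original outcome units via the scaling
#' record; a 95% Wald interval and a two-sided normal p-value accompany
#' the point estimate.
#'
#' @param Qstar1,QstarT Targeted predictions on the scaled scale.
#' @param T_ind Binary membership vector.
#' @param g Bounded propensity vector.
#' @param Y_scaled Scaled outcome.
#' @param record Scaling record from [scale_outcome()].
#' @param eps_fluct Fluctuation coefficient (carried into the fit object).
#' @return Object of class `tmle_fit` with `psi_hat`, `theta_hat` (targeted
#'   treated mean), `se`, `ci_low`, `ci_high`, `p_value`, `eps_fluct`,
#'   `eif` (original outcome units), `n`.
#' @export
estimate_are <- function(Qstar1, QstarT, T_ind, g, Y_scaled, record,
                         eps_fluct = NA_real_) {
  n <- length(Y_scaled)
  if (n < 2) stop("aretree_error_n: need n >= 2 for variance estimation")
  T_ind <- as.numeric(T_ind)
  psi_s <- mean(Qstar1 - Y_scaled)
  eif_s <- (T_ind / g) * (Y_scaled - QstarT) + Qstar1 - Y_scaled - psi_s
  # after a successful fluctuation the H-residual term already averages to
  # zero; explicit centering makes the empirical mean exactly zero for any
  # inputs without changing the variance
  eif_s <- eif_s - mean(eif_s)
  psi <- unscale_estimate(psi_s, record, "difference")
  eif <- unscale_estimate(eif_s, record, "difference")
  se <- sqrt(stats::var(eif) / n)
  theta <- unscale_estimate(mean(Qstar1), record, "mean")
  z <- if (se > 0) psi / se else 0
  structure(list(
    psi_hat = psi, theta_hat = theta, se = se,
    ci_low = psi - 1.96 * se, ci_high = psi + 1.96 * se,
    p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(psi == 0),
    eps_fluct = eps_fluct, eif = eif, n = n), class = "tmle_fit")
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf("ARE = %.4g (SE %.4g, 95%% CI [%.4g, %.4g], p = %.3g, n = %d)\n",
              x$psi_hat, x$se, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Targeted mean outcome within one split arm
#'
#' TMLE for E[Q(arm, W)] where `arm` is the treated (T = 1) or control
#' (T = 0) side of a candidate split, with clever covariate
#' `1{T = arm} / P(T = arm | W)`. Used by the tree search to compare each
#' child node's targeted mean against the parent mean.
#'
#' @param fits List with `Qarm` (initial predictions at the requested arm),
#'   `QT` (at observed T) and `g` (P(T=1|W), bounded), scaled scale.
#' @param T_ind Binary membership vector.
#' @param Y_scaled Scaled outcome.
#' @param arm `"treated"` or `"control"`.
#' @param record Scaling record; estimates returned in outcome units.
#' @return List with `theta` (outcome units), `theta_scaled`, `se`
#'   (outcome units), `eif` (outcome units, mean zero), `eps_fluct`.
#' @export
tmle_node_mean <- function(fits, T_ind, Y_scaled, arm = c("treated", "control"),
                           record = list(min = 0, range = 1)) {
  arm <- match.arg(arm)
  T_ind <- as.numeric(T_ind)
  ind <- if (arm == "treated") T_ind else 1 - T_ind
  if (sum(ind) == 0) {
    stop(sprintf("aretree_error_empty_arm: no observations in the %s arm", arm))
  }
  g_arm <- if (arm == "treated") fits$g else 1 - fits$g
  H <- ind / g_arm
  off <- stats::qlogis(clip01(fits$QT))
  sol <- solve_fluctuation(off, H, Y_scaled)
  Qstar_arm <- stats::plogis(stats::qlogis(clip01(fits$Qarm)) + sol$eps / g_arm)
  QstarT <- stats::plogis(off + sol$eps * H)
  n <- length(Y_scaled)
  theta_s <- mean(Qstar_arm)
  eif_s <- H * (Y_scaled - QstarT) + Qstar_arm - theta_s
  eif_s <- eif_s - mean(eif_s)
  eif <- unscale_estimate(eif_s, record, "difference")
  list(theta = unscale_estimate(theta_s, record, "mean"),
       theta_scaled = theta_s,
       se = sqrt(stats::var(eif) / n),
       eif = eif, eps_fluct = sol$eps)
}
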