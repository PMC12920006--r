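#' Ensemble (super learner) configuration
#'
#' Configures the cross-validated convex ensemble used to estimate the
#' outcome regression Q(T, W) = E[Y | T, W] and the propensity
#' g(W) = P(T = 1 | W). The meta-learner is non-negative least squares on
#' out-of-fold predictions, normalized to a convex combination; the
#' resulting cross-validated risk is never worse than the best single
#' learner up to optimizer tolerance.
#'
#' @param learners Character vector naming base learners, any of
#'   `"mean"` (intercept only), `"glm"` (main-terms generalized linear
#'   model), `"glmnet"` (elastic net, alpha = 0.5), `"ranger"` (random
#'   forest), `"xgboost"` (gradient boosting). Order is irrelevant.
#' @param params Optional named list of per-learner hyperparameter lists,
#'   e.g. `list(ranger = list(num.trees = 300))`.
#' @param v Internal cross-validation fold count (>= 2, default 5).
#' @param g_min Propensity clip bound in (0, 0.5); predictions of
#'   P(T = 1 | W) are truncated to `[g_min, 1 - g_min]` (default 0.025).
#' @return Object of class `ensemble_config`.
#' @examples
#' cfg <- ensemble_config(c("mean", "glm"))
#' @export
ensemble_config <- function(learners = c("mean", "glm", "glmnet", "ranger",
                                         "xgboost"),
                            params = list(), v = 5L, g_min = 0.025) {
  known <- c("mean", "glm", "glmnet", "ranger", "xgboost")
  learners <- unique(as.character(learners))
  if (length(learners) == 0) stop("aretree_error_config: learner menu is empty")
  bad <- setdiff(learners, known)
  if (length(bad)) {
    stop(sprintf("aretree_error_config: unknown learner(s): %s",
                 paste(bad, collapse = ", ")))
  }
  v <- as.integer(v)
  if (v < 2) stop("aretree_error_config: internal folds must be >= 2")
  if (!(g_min > 0 && g_min < 0.5)) {
    stop("aretree_error_config: g_min must be in (0, 0.5)")
  }
  structure(list(learners = learners, params = params, v = v, g_min = g_min),
            class = "ensemble_config")
}

# ---- base learners ----------------------------------------------------------
# Each fitter returns a list with a `predict(newX)` closure. X is a numeric
# matrix (possibly zero columns); y numeric (0/1 for binomial).

fit_learner <- function(name, X, y, family, seed, params = NULL) {
  p <- ncol(X)
  if (name == "mean" || p == 0L || stats::var(y) == 0) {
    mu <- mean(y)
    return(list(predict = function(newX) rep(mu, nrow(newX))))
  }
  if (name == "glm") return(fit_glm_learner(X, y, family))
  if (name == "glmnet") {
    if (p < 2L) return(fit_glm_learner(X, y, family))  # glmnet needs >= 2 cols
    set.seed(seed)
    fam <- if (family == "binomial") "binomial" else "gaussian"
    fit <- tryCatch(
      suppressWarnings(glmnet::cv.glmnet(X, y, family = fam, alpha = 0.5,
                                         nfolds = 3)),
      error = function(e) NULL)
    if (is.null(fit)) return(fit_glm_learner(X, y, family))
    return(list(predict = function(newX) {
      as.numeric(stats::predict(fit, newx = newX, s = "lambda.min",
                                type = "response"))
    }))
  }
  if (name == "ranger") {
    pr <- c(list(num.trees = 200, min.node.size = if (family == "binomial") 10 else 5),
            params)
    df <- data.frame(.y = y, X)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = pr$num.trees, min.node.size = pr$min.node.size,
      num.threads = 1, seed = seed, verbose = FALSE)
    cn <- colnames(X)
    return(list(predict = function(newX) {
      nd <- as.data.frame(newX); names(nd) <- cn
      as.numeric(stats::predict(fit, data = nd, num.threads = 1)$predictions)
    }))
  }
  if (name == "xgboost") {
    pr <- c(list(nrounds = 50, max_depth = 3, eta = 0.3), params)
    set.seed(seed)
    yfit <- if (family == "binomial") factor(y, levels = c(0, 1)) else y
    fit <- xgboost::xgboost(
      x = X, y = yfit, nrounds = pr$nrounds, max_depth = pr$max_depth,
      learning_rate = pr$eta, nthreads = 1, verbosity = 0)
    return(list(predict = function(newX) {
      if (family == "binomial") {
        as.numeric(stats::predict(fit, newX, type = "response"))
      } else {
        as.numeric(stats::predict(fit, newX))
      }
    }))
  }
  stop("aretree_error_config: unknown learner: ", name)
}

fit_glm_learner <- function(X, y, family) {
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xd, y, family = fam)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)[1]))) {
    mu <- mean(y)
    return(list(predict = function(newX) rep(mu, nrow(newX))))
  }
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  linkinv <- fam$linkinv
  list(predict = function(newX) {
    eta <- as.numeric(cbind(1, newX) %*% beta)
    linkinv(eta)
  })
}

# ---- super learner ----------------------------------------------------------

#' Fit a cross-validated convex ensemble
#'
#' Internal workhorse for [fit_outcome_ensemble()] and
#' [fit_propensity_ensemble()]. Each base learner is fitted on each
#' internal training fold and evaluated out-of-fold; ensemble weights are
#' the non-negative least-squares solution (normalized to sum to one) that
#' minimizes cross-validated squared error of the convex combination.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response (0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param config An [ensemble_config()].
#' @param seed Integer seed controlling internal folds and stochastic
#'   learners.
#' @return Object of class `ensemble_fit` with elements `weights`,
#'   `cv_risk` (per learner and for the ensemble), `oof` (out-of-fold
#'   ensemble predictions), and a `predict(newX)` closure.
#' @keywords internal
fit_ensemble <- function(X, y, family = c("gaussian", "binomial"),
                         config = ensemble_config(), seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- length(y)
  if (n < 2L * config$v) {
    stop("aretree_error_n: need n >= 2 * internal folds for the ensemble")
  }
  if (stats::var(y) == 0) {  # degenerate response: constant predictor
    mu <- y[1]
    return(structure(list(
      weights = stats::setNames(1, "mean"),
      cv_risk = stats::setNames(0, "mean"), oof = rep(mu, n),
      predict = function(newX) rep(mu, nrow(as.matrix(newX)))),
      class = "ensemble_fit"))
  }
  L <- config$learners
  set.seed(seed)
  folds <- sample(rep(seq_len(config$v), length.out = n))
  Z <- matrix(NA_real_, n, length(L), dimnames = list(NULL, L))
  for (v in seq_len(config$v)) {
    tr <- folds != v
    for (j in seq_along(L)) {
      fit <- tryCatch(
        fit_learner(L[j], X[tr, , drop = FALSE], y[tr], family,
                    seed = seed + 7L * v + 131L * j,
                    params = config$params[[L[j]]]),
        error = function(e) NULL)
      Z[!tr, j] <- if (is.null(fit)) mean(y[tr])
                   else fit$predict(X[!tr, , drop = FALSE])
    }
  }
  if (family == "binomial") Z <- clip01(Z)
  cv_risk <- colMeans((Z - y)^2)
  w <- tryCatch(pracma::lsqnonneg(Z, y)$x, error = function(e) NULL)
  if (is.null(w) || sum(w) <= 0 || any(!is.finite(w))) {
    w <- as.numeric(seq_along(L) == which.min(cv_risk))
  }
  w <- w / sum(w)
  names(w) <- L
  oof <- as.numeric(Z %*% w)
  ens_risk <- mean((oof - y)^2)
  # normalizing the NNLS solution to a convex combination can degrade the
  # CV risk; fall back to the single best learner when it does
  if (ens_risk > min(cv_risk)) {
    w <- as.numeric(seq_along(L) == which.min(cv_risk))
    names(w) <- L
    oof <- as.numeric(Z %*% w)
    ens_risk <- mean((oof - y)^2)
  }
  # refit each contributing learner on the full data
  full_fits <- vector("list", length(L))
  for (j in seq_along(L)) {
    if (w[j] > 0) {
      full_fits[[j]] <- tryCatch(
        fit_learner(L[j], X, y, family, seed = seed + 977L * j,
                    params = config$params[[L[j]]]),
        error = function(e) NULL)
      if (is.null(full_fits[[j]])) w[j] <- 0
    }
  }
  if (sum(w) == 0) stop("aretree_error_learners: all learners failed")
  w <- w / sum(w)
  pred_fun <- function(newX) {
    newX <- as.matrix(newX); storage.mode(newX) <- "double"
    out <- numeric(nrow(newX))
    for (j in seq_along(L)) {
      if (w[j] > 0) out <- out + w[j] * full_fits[[j]]$predict(newX)
    }
    if (family == "binomial") out <- clip01(out)
    out
  }
  structure(list(weights = w, cv_risk = c(cv_risk, ensemble = ens_risk),
                 oof = oof, predict = pred_fun),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("super-learner fit; weights:\n")
  print(round(x$weights[x$weights > 0], 3))
  invisible(x)
}

#' Super-learner fit of the outcome regression
#'
#' Estimates Q(T, W) = E[Y | T, W] by regressing the outcome on the region
#' indicator and covariates with a cross-validated convex ensemble.
#'
#' @param T_ind Binary region-membership vector.
#' @param W Covariate matrix (may have zero columns).
#' @param Y Numeric outcome (typically already scaled to [0, 1] for
#'   targeting).
#' @param config An [ensemble_config()].
#' @param seed Integer seed.
#' @return List with `predict(t, W)` returning predictions at T = t,
#'   `weights`, `cv_risk`.
#' @export
fit_outcome_ensemble <- function(T_ind, W, Y, config = ensemble_config(),
                                 seed = 1L) {
  W <- as.matrix(W)
  X <- cbind(.T = as.numeric(T_ind), W)
  fit <- fit_ensemble(X, Y, "gaussian", config, seed)
  list(
    predict = function(t, Wnew) {
      Wnew <- as.matrix(Wnew)
      fit$predict(cbind(.T = rep(as.numeric(t), nrow(Wnew)), Wnew))
    },
    weights = fit$weights, cv_risk = fit$cv_risk)
}

#' Super-learner fit of the propensity score
#'
#' Estimates g(W) = P(T = 1 | W) with a cross-validated convex ensemble.
#' The returned per-observation predictions are cross-fitted (each comes
#' from models not trained on that observation) and truncated to
#' `[g_min, 1 - g_min]`.
#'
#' @inheritParams fit_outcome_ensemble
#' @return List with `g` (cross-fitted bounded predictions for the input
#'   rows), `predict(Wnew)` (bounded predictions for new rows from the
#'   full-data refit), `weights`, `cv_risk`, `g_min`.
#' @export
fit_propensity_ensemble <- function(T_ind, W, config = ensemble_config(),
                                    seed = 1L) {
  T_ind <- as.numeric(T_ind)
  if (length(unique(T_ind)) < 2) {
    stop("aretree_error_single_class: T has a single class (positivity failure)")
  }
  W <- as.matrix(W)
  fit <- fit_ensemble(W, T_ind, "binomial", config, seed)
  gm <- config$g_min
  list(
    g = pmin(pmax(fit$oof, gm), 1 - gm),
    predict = function(Wnew) {
      pmin(pmax(fit$predict(as.matrix(Wnew)), gm), 1 - gm)
    },
    weights = fit$weights, cv_risk = fit$cv_risk, g_min = gm)
}

# ---- fast in-tree nuisance fits --------------------------------------------
# The tree search evaluates hundreds of candidate splits per node; each needs
# a propensity fit (positivity check, clever covariate) and an initial
# outcome fit. Both come from one coarse covariate stratification per
# node/exposure, so the per-candidate cost is a few tapply passes; the
# fold-level nuisances used for reported inference are always the full
# ensemble.

# Coarse covariate stratification for the in-tree split propensity: the
# leaves of one depth-limited regression tree of the target variable on W.
# Stratum means of T then estimate P(T = 1 | W) for *every* candidate
# cutpoint of the same exposure at once. The deliberate coarseness (few,
# large strata) mirrors a shallow random forest: it smooths extreme
# conditional probabilities so the positivity filter rejects genuinely
# unsupported tail splits without vetoing every split under strong
# exposure-covariate confounding.
propensity_strata <- function(target, W, min_bucket = 20L) {
  n <- length(target)
  if (ncol(W) == 0L || n < 2L * min_bucket) return(factor(rep(1L, n)))
  df <- data.frame(.t = target, W)
  fit <- tryCatch(
    rpart::rpart(.t ~ ., data = df, method = "anova",
                 control = rpart::rpart.control(
                   maxdepth = 2L, minbucket = min_bucket, cp = 0.01,
                   maxsurrogate = 0L, maxcompete = 0L, xval = 0L)),
    error = function(e) NULL)
  if (is.null(fit)) return(factor(rep(1L, n)))
  factor(fit$where)
}

stratified_propensity <- function(T_ind, strata) {
  mu <- tapply(T_ind, strata, mean)
  as.numeric(mu[strata])
}


# Outcome fit saturated on the propensity strata: stratum-by-arm means.
# Paired with the stratified propensity this makes the in-tree TMLE the
# classic post-stratification estimator: the fluctuation score is already
# solved (eps = 0) and the EIF variance matches the estimator's actual
# sampling variance to first order. Strata with an empty arm fall back to
# the overall stratum mean (such candidates fail positivity anyway).
stratum_outcome <- function(T_ind, strata, Y) {
  mu_s <- tapply(Y, strata, mean)
  mu1 <- tapply(Y[T_ind == 1], strata[T_ind == 1], mean)
  mu0 <- tapply(Y[T_ind == 0], strata[T_ind == 0], mean)
  lev <- levels(strata)
  m1 <- mu1[lev]; m0 <- mu0[lev]; ms <- mu_s[lev]
  m1[is.na(m1)] <- ms[is.na(m1)]
  m0[is.na(m0)] <- ms[is.na(m0)]
  si <- as.integer(strata)
  Q1 <- as.numeric(m1[si]); Q0 <- as.numeric(m0[si])
  list(Q1 = Q1, Q0 = Q0, QT = ifelse(T_ind == 1, Q1, Q0))
}

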