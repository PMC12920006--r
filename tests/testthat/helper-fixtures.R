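# Programmatic fixtures shared across tests.

# dataset with a single strong step effect: Y jumps by `effect` when A1 <= 2
step_dataset <- function(n = 500, effect = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  A1 <- sample(1:4, n, replace = TRUE)
  A2 <- round(rnorm(n), 1)
  W1 <- rnorm(n)
  Y <- effect * (A1 <= 2) + 0.2 * W1 + rnorm(n, 0, sd)
  mixture_dataset(W = data.frame(W1 = W1),
                  A = data.frame(A1 = A1, A2 = A2), Y = Y)
}

# dataset with Y independent of the exposures (and of W)
noise_dataset <- function(n = 400, seed = 1) {
  set.seed(seed)
  mixture_dataset(W = data.frame(W1 = rnorm(n), W2 = rnorm(n)),
                  A = data.frame(A1 = round(rnorm(n), 1),
                                 A2 = round(rnorm(n), 1)),
                  Y = rnorm(n))
}

fast_ens <- function() ensemble_config(c("mean", "glm"))

expect_region_equal <- function(a, b) {
  fa <- region_to_frame(a); fb <- region_to_frame(b)
  oa <- order(fa$exposure, fa$operator); ob <- order(fb$exposure, fb$operator)
  expect_equal(fa[oa, , drop = FALSE], fb[ob, , drop = FALSE],
               ignore_attr = TRUE)
}
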