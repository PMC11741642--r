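# Shared fixtures: everything is generated in code at test time.

rand_psd <- function(r, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(r * r), r, r)
  crossprod(A) / r
}

# small individual-level dataset with mild LD and sparse effects
small_dataset <- function(n = 80, p = 10, r = 2, n_causal = 3, seed = 1,
                          h2 = 0.5) {
  sim <- simulate_scenario("equal_effects", n_train = n, n_test = 0, p = p,
                           n_causal = n_causal, r = r, h2 = h2, seed = seed)
  list(X = sim$X_train, Y = sim$Y_train, B = sim$B_true, sim = sim)
}

# a small random prior: null + a few scaled canonical components
small_prior <- function(r, seed = NULL, n_scales = 2) {
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(10^runif(n_scales, -3, -0.5))
  mixture_prior(scale_expand(canonical_covs(r, rho = 0.5), grid))
}

# random sufficient statistics derived from simulated data (always valid)
random_suffstats <- function(seed, n = NULL, p = NULL, r = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(60:140, 1)
  if (is.null(p)) p <- sample(6:14, 1)
  if (is.null(r)) r <- sample(1:3, 1)
  d <- small_dataset(n = n, p = p, r = r,
                     n_causal = max(2, p %/% 3), seed = seed)
  compute_suffstats(d$X, scale(d$Y))
}

expect_simplex <- function(w, tol = 1e-12) {
  expect_true(all(w >= -tol))
  expect_lt(abs(sum(w) - 1), 1e-8)
}
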