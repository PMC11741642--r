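# log N(x; 0, S) used as an independent density reference in the oracles
ldmvn <- function(x, S) {
  L <- chol(S)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

test_that("single-variant posterior matches the scalar conjugate closed form", {
  # r = 1, K = 1 beyond the null: d = 10, bhat = 1, V = 1, S0 = 1
  pr <- mixture_prior(list(matrix(0, 1, 1), matrix(1, 1, 1)), w0 = c(0, 1))
  up <- mixture_posterior(1, 10, matrix(1, 1, 1), pr)
  expect_equal(up$mu1[1, 2], 10 / 11, tolerance = 1e-12)
  expect_equal(up$Sigma1[1, 1, 2], 1 / 11, tolerance = 1e-12)
  expect_equal(up$b_bar, 10 / 11, tolerance = 1e-12, ignore_attr = TRUE)

  # the null component has exactly zero posterior mean and covariance
  pr2 <- mixture_prior(list(matrix(0, 1, 1), matrix(1, 1, 1)), w0 = c(0.5, 0.5))
  up2 <- mixture_posterior(3, 5, matrix(2, 1, 1), pr2)
  expect_identical(up2$mu1[1, 1], 0)
  expect_identical(up2$Sigma1[1, 1, 1], 0)
})

test_that("component marginal likelihood agrees with 2-D quadrature", {
  # N(bhat; 0, S0 + V/d) must equal the integral of
  # N(bhat; b, V/d) N(b; 0, S0) db, computed on a grid
  set.seed(31)
  S0 <- rand_psd(2) + 0.3 * diag(2)
  V <- rand_psd(2) + 0.5 * diag(2)
  d <- 4
  bhat <- c(0.8, -0.4)
  pr <- mixture_prior(list(matrix(0, 2, 2), S0), w0 = c(0.5, 0.5))
  up <- mixture_posterior(bhat, d, V, pr)

  h <- 0.02
  g <- seq(-8, 8, by = h)
  gr <- as.matrix(expand.grid(b1 = g, b2 = g))
  Vd <- V / d
  lik <- exp(apply(gr, 1, function(b) ldmvn(bhat - b, Vd)) +
               apply(gr, 1, function(b) ldmvn(b, S0)))
  quad <- sum(lik) * h^2
  analytic <- exp(ldmvn(bhat, S0 + Vd))
  expect_lt(abs(quad - analytic) / analytic, 1e-6)

  # and the responsibilities use exactly that marginal
  lg <- c(ldmvn(bhat, Vd), ldmvn(bhat, S0 + Vd)) + log(c(0.5, 0.5))
  gamma_oracle <- exp(lg - max(lg)) / sum(exp(lg - max(lg)))
  expect_equal(as.numeric(up$gamma), gamma_oracle, tolerance = 1e-10)
})

test_that("near-duplicate components share responsibilities symmetrically", {
  S <- diag(2)
  pr <- mixture_prior(list(matrix(0, 2, 2), S, S + 1e-9),
                      w0 = c(0.2, 0.4, 0.4))
  expect_identical(pr$K, 3L)  # 1e-9 apart: not deduplicated
  up <- mixture_posterior(c(1, 2), 8, diag(2), pr)
  expect_equal(up$gamma[2], up$gamma[3], tolerance = 1e-6)
})

test_that("null-only prior yields a zero fit", {
  d <- small_dataset(n = 60, p = 8, r = 2, seed = 3)
  ss <- compute_suffstats(d$X, d$Y)
  pr <- mixture_prior(list(matrix(0, 2, 2)), w0 = 1)
  fit <- mr_mash_rss(ss, prior = pr, control = mr_mash_control(update_V = FALSE))
  expect_equal(unname(coef(fit)), matrix(0, 8, 2))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2L)
  expect_equal(unname(predict(fit, d$X)), matrix(0, 60, 2))
})

test_that("K = 1 normal prior converges to the Bayesian ridge fixed point", {
  set.seed(41)
  n <- 200; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) * 0.3 + rnorm(n)
  ss <- compute_suffstats(X, y)
  s0 <- 0.5; sig2 <- 2
  pr <- mixture_prior(list(matrix(0, 1, 1), matrix(s0, 1, 1)), w0 = c(0, 1))
  fit <- mr_mash_rss(ss, prior = pr, V_init = matrix(sig2, 1, 1),
                     control = mr_mash_control(tol = 1e-13, max_iter = 5000,
                                               update_w0 = FALSE,
                                               update_V = FALSE))
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  ridge <- solve(crossprod(Xc) + (sig2 / s0) * diag(p), crossprod(Xc, yc))
  expect_lt(max(abs(coef(fit) - ridge)), 1e-6)
})

test_that("ELBO equals the exact log marginal likelihood in the conjugate case", {
  set.seed(42)
  n <- 50
  x <- rnorm(n); x <- x - mean(x)
  y <- 0.5 * x + rnorm(n); y <- y - mean(y)
  s02 <- 0.7; sig2 <- 1.3
  ss <- suff_stats(matrix(sum(x^2), 1, 1), matrix(sum(x * y), 1, 1),
                   YtY = matrix(sum(y^2), 1, 1), n = n)
  pr <- mixture_prior(list(matrix(0, 1, 1), matrix(s02, 1, 1)), w0 = c(0, 1))
  fit <- mr_mash_rss(ss, prior = pr, V_init = matrix(sig2, 1, 1),
                     control = mr_mash_control(update_w0 = FALSE,
                                               update_V = FALSE, max_iter = 4))
  C <- sig2 * diag(n) + s02 * tcrossprod(x)
  logml <- as.numeric(-0.5 * (n * log(2 * pi) +
                              determinant(C)$modulus) -
                        0.5 * crossprod(y, solve(C, y)))
  expect_equal(tail(fit$elbo, 1), logml, tolerance = 1e-8)
  # the standalone state-function evaluation agrees at the fixed point
  expect_equal(compute_elbo(ss, coef(fit), pr, matrix(sig2, 1, 1)), logml,
               tolerance = 1e-8)
})

test_that("the ELBO is a function of the state, invariant to variant relabeling", {
  d <- small_dataset(n = 100, p = 9, r = 2, seed = 13)
  ss <- compute_suffstats(d$X, scale(d$Y))
  pr <- small_prior(2, seed = 13)
  fit <- mr_mash_rss(ss, prior = pr,
                     control = mr_mash_control(update_V = FALSE))
  e1 <- compute_elbo(ss, coef(fit), pr, fit$V)
  # permute the variant order of the whole state; the ELBO cannot change
  perm <- sample(9)
  ss_p <- suff_stats(ss$XtX[perm, perm], ss$XtY[perm, , drop = FALSE],
                     YtY = ss$YtY, n = ss$n)
  e2 <- compute_elbo(ss_p, coef(fit)[perm, , drop = FALSE], pr, fit$V)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("per-sweep ELBO is nondecreasing across random small fits", {
  for (seed in 1:12) {
    ss <- random_suffstats(seed)
    r <- ncol(ss$XtY)
    pr <- small_prior(r, seed = seed + 100)
    fit <- mr_mash_rss(ss, prior = pr,
                       control = mr_mash_control(update_V = (seed %% 2 == 0)))
    difs <- diff(fit$elbo)
    expect_true(all(difs >= -1e-8 * abs(fit$elbo[-1])))
  }
})

test_that("weight updates are exact responsibility averages on the simplex", {
  g <- matrix(rep(c(0.3, 0.7), each = 5), 5, 2)
  expect_equal(update_w0(g), c(0.3, 0.7))
  expect_equal(update_w0(diag(4)), rep(0.25, 4))

  set.seed(51)
  G <- matrix(rexp(60), 12, 5); G <- G / rowSums(G)
  w <- update_w0(G)
  expect_simplex(w)
  # local optimality of the ELBO's weight term sum_jk gamma_jk log w_k
  # against perturbations projected back to the simplex
  obj <- function(w) sum(G %*% log(w))
  for (i in 1:10) {
    eps <- rnorm(5, sd = 1e-3)
    wp <- pmax(w + eps, 1e-9); wp <- wp / sum(wp)
    expect_lte(obj(wp), obj(w) + 1e-12)
  }
})

test_that("residual covariance update: null-model case, recovery, and floor", {
  # B = 0 and no posterior variance -> V = Y'Y / n
  d <- small_dataset(n = 70, p = 6, r = 2, seed = 9)
  ss <- compute_suffstats(d$X, d$Y)
  V <- update_V(ss, matrix(0, 6, 2), matrix(0, 2, 2))
  expect_equal(V, ss$YtY / ss$n, tolerance = 1e-12, ignore_attr = TRUE)

  # symmetric with floored eigenvalues on random valid inputs
  for (seed in 1:5) {
    set.seed(seed)
    ssr <- random_suffstats(seed + 40, r = 2)
    B <- matrix(rnorm(nrow(ssr$XtX) * 2, sd = 0.05), ncol = 2)
    vp <- rand_psd(2) * 0.1
    Vr <- update_V(ssr, B, vp)
    expect_lt(max(abs(Vr - t(Vr))), 1e-12)
    expect_gte(min(eigen(Vr, symmetric = TRUE, only.values = TRUE)$values),
               1e-8 - 1e-15)
  }
  ss_noyty <- suff_stats(ss$XtX, ss$XtY, n = ss$n)
  expect_error(update_V(ss_noyty, matrix(0, 6, 2), matrix(0, 2, 2)), "Y'Y")
})

test_that("estimated residual covariance approaches the simulation truth", {
  set.seed(61)
  n <- 500; p <- 20; r <- 2
  X <- matrix(rnorm(n * p), n, p)
  B_true <- matrix(0, p, r)
  B_true[1:5, ] <- matrix(rnorm(10, sd = 0.4), 5, r)
  V_true <- matrix(c(1, 0.3, 0.3, 0.8), 2, 2)
  Y <- X %*% B_true + matrix(rnorm(n * r), n, r) %*% chol(V_true)
  ss <- compute_suffstats(X, Y)
  pr <- mixture_prior(scale_expand(canonical_covs(2), c(0.05, 0.2, 0.8)))
  fit <- mr_mash_rss(ss, prior = pr)
  expect_lt(norm(fit$V - V_true, "F") / norm(V_true, "F"), 0.15)
})

test_that("shrinkage is monotone in prior variance and in precision", {
  V <- matrix(1, 1, 1)
  post_mean <- function(s0, d) {
    pr <- mixture_prior(list(matrix(0, 1, 1), matrix(s0, 1, 1)), w0 = c(0, 1))
    abs(mixture_posterior(1.5, d, V, pr)$b_bar)
  }
  m_s0 <- sapply(c(0.1, 0.5, 1, 5, 20), post_mean, d = 5)
  expect_true(all(diff(m_s0) > 0))
  m_d <- sapply(c(0.5, 2, 8, 32), function(d) post_mean(1, d))
  expect_true(all(diff(m_d) > 0))
})

test_that("posterior mean effects track large simulated effects", {
  sim <- simulate_scenario("equal_effects", n_train = 1000, n_test = 0,
                           p = 150, n_causal = 8, r = 3, h2 = 0.6, seed = 19)
  ss <- compute_suffstats(sim$X_train, scale(sim$Y_train))
  pr <- mixture_prior(scale_expand(canonical_covs(3),
                                   c(1e-4, 1e-3, 1e-2, 0.1)))
  fit <- mr_mash_rss(ss, prior = pr)
  # phenotypes were rescaled to unit variance; correlation is scale-free
  expect_gt(cor(as.vector(coef(fit)), as.vector(sim$B_true)), 0.8)
})

test_that("summary-data fit with in-sample LD equals the individual-data fit", {
  d <- small_dataset(n = 300, p = 30, r = 3, n_causal = 5, seed = 23)
  Y <- scale(d$Y)
  ss_ind <- compute_suffstats(d$X, Y)
  gw <- gwas_scan(d$X, Y)
  ld <- compute_ld(d$X, d$sim$positions_cm, d$sim$chrom)
  ss_rec <- recover_suffstats(gw, ld, yty_mode = "supplied",
                              YtY = crossprod(scale(Y, scale = FALSE)))
  pr <- small_prior(3, seed = 23)
  f1 <- mr_mash_rss(ss_ind, prior = pr)
  f2 <- mr_mash_rss(ss_rec, prior = pr)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-6)
  expect_equal(f1$w0, f2$w0, tolerance = 1e-6)
})

test_that("update-order shuffling reaches an equivalent optimum", {
  ss <- random_suffstats(71, n = 120, p = 10, r = 2)
  pr <- small_prior(2, seed = 71)
  f_fixed <- mr_mash_rss(ss, prior = pr,
                         control = mr_mash_control(tol = 1e-10))
  f_shuf <- mr_mash_rss(ss, prior = pr,
                        control = mr_mash_control(tol = 1e-10,
                                                  update_order = "shuffled",
                                                  seed = 5))
  expect_lt(max(abs(coef(f_fixed) - coef(f_shuf))), 1e-4)
  expect_true(all(diff(f_shuf$elbo) >= -1e-8 * abs(f_shuf$elbo[-1])))
})

test_that("responsibility rows lie on the simplex and V stays positive definite", {
  ss <- random_suffstats(81, r = 2)
  pr <- small_prior(2, seed = 81)
  fit <- mr_mash_rss(ss, prior = pr)
  expect_true(all(abs(rowSums(fit$gamma) - 1) < 1e-8))
  expect_true(all(fit$gamma >= 0))
  expect_gt(min(eigen(fit$V, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("the fitted V is the M-step of the returned state", {
  ss <- random_suffstats(95, n = 100, p = 10, r = 2)
  fit <- mr_mash_rss(ss, prior = small_prior(2, seed = 95),
                     control = mr_mash_control(update_V = TRUE))
  expect_equal(fit$V, update_V(ss, coef(fit), fit$var_part),
               tolerance = 1e-8, ignore_attr = TRUE)
})
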