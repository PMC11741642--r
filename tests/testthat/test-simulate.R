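test_that("genotype simulation is deterministic and LD-tunable", {
  g1 <- simulate_genotypes(50, 20, seed = 9)
  g2 <- simulate_genotypes(50, 20, seed = 9)
  expect_identical(g1, g2)  # bit-identical under a fixed seed
  expect_true(all(g1$X %in% 0:2))
  expect_true(!is.unsorted(g1$positions_cm))

  # no latent correlation: adjacent sample r^2 stays near zero
  g0 <- simulate_genotypes(5000, 12, ld_decay = 0, seed = 10)
  adj <- sapply(1:11, function(j) cor(g0$X[, j], g0$X[, j + 1])^2)
  expect_lt(max(adj), 0.05)
})

test_that("adjacent dosage correlation matches the threshold-model oracle", {
  # at MAF 0.5 and latent AR(1) rho = 0.9, the dosage correlation follows
  # from bivariate-normal rectangle probabilities, integrated numerically
  rho <- 0.9; f <- 0.5
  q0 <- qnorm((1 - f)^2); q1 <- qnorm((1 - f)^2 + 2 * f * (1 - f))
  h <- 0.01
  g <- seq(-6, 6, by = h)
  dens <- outer(g, g, function(a, b)
    exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2)))
  upper_tail2 <- function(a, b) sum(dens[g > a, g > b]) * h^2
  Eg1g2 <- 0
  for (a in c(q0, q1)) for (b in c(q0, q1))
    Eg1g2 <- Eg1g2 + upper_tail2(a, b)
  mu <- 2 * f
  v <- 2 * f * (1 - f)
  cor_oracle <- (Eg1g2 - mu^2) / v

  gg <- simulate_genotypes(10000, 8, ld_decay = rho,
                           maf_range = c(0.4999, 0.5), seed = 12)
  adj <- mean(sapply(1:7, function(j) cor(gg$X[, j], gg$X[, j + 1])))
  expect_lt(abs(adj - cor_oracle), 0.1)
})

test_that("effect sampling obeys the scenario sharing patterns exactly", {
  B <- simulate_effects(500, 40, 5, "equal_effects", seed = 3)
  nz <- rowSums(B != 0) > 0
  expect_identical(sum(nz), 40L)                       # causal count exact
  expect_true(all(apply(B[nz, ], 1, function(x) length(unique(x))) == 1))

  Bm <- simulate_effects(500, 40, 5, "mostly_null", seed = 3)
  expect_true(all(Bm[, 2:5] == 0))
  expect_identical(sum(Bm[, 1] != 0), 40L)

  Bs <- simulate_effects(500, 60, 5, "shared_subgroups", seed = 3)
  nzs <- which(rowSums(Bs != 0) > 0)
  expect_identical(length(nzs), 60L)
  for (j in nzs) {
    act <- unname(which(Bs[j, ] != 0))
    expect_true(identical(act, 1:3) || identical(act, 4:5))
  }
  # both subgroups appear under a fair coin
  pat <- apply(Bs[nzs, ], 1, function(x) paste(which(x != 0), collapse = ""))
  expect_setequal(unique(pat), c("123", "45"))
})

test_that("phenotype simulation hits target heritability exactly in-sample", {
  g <- simulate_genotypes(400, 50, seed = 21)
  B <- simulate_effects(50, 10, 3, "equal_effects", seed = 21)

  ph <- simulate_phenotypes(g$X, B, h2 = c(0.5, 0, 1), seed = 21)
  # h2 = 0: effect column zeroed, realized exactly 0
  expect_true(all(ph$B[, 2] == 0))
  expect_identical(ph$realized_h2[2], 0)
  # h2 = 1: no residual, phenotype equals the genetic value
  expect_equal(ph$Y[, 3], ph$G[, 3], ignore_attr = TRUE)
  # in-sample genetic variance is the target exactly
  expect_equal(var(ph$G[, 1]), 0.5, tolerance = 1e-12)
  # realized value differs only through residual sampling noise
  expect_lt(abs(ph$realized_h2[1] - 0.5), 0.1)

  expect_error(simulate_phenotypes(g$X, matrix(0, 50, 1), h2 = 0.3),
               "zero genetic variance")
})

test_that("quantile normalization matches an independent transform oracle", {
  y <- c(5, 1, 3, 2, 4)
  q <- quantile_normalize(y)
  expect_true(all(diff(q[order(y)]) > 0))  # order-isomorphic

  set.seed(31)
  yr <- rnorm(100)
  q2 <- quantile_normalize(yr)
  expect_lt(abs(mean(q2)), 1e-10)  # Blom scores are symmetric
  # independently coded sort-then-transform oracle
  oracle <- numeric(100)
  oracle[order(yr)] <- qnorm(((1:100) - 3 / 8) / (100 + 1 / 4))
  expect_equal(q2, oracle, tolerance = 1e-12)

  expect_error(quantile_normalize(rep(1, 5)), "constant")
})

test_that("the single-variant scan matches least squares and is calibrated", {
  set.seed(41)
  n <- 200
  X <- simulate_genotypes(n, 10, seed = 41)$X
  # exact linear relation: coefficient recovered, se collapses
  y_exact <- 2 * X[, 3]
  gw <- gwas_scan(X, cbind(y = y_exact + 0))
  expect_equal(gw$betahat[3, 1], 2, tolerance = 1e-10)
  expect_lte(gw$se[3, 1], 1e-10)

  # library-grade OLS oracle on random variant-phenotype pairs
  Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p1", "p2")))
  gw2 <- gwas_scan(X, Y)
  for (i in 1:20) {
    j <- sample(10, 1); t <- sample(2, 1)
    sm <- summary(lm(Y[, t] ~ X[, j]))$coefficients
    expect_equal(gw2$betahat[j, t], sm[2, 1], tolerance = 1e-10)
    expect_equal(gw2$se[j, t], sm[2, 2], tolerance = 1e-10)
  }

  # permuted-phenotype null: z-scores are standard normal
  sim <- simulate_scenario("equal_effects", n_train = 500, n_test = 0,
                           p = 1000, n_causal = 10, r = 1, seed = 43)
  yperm <- sim$Y_train[sample(nrow(sim$Y_train)), 1, drop = FALSE]
  gwn <- gwas_scan(sim$X_train, yperm, quantile_norm = TRUE)
  z <- gwn$betahat / gwn$se
  expect_gt(suppressWarnings(ks.test(z, "pnorm")$p.value), 0.01)
})

test_that("MCAR masking draws uniform nonempty patterns", {
  Y <- matrix(rnorm(60), 20, 3)
  expect_identical(mcar_mask(Y, 0), Y)          # no masking
  m1 <- mcar_mask(Y, 0.5, seed = 5)
  m2 <- mcar_mask(Y, 0.5, seed = 5)
  expect_identical(m1, m2)                      # deterministic under seed

  # frac = 1, r = 5: every individual gets >= 1 missing entry and the 31
  # nonempty patterns occur uniformly
  set.seed(6)
  Yb <- matrix(rnorm(31000 * 5), 31000, 5)
  Mb <- mcar_mask(Yb, 1, seed = 6)
  miss <- is.na(Mb)
  expect_true(all(rowSums(miss) >= 1))
  pat <- as.integer(miss %*% 2^(0:4))
  expect_gt(chisq.test(tabulate(pat, 31))$p.value, 0.01)
})

test_that("LD computation handles edge cases and external panels degrade accuracy", {
  X1 <- matrix(c(0, 1, 2, 1, 0), 5, 1, dimnames = list(NULL, "v1"))
  expect_equal(compute_ld(X1)$R, matrix(1, 1, 1), ignore_attr = TRUE)
  expect_error(compute_ld(cbind(v1 = rep(1, 5))), "zero-variance")

  # reference-panel mismatch: a small external panel with perturbed LD gives
  # lower prediction accuracy than in-sample LD on the same simulation
  sim <- simulate_scenario("equal_effects", n_train = 1000, n_test = 500,
                           p = 300, n_causal = 15, r = 3, seed = 9)
  gw <- gwas_scan(sim$X_train, sim$Y_train, quantile_norm = TRUE)
  Yq <- apply(sim$Y_train, 2, quantile_normalize)
  YtY <- crossprod(scale(Yq, scale = FALSE))
  pr <- mixture_prior(scale_expand(canonical_covs(3),
                                   default_scale_grid(gw, length = 5)))
  ld_in <- compute_ld(sim$X_train, sim$positions_cm, sim$chrom)
  ref <- simulate_genotypes(503, 300, ld_decay = 0.8, seed = 99)
  blocks <- ld_block_diagonal(as.integer(cut(sim$positions_cm,
                                             seq(0, max(sim$positions_cm) + 3,
                                                 by = 3))))
  ld_ext <- ld_matrix(cor(ref$X), sim$positions_cm, sim$chrom,
                      colnames(sim$X_train), structure = blocks)
  ctl <- mr_mash_control(tol = 1e-5)
  f_in <- mr_mash_rss(recover_suffstats(gw, ld_in, yty_mode = "supplied",
                                        YtY = YtY), prior = pr, control = ctl)
  f_ex <- mr_mash_rss(recover_suffstats(gw, ld_ext, yty_mode = "supplied",
                                        YtY = YtY), prior = pr, control = ctl)
  r2_in <- mean(evaluate_r2(sim$Y_test, sim$X_test %*% coef(f_in)))
  r2_ex <- mean(evaluate_r2(sim$Y_test, sim$X_test %*% coef(f_ex)))
  expect_gt(r2_in, r2_ex)
})

test_that("scenario generation is reproducible and respects its presets", {
  s1 <- simulate_scenario("mostly_null", n_train = 100, n_test = 50, p = 40,
                          n_causal = 5, seed = 77)
  s2 <- simulate_scenario("mostly_null", n_train = 100, n_test = 50, p = 40,
                          n_causal = 5, seed = 77)
  expect_identical(s1$Y_train, s2$Y_train)
  expect_identical(s1$X_test, s2$X_test)
  expect_identical(ncol(s1$Y_train), 5L)
  expect_true(all(s1$B_true[, 2:5] == 0))

  s3 <- simulate_scenario("more_phenotypes", n_train = 100, n_test = 0,
                          p = 40, n_causal = 5, seed = 78)
  expect_identical(ncol(s3$Y_train), 10L)

  s4 <- simulate_scenario("mcar_missingness", n_train = 100, n_test = 0,
                          p = 40, n_causal = 5, mcar_frac = 0.2, seed = 79)
  expect_identical(sum(apply(is.na(s4$Y_train_missing), 1, any)), 20L)
})
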