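#' Simulate LD-structured genotype dosages
#'
#' Draws 0/1/2 genotype dosages with tunable local LD by thresholding
#' latent Gaussian vectors: individuals' latent values follow an AR(1)
#' process along the variant axis with lag-one correlation `ld_decay`, and
#' each variant's latent value is cut twice at the quantiles implied by its
#' minor allele frequency (Hardy-Weinberg genotype frequencies
#' \eqn{(1-f)^2, 2f(1-f), f^2}).  Genetic-map positions accumulate
#' exponential gaps with mean `map_density_cm` centimorgans.  This stands in
#' for real array genotypes at desk scale; it reproduces tunable banded LD
#' and a genetic-map coordinate but not human demographic structure.
#'
#' @param n Number of individuals.
#' @param p Number of variants.
#' @param ld_decay AR(1) latent correlation between adjacent variants in
#'   \[0, 1) (default 0.9).
#' @param maf_range Minor-allele-frequency range, a sub-interval of
#'   (0, 0.5\] (default `c(0.05, 0.5)`).
#' @param map_density_cm Mean genetic-map gap between adjacent variants in
#'   centimorgans (default 0.01).
#' @param seed Optional integer seed; output is bit-identical given the
#'   seed.
#' @param chrom Chromosome label (default `"1"`).
#' @return List with `X` (n x p dosage matrix, columns named `v1..vp`),
#'   `positions_cm`, `chrom`, `maf`.
#' @export
simulate_genotypes <- function(n, p, ld_decay = 0.9,
                               maf_range = c(0.05, 0.5),
                               map_density_cm = 0.01, seed = NULL,
                               chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ld_decay >= 0, ld_decay < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (ld_decay > 0 && p > 1) {
    sc <- sqrt(1 - ld_decay^2)
    for (j in 2:p) Z[, j] <- ld_decay * Z[, j - 1] + sc * Z[, j]
  }
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  q0 <- stats::qnorm((1 - maf)^2)
  q1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  X <- (sweep(Z, 2, q0, ">") + sweep(Z, 2, q1, ">")) * 1
  colnames(X) <- paste0("v", seq_len(p))
  positions <- cumsum(stats::rexp(p, rate = 1 / map_density_cm))
  list(X = X, positions_cm = positions, chrom = rep(chrom, p), maf = maf)
}

.scenarios <- c("equal_effects", "mostly_null", "shared_subgroups",
                "low_h2", "high_polygenicity", "more_phenotypes",
                "external_ld", "mcar_missingness")

#' Simulate sparse causal effects under the effect-sharing scenarios
#'
#' Samples `n_causal` causal variants uniformly without replacement and
#' draws their effects according to the scenario:
#' * `equal_effects` (also `low_h2`, `high_polygenicity`,
#'   `more_phenotypes`, `external_ld`, `mcar_missingness`): one standard
#'   normal draw per causal variant, copied across all r phenotypes.
#' * `mostly_null`: draws in phenotype 1 only; all other columns exactly 0.
#' * `shared_subgroups`: per causal variant a fair coin chooses phenotype
#'   group \{1, 2, 3\} or \{4, 5\}; within the active group effects are
#'   drawn correlated but unequal (pairwise correlation `rho_share`), and
#'   are exactly 0 outside it (requires r >= 5).
#' Non-causal rows are exactly zero.  Effect columns are rescaled later by
#' [simulate_phenotypes()] to hit the target heritabilities, so the unit
#' variance here is a convention.
#'
#' @param p Number of variants.
#' @param n_causal Number of causal variants (<= p).
#' @param r Number of phenotypes.
#' @param scenario One of the scenario names above.
#' @param rho_share Within-group effect correlation for
#'   `shared_subgroups` (default 0.8).
#' @param seed Optional seed.
#' @return p x r effect matrix `B_true` with attribute `causal` (indices).
#' @export
simulate_effects <- function(p, n_causal, r, scenario = "equal_effects",
                             rho_share = 0.8, seed = NULL) {
  scenario <- match.arg(scenario, .scenarios)
  if (!is.null(seed)) set.seed(seed)
  if (n_causal > p) stop("'n_causal' must be at most p")
  B <- matrix(0, p, r)
  causal <- sort(sample.int(p, n_causal))
  if (scenario == "mostly_null") {
    B[causal, 1] <- stats::rnorm(n_causal)
  } else if (scenario == "shared_subgroups") {
    if (r < 5) stop("'shared_subgroups' requires r >= 5")
    groups <- list(1:3, 4:5)
    pick <- sample(c(1L, 2L), n_causal, replace = TRUE)
    for (g in 1:2) {
      idx <- causal[pick == g]
      m <- length(groups[[g]])
      if (!length(idx)) next
      C <- matrix(rho_share, m, m); diag(C) <- 1
      E <- matrix(stats::rnorm(length(idx) * m), ncol = m) %*% chol(C)
      B[idx, groups[[g]]] <- E
    }
  } else {
    b <- stats::rnorm(n_causal)
    B[causal, ] <- b  # recycled column-wise: identical effect per phenotype
  }
  colnames(B) <- paste0("pheno", seq_len(r))
  structure(B, causal = causal)
}

#' Simulate phenotypes at exact in-sample heritability
#'
#' Computes genetic values `G = X B`, rescales each effect column so that
#' the in-sample ratio `Var(G_t) / (Var(G_t) + sigma2_e_t)` equals the
#' target heritability exactly, with residual variances
#' `sigma2_e_t = 1 - h2_t` (so each phenotype has theoretical variance 1),
#' and adds multivariate-normal residuals with the given cross-phenotype
#' correlation.  The realized heritability `Var(G_t)/Var(Y_t)` differs from
#' the target only through the sampling variability of the realized
#' residual variance.
#'
#' @param X n x p genotype matrix.
#' @param B p x r effect matrix (e.g. from [simulate_effects()]).
#' @param h2 Target heritabilities, scalar or length-r vector in \[0, 1\].
#' @param residual_cor r x r residual correlation matrix (default
#'   identity).
#' @param seed Optional seed.
#' @return List with `Y` (n x r), `B` (rescaled effects), `G` (genetic
#'   values), `realized_h2`.
#' @export
simulate_phenotypes <- function(X, B, h2, residual_cor = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X); B <- as.matrix(B)
  n <- nrow(X); r <- ncol(B)
  h2 <- rep_len(h2, r)
  if (any(h2 < 0 | h2 > 1)) stop("'h2' entries must lie in [0, 1]")
  G <- X %*% B
  for (t in seq_len(r)) {
    vG <- stats::var(G[, t])
    if (h2[t] == 0) {
      B[, t] <- 0; G[, t] <- 0
    } else {
      if (vG == 0)
        stop("phenotype ", t, " has zero genetic variance but h2 > 0")
      s <- sqrt(h2[t] / vG)
      B[, t] <- B[, t] * s
      G[, t] <- G[, t] * s
    }
  }
  if (is.null(residual_cor)) residual_cor <- diag(r)
  sd_e <- sqrt(1 - h2)
  E <- matrix(stats::rnorm(n * r), n, r) %*% chol(residual_cor)
  E <- sweep(E, 2, sd_e, "*")
  Y <- G + E
  colnames(Y) <- colnames(B)
  realized <- vapply(seq_len(r), function(t) {
    vy <- stats::var(Y[, t])
    if (vy == 0) 0 else stats::var(G[, t]) / vy
  }, numeric(1))
  list(Y = Y, B = B, G = G, realized_h2 = realized)
}

#' Rank-based inverse normal transform
#'
#' Quantile normalization with the Blom offset: maps ranks (average rank
#' for ties) through `qnorm((rank - 3/8) / (n + 1/4))`.  The output is
#' order-isomorphic to the input; phenotypes are transformed this way
#' before the single-variant scan.
#'
#' @param y Numeric vector, length >= 2, not constant.
#' @return Transformed vector.
#' @export
quantile_normalize <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  if (length(unique(y)) == 1L) stop("constant input cannot be quantile normalized")
  stats::qnorm((rank(y, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Single-variant GWAS scan
#'
#' Computes per-variant, per-phenotype summary statistics by simple linear
#' regression with intercept of each phenotype on each variant, one at a
#' time.  Phenotypes may carry missing values: each phenotype is then
#' scanned on its own complete cases, reproducing the robustness setting in
#' which the downstream model's complete-sample-overlap assumption is
#' violated.  The recorded sample size is the mean per-phenotype
#' complete-case count (rounded); with no missingness it is exactly n.
#'
#' @param X n x p complete genotype matrix.
#' @param Y n x r phenotype matrix, possibly with `NA`s.
#' @param quantile_norm Apply [quantile_normalize()] to each phenotype's
#'   observed values before the scan (default `FALSE`).
#' @param positions_cm,chrom Optional variant metadata carried into the
#'   result.
#' @return A [gwas_summary()].
#' @export
gwas_scan <- function(X, Y, quantile_norm = FALSE, positions_cm = NULL,
                      chrom = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X)) stop("'X' must be complete")
  n <- nrow(X); p <- ncol(X); r <- ncol(Y)
  betahat <- se <- matrix(NA_real_, p, r)
  ns <- integer(r)
  complete <- !anyNA(Y)
  if (complete) {
    Xc_all <- scale(X, center = TRUE, scale = FALSE)
    xss_all <- colSums(Xc_all^2)
  }
  for (t in seq_len(r)) {
    obs <- which(!is.na(Y[, t]))
    m <- length(obs)
    if (m < 3L) stop("fewer than 3 complete cases for phenotype ", t)
    ns[t] <- m
    y <- Y[obs, t]
    if (quantile_norm) y <- quantile_normalize(y)
    y <- y - mean(y)
    if (complete) {
      Xc <- Xc_all; xss <- xss_all
    } else {
      Xc <- scale(X[obs, , drop = FALSE], center = TRUE, scale = FALSE)
      xss <- colSums(Xc^2)
    }
    if (any(xss == 0))
      stop("zero-variance variant within complete cases of phenotype ", t,
           ": ", paste(utils::head(which(xss == 0), 5), collapse = ", "))
    b <- drop(crossprod(Xc, y)) / xss
    rss <- sum(y^2) - b^2 * xss
    rss <- pmax(rss, 0)
    betahat[, t] <- b
    se[, t] <- sqrt(rss / ((m - 2) * xss))
  }
  if (any(se == 0)) se[se == 0] <- .Machine$double.xmin  # exact fits
  gwas_summary(betahat, se, n = round(mean(ns)),
               variant_ids = colnames(X),
               phenotype_ids = colnames(Y), chrom = chrom,
               pos_cm = positions_cm)
}

#' Mask phenotypes missing completely at random
#'
#' Selects `floor(frac * n)` individuals and, for each, masks a nonempty
#' subset of their r phenotypes drawn uniformly from the `2^r - 1` nonempty
#' missingness patterns.
#'
#' @param Y n x r phenotype matrix.
#' @param frac Fraction of individuals to receive missing values, in
#'   \[0, 1\].
#' @param seed Optional seed.
#' @return `Y` with `NA`s inserted.
#' @export
mcar_mask <- function(Y, frac, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  stopifnot(frac >= 0, frac <= 1)
  n <- nrow(Y); r <- ncol(Y)
  m <- floor(frac * n)
  if (m == 0) return(Y)
  who <- sample.int(n, m)
  pats <- sample.int(2^r - 1L, m, replace = TRUE)
  for (i in seq_len(m)) {
    bits <- as.logical(bitwAnd(pats[i], bitwShiftL(1L, 0:(r - 1L))))
    Y[who[i], bits] <- NA
  }
  Y
}

#' LD matrix from reference genotypes
#'
#' Computes the Pearson correlation matrix of the genotype columns and
#' optionally imposes a banded or block-diagonal structure.  Passing a
#' small, differently generated reference panel (e.g. 503 individuals drawn
#' with a perturbed `ld_decay`) emulates external reference-panel LD and
#' its mismatch with the GWAS sample.
#'
#' @param X_ref n_ref x p complete genotype matrix.
#' @param positions_cm,chrom Variant metadata.
#' @param structure Optional [ld_banded()] / [ld_block_diagonal()]
#'   descriptor.
#' @return An [ld_matrix()].
#' @export
compute_ld <- function(X_ref, positions_cm = NULL, chrom = NULL,
                       structure = NULL) {
  X_ref <- as.matrix(X_ref)
  if (anyNA(X_ref)) stop("'X_ref' must be complete")
  sds <- apply(X_ref, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s) in 'X_ref': ",
         paste(utils::head(which(sds == 0), 5), collapse = ", "))
  R <- stats::cor(X_ref)
  ld_matrix(R, positions_cm = positions_cm, chrom = chrom,
            variant_ids = colnames(X_ref), structure = structure)
}

#' Simulate a full scenario at desk scale
#'
#' Generates a complete synthetic study under one of the effect-sharing
#' scenarios: LD-structured genotypes for training and test individuals
#' (drawn jointly so they share variants, frequencies and map), sparse
#' causal effects, and phenotypes at the scenario's target heritabilities.
#' Scenario presets (overridable):
#' * `equal_effects`: r = 5, h2 = 0.5 for every phenotype.
#' * `mostly_null`: r = 5, h2 = (0.5, 0, 0, 0, 0).
#' * `shared_subgroups`: r = 5, h2 = (0.3, 0.3, 0.3, 0.5, 0.5).
#' * `low_h2`: equal effects with h2 = 0.2.
#' * `high_polygenicity`: equal effects with 10x the causal variants.
#' * `more_phenotypes`: equal effects with r = 10.
#' * `external_ld`: equal effects; pair with an external reference panel
#'   via [compute_ld()].
#' * `mcar_missingness`: equal effects; `mcar_frac` of training individuals
#'   get missing phenotype values ([mcar_mask()]).
#'
#' Default sizes are scaled down from biobank scale, keeping the causal
#' fraction's order of magnitude: 2,000 training individuals, 2,000
#' variants, 50 causal variants.
#'
#' @param scenario Scenario name.
#' @param n_train,n_test Training and test sample sizes (`n_test = 0`
#'   skips the test set).
#' @param p Number of variants.
#' @param n_causal Number of causal variants (scenario preset for
#'   `high_polygenicity`).
#' @param r Number of phenotypes (scenario presets may override).
#' @param h2 Target heritabilities (scenario preset when `NULL`).
#' @param residual_cor Residual correlation across phenotypes (identity
#'   default).
#' @param rho_share Within-group effect correlation for
#'   `shared_subgroups`.
#' @param mcar_frac Missingness fraction for `mcar_missingness`
#'   (default 0.2).
#' @param ld_decay,maf_range,map_density_cm Genotype generator settings.
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @return List of class `"mrmash_sim"`: `X_train`, `X_test`, `Y_train`,
#'   `Y_test`, `B_true`, `positions_cm`, `chrom`, `realized_h2`, `h2`,
#'   `causal`, `scenario`, plus `Y_train_missing` for `mcar_missingness`.
#' @export
simulate_scenario <- function(scenario = "equal_effects", n_train = 2000,
                              n_test = 1000, p = 2000, n_causal = 50,
                              r = NULL, h2 = NULL, residual_cor = NULL,
                              rho_share = 0.8, mcar_frac = 0.2,
                              ld_decay = 0.9, maf_range = c(0.05, 0.5),
                              map_density_cm = 0.01, seed = NULL) {
  scenario <- match.arg(scenario, .scenarios)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(r)) r <- if (scenario == "more_phenotypes") 10L else 5L
  if (scenario == "high_polygenicity" && missing(n_causal))
    n_causal <- min(p, 10L * n_causal)
  if (is.null(h2)) {
    h2 <- switch(scenario,
                 mostly_null = c(0.5, rep(0, r - 1)),
                 shared_subgroups = c(0.3, 0.3, 0.3, rep(0.5, r - 3)),
                 low_h2 = rep(0.2, r),
                 rep(0.5, r))
  }
  h2 <- rep_len(h2, r)
  geno <- simulate_genotypes(n_train + n_test, p, ld_decay = ld_decay,
                             maf_range = maf_range,
                             map_density_cm = map_density_cm)
  B <- simulate_effects(p, n_causal, r, scenario = scenario,
                        rho_share = rho_share)
  train <- seq_len(n_train)
  Xtr <- geno$X[train, , drop = FALSE]
  # scale effects on the training sample, then phenotype everyone with the
  # same effect sizes and residual model
  ph_tr <- simulate_phenotypes(Xtr, B, h2, residual_cor = residual_cor)
  out <- list(X_train = Xtr, Y_train = ph_tr$Y, B_true = ph_tr$B,
              positions_cm = geno$positions_cm, chrom = geno$chrom,
              realized_h2 = ph_tr$realized_h2, h2 = h2,
              causal = attr(B, "causal"), scenario = scenario,
              maf = geno$maf)
  if (n_test > 0) {
    Xte <- geno$X[-train, , drop = FALSE]
    Gte <- Xte %*% ph_tr$B
    if (is.null(residual_cor)) residual_cor <- diag(r)
    Ete <- matrix(stats::rnorm(n_test * r), n_test, r) %*% chol(residual_cor)
    Ete <- sweep(Ete, 2, sqrt(1 - h2), "*")
    out$X_test <- Xte
    out$Y_test <- Gte + Ete
    colnames(out$Y_test) <- colnames(ph_tr$Y)
  }
  if (scenario == "mcar_missingness")
    out$Y_train_missing <- mcar_mask(out$Y_train, mcar_frac)
  class(out) <- "mrmash_sim"
  out
}

#' @export
print.mrmash_sim <- function(x, ...) {
  cat("Simulated scenario '", x$scenario, "': n_train = ",
      nrow(x$X_train), ", p = ", ncol(x$X_train), ", r = ",
      ncol(x$Y_train), ", causal = ", length(x$causal), "\n", sep = "")
  cat("  realized h2:", paste(round(x$realized_h2, 3), collapse = ", "), "\n")
  invisible(x)
}
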