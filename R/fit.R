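#' Control parameters for the variational fit
#'
#' @param tol Relative evidence-lower-bound (ELBO) change at which the
#'   coordinate ascent stops (default 1e-6).
#' @param max_iter Maximum number of sweeps (default 500).
#' @param update_w0 Update the mixture weights by empirical Bayes
#'   (default `TRUE`).
#' @param w0_max_updates Restrict weight updates to the first this many
#'   sweeps (default `Inf`, i.e. unconstrained; the mash-initialized
#'   strategy for dense architectures uses 10).
#' @param update_V Update the residual covariance V (default: `TRUE` when
#'   Y'Y is available, else `FALSE`).  Requires Y'Y.
#' @param update_order `"fixed"` (ascending variant order, default) or
#'   `"shuffled"` (a fresh permutation each sweep, driven by `seed`).
#' @param seed Seed for the shuffled update order.
#' @return A list of class `"mr_mash_control"`.
#' @export
mr_mash_control <- function(tol = 1e-6, max_iter = 500, update_w0 = TRUE,
                            w0_max_updates = Inf, update_V = NULL,
                            update_order = c("fixed", "shuffled"),
                            seed = NULL) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0)
  max_iter <- as.integer(max_iter)
  stopifnot(max_iter >= 1L)
  structure(list(tol = tol, max_iter = max_iter,
                 update_w0 = isTRUE(update_w0),
                 w0_max_updates = w0_max_updates,
                 update_V = update_V,
                 update_order = match.arg(update_order), seed = seed),
            class = "mr_mash_control")
}

#' Fit the multivariate summary-statistics regression
#'
#' Fits the multivariate multiple regression \eqn{Y = XB + E},
#' \eqn{E ~ MN(0, I_n, V)}, with the mixture-of-multivariate-normals prior
#' on the rows of B, by coordinate-ascent variational inference on the
#' sufficient statistics (X'X, X'Y, Y'Y), maximizing the evidence lower
#' bound (ELBO).  The mixture weights (and, when Y'Y is available, the
#' residual covariance V) are estimated by empirical Bayes as part of the
#' same objective.
#'
#' Data can be given as (a) a [suff_stats()] object, (b) a
#' [gwas_summary()] plus [ld_matrix()] (sufficient statistics are recovered
#' via [recover_suffstats()]; exact for X'Y, approximate for X'X when the LD
#' comes from a reference panel), or (c) individual-level `X`, `Y` matrices
#' (via [compute_suffstats()]).  Fitting from summary statistics with
#' in-sample LD reproduces the individual-level fit.
#'
#' Genomes are conventionally fitted one chromosome (one LD block-set) at a
#' time; predictions from per-chromosome fits add (see [pgs_score()]).
#'
#' @param data A [suff_stats()], [gwas_summary()], or n x p genotype matrix.
#' @param ld An [ld_matrix()] (required when `data` is a `gwas_summary`).
#' @param Y n x r phenotype matrix (required when `data` is a genotype
#'   matrix).
#' @param prior A [mixture_prior()]; when missing, a canonical prior
#'   expanded over [default_scale_grid()] is built (summary-data path only).
#' @param V_init Initial residual covariance (r x r positive definite).
#'   Default: `YtY/n` when Y'Y is present, else a diagonal plug-in
#'   (see Details in the package vignette), falling back to the identity.
#' @param control A [mr_mash_control()] list.
#' @param ... Passed to [recover_suffstats()] / [compute_suffstats()] on the
#'   respective input paths.
#' @return An object of class `"mr_mash_rss"` with components
#'   `coefficients` (posterior mean effects, p x r), `gamma` (p x K
#'   responsibilities), `w0` (fitted weights), `V` (fitted or fixed residual
#'   covariance), `var_part` (the accumulated posterior-variance term
#'   `sum_j d_j (M2_j - b_j b_j')`, kept as an r x r running sum rather than
#'   p per-variant second-moment matrices to bound memory at biobank p),
#'   `elbo` (per-sweep ELBO trace, nondecreasing), `converged`, `n_iter`,
#'   `prior`, and metadata.
#' @export
mr_mash_rss <- function(data, ld = NULL, Y = NULL, prior = NULL,
                        V_init = NULL, control = mr_mash_control(), ...) {
  cl <- match.call()
  if (inherits(data, "gwas_summary")) {
    if (is.null(ld)) stop("summary-data fitting requires 'ld'")
    if (is.null(prior))
      prior <- mixture_prior(
        scale_expand(canonical_covs(ncol(data$betahat)),
                     default_scale_grid(data)))
    ss <- recover_suffstats(data, ld, ...)
  } else if (inherits(data, "suff_stats")) {
    ss <- data
  } else if (is.matrix(data) || is.data.frame(data)) {
    if (is.null(Y)) stop("individual-level fitting requires 'Y'")
    ss <- compute_suffstats(as.matrix(data), as.matrix(Y), ...)
  } else stop("'data' must be a suff_stats, gwas_summary, or genotype matrix")
  if (is.null(prior)) stop("'prior' is required on this input path")
  stopifnot(inherits(prior, "mixture_prior"),
            inherits(control, "mr_mash_control"))
  p <- nrow(ss$XtX); r <- ncol(ss$XtY)
  if (prior$r != r)
    stop("prior dimension (", prior$r, ") does not match data (", r, ")")
  has_yty <- !is.null(ss$YtY)
  update_V <- control$update_V
  if (is.null(update_V)) update_V <- has_yty
  if (update_V && !has_yty)
    stop("estimating V requires Y'Y; supply it or fit with V fixed ",
         "(control = mr_mash_control(update_V = FALSE))")
  if (is.null(V_init)) {
    V_init <- if (has_yty) ss$YtY / ss$n else .default_V(ss)
  }
  V_init <- as.matrix(V_init)
  if (nrow(V_init) != r || ncol(V_init) != r)
    stop("'V_init' must be r x r")
  if (min(eigen(V_init, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("'V_init' must be positive definite")

  S0 <- array(unlist(prior$S0), dim = c(r, r, prior$K))
  if (control$update_order == "shuffled") {
    if (!is.null(control$seed)) set.seed(control$seed)
    orders <- t(vapply(seq_len(control$max_iter),
                       function(i) sample.int(p) - 1L, integer(p)))
  } else {
    orders <- matrix(seq_len(p) - 1L, nrow = 1)
  }
  w0max <- if (is.finite(control$w0_max_updates))
    as.integer(control$w0_max_updates) else control$max_iter
  res <- mrmash_rss_core(ss$XtX, ss$XtY, ss$d, S0, prior$w0, V_init,
                         if (has_yty) ss$YtY else matrix(0, r, r), has_yty,
                         ss$n, matrix(0, p, r), orders,
                         control$tol, control$max_iter,
                         control$update_w0, w0max, update_V, 1e-8)
  if (nzchar(res$error))
    stop("fit failed at sweep ", res$n_iter, ": ", res$error,
         " (last ELBO ", format(utils::tail(res$elbo, 1)), ")")
  B <- res$B_bar
  dimnames(B) <- list(ss$variant_ids, ss$phenotype_ids)
  structure(list(coefficients = B, gamma = res$gamma,
                 w0 = as.numeric(res$w0), V = res$V,
                 var_part = res$var_part,  # sum_j d_j (M2_j - b_j b_j')
                 elbo = as.numeric(res$elbo), converged = res$converged,
                 n_iter = res$n_iter, prior = prior, d = ss$d, n = ss$n,
                 yty_used = has_yty, update_V = update_V,
                 w0_max_updates = control$w0_max_updates,
                 approximate_XtX = isTRUE(ss$approximate_XtX),
                 variant_ids = ss$variant_ids,
                 phenotype_ids = ss$phenotype_ids, call = cl),
            class = "mr_mash_rss")
}

# Plug-in residual variance when Y'Y is unavailable, under the
# variance-standardized phenotype convention: per phenotype 1 - h2hat with
# the LD-score-corrected chi-square heritability estimate
# h2hat = p (mean z^2 - 1) / (n lbar), lbar the mean LD score computed from
# X'X (E[z^2] ~ 1 + n h2 l_j / p for standardized variants in LD), clipped
# to [0, 0.9]; identity fallback when degenerate.
.default_V <- function(ss) {
  r <- ncol(ss$XtY); p <- nrow(ss$XtX); n <- ss$n
  z2 <- (ss$XtY / sqrt(ss$d))^2 * (n - 2) / (n - 1)
  lbar <- mean(rowSums((ss$XtX / tcrossprod(sqrt(ss$d)))^2))
  h2 <- p * (colMeans(z2) - 1) / (n * lbar)
  if (any(!is.finite(h2))) return(diag(r))
  h2 <- pmin(pmax(h2, 0), 0.9)
  diag(1 - h2, nrow = r)
}

#' @export
print.mr_mash_rss <- function(x, ...) {
  cat("Multivariate summary-statistics regression fit\n")
  cat("  p =", nrow(x$coefficients), "variants, r =", ncol(x$coefficients),
      "phenotypes, K =", x$prior$K, "prior components\n")
  cat("  ", x$n_iter, " sweeps, ",
      if (x$converged) "converged" else "NOT converged",
      "; final ELBO ", format(utils::tail(x$elbo, 1)), "\n", sep = "")
  cat("  fitted null weight:", format(x$w0[1], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.mr_mash_rss <- function(object, ...) {
  B <- object$coefficients
  out <- list(
    dims = c(p = nrow(B), r = ncol(B), K = object$prior$K),
    n_iter = object$n_iter, converged = object$converged,
    elbo = utils::tail(object$elbo, 1),
    w0_top = sort(stats::setNames(object$w0, object$prior$labels),
                  decreasing = TRUE)[seq_len(min(8, object$prior$K))],
    V = object$V,
    prop_nonnull = mean(1 - object$gamma[, 1]),
    effect_scale = apply(B, 2, function(b) sqrt(mean(b^2))))
  class(out) <- "summary.mr_mash_rss"
  out
}

#' @export
print.summary.mr_mash_rss <- function(x, ...) {
  cat("Fit of", x$dims["p"], "variants x", x$dims["r"], "phenotypes with",
      x$dims["K"], "prior components\n")
  cat("Sweeps:", x$n_iter, "| converged:", x$converged,
      "| ELBO:", format(x$elbo), "\n")
  cat("Mean non-null responsibility:", format(x$prop_nonnull, digits = 3), "\n")
  cat("Largest mixture weights:\n")
  print(round(x$w0_top, 4))
  cat("Residual covariance V:\n")
  print(round(x$V, 4))
  invisible(x)
}

#' @export
coef.mr_mash_rss <- function(object, ...) object$coefficients

#' Polygenic scores from a fitted model
#'
#' Computes linear predictions (polygenic scores) `X_new %*% B` for test
#' individuals.  Column alignment is verified via variant ids when `X_new`
#' has column names.
#'
#' @param object A fitted [mr_mash_rss()] model.
#' @param newdata n_test x p genotype matrix.
#' @param ... Unused.
#' @return n_test x r matrix of scores.
#' @export
predict.mr_mash_rss <- function(object, newdata, ...) {
  pgs_score(newdata, object)
}

#' @export
plot.mr_mash_rss <- function(x, ...) {
  graphics::plot(seq_along(x$elbo), x$elbo, type = "b", pch = 20,
                 xlab = "sweep", ylab = "ELBO",
                 main = "Evidence lower bound trace", ...)
  invisible(x)
}

#' Single-variant mixture posterior
#'
#' The per-variant conjugate update at the heart of the coordinate ascent:
#' given the residualized single-variant estimate \eqn{\hat b_j ~ N(b_j,
#' V/d_j)} and the mixture prior, returns per-component posteriors
#' \eqn{\Sigma_{1k} = S_{0k}(S_{0k} + V/d_j)^{-1}(V/d_j)},
#' \eqn{\mu_{1k} = S_{0k}(S_{0k} + V/d_j)^{-1}\hat b_j}, responsibilities
#' \eqn{\gamma_k \propto w_{0k} N(\hat b_j; 0, S_{0k} + V/d_j)} (normalized
#' in log space), and the mixture posterior mean and second moment.
#'
#' @param bhat Length-r residualized estimate.
#' @param d Positive scalar diagonal cross-product \eqn{d_j}.
#' @param V r x r positive-definite residual covariance.
#' @param prior A [mixture_prior()].
#' @return List with `gamma` (K), `mu1` (r x K), `Sigma1` (r x r x K),
#'   `b_bar` (r), `M2` (r x r), `log_marginal`.
#' @export
mixture_posterior <- function(bhat, d, V, prior) {
  stopifnot(inherits(prior, "mixture_prior"), d > 0)
  r <- prior$r
  S0 <- array(unlist(prior$S0), dim = c(r, r, prior$K))
  mix_posterior_cpp(as.numeric(bhat), d, as.matrix(V), prior$w0, S0)
}

#' Empirical-Bayes update of the mixture weights
#'
#' The closed-form M-step maximizing the weight term of the ELBO:
#' `w0_k = mean_j gamma_jk`.
#'
#' @param gamma p x K responsibility matrix (rows on the simplex).
#' @return Length-K weight vector on the simplex.
#' @export
update_w0 <- function(gamma) {
  gamma <- as.matrix(gamma)
  w <- colMeans(gamma)
  w / sum(w)
}

#' Empirical-Bayes update of the residual covariance
#'
#' The M-step maximizing the likelihood term of the ELBO:
#' \eqn{V = E_q[(Y - XB)'(Y - XB)]/n}, expanded in sufficient statistics as
#' `(YtY - XtY'B - B'XtY + B'XtX B + var_part)/n` where
#' `var_part = sum_j d_j (M2_j - b_j b_j')` collects the posterior
#' variances.  The result is symmetrized and eigenvalue-floored.
#'
#' @param ss A [suff_stats()] with Y'Y present.
#' @param B_bar p x r posterior mean effects.
#' @param var_part r x r accumulated posterior-variance term.
#' @param eig_floor Eigenvalue floor (default 1e-8).
#' @return Symmetric positive-definite r x r matrix.
#' @export
update_V <- function(ss, B_bar, var_part, eig_floor = 1e-8) {
  if (is.null(ss$YtY))
    stop("estimating V requires Y'Y; fit with V fixed instead")
  XtYtB <- crossprod(ss$XtY, B_bar)
  ERSS <- ss$YtY - XtYtB - t(XtYtB) + crossprod(B_bar, ss$XtX %*% B_bar) +
    var_part
  V <- (ERSS + t(ERSS)) / (2 * ss$n)
  .psd_project(V, floor = eig_floor)
}

#' Evidence lower bound at a variational state
#'
#' Evaluates the ELBO as a function of the current state (posterior mean
#' effects and the implied per-variant local posteriors), independent of
#' the update path: per variant the residualized estimate is recomputed
#' from `B_bar` and the exact local mixture posterior at that estimate is
#' used.  At a coordinate-ascent fixed point this equals the fitter's
#' internal trace value; in the single-variant conjugate case it equals the
#' exact log marginal likelihood.  Without Y'Y the value is reported up to
#' an additive constant (the `-tr(V^{-1} Y'Y)/2` term is dropped).
#'
#' @param ss A [suff_stats()].
#' @param B_bar p x r posterior mean effects.
#' @param prior A [mixture_prior()].
#' @param V r x r residual covariance.
#' @return Scalar ELBO value.
#' @export
compute_elbo <- function(ss, B_bar, prior, V) {
  stopifnot(inherits(ss, "suff_stats"), inherits(prior, "mixture_prior"))
  p <- nrow(ss$XtX); r <- ncol(ss$XtY); n <- ss$n
  B_bar <- as.matrix(B_bar)
  V <- as.matrix(V)
  Vinv <- solve(V)
  ldetV <- determinant(V, logarithm = TRUE)$modulus
  S0 <- array(unlist(prior$S0), dim = c(r, r, prior$K))
  Tm <- ss$XtY - ss$XtX %*% B_bar
  neg_kl <- 0
  var_part <- matrix(0, r, r)
  Bq <- B_bar
  for (j in seq_len(p)) {
    bhat <- (Tm[j, ] + ss$d[j] * B_bar[j, ]) / ss$d[j]
    up <- mix_posterior_cpp(bhat, ss$d[j], V, prior$w0, S0)
    Cov <- up$M2 - tcrossprod(up$b_bar)
    var_part <- var_part + ss$d[j] * Cov
    resid <- bhat - up$b_bar
    neg_kl <- neg_kl + up$log_marginal +
      0.5 * (r * log(2 * pi) + ldetV - r * log(ss$d[j])) +
      0.5 * ss$d[j] * (drop(crossprod(resid, Vinv %*% resid)) +
                         sum(Vinv * Cov))
    Bq[j, ] <- up$b_bar
  }
  XtYtB <- crossprod(ss$XtY, Bq)
  ERSS <- -XtYtB - t(XtYtB) + crossprod(Bq, ss$XtX %*% Bq) + var_part
  if (!is.null(ss$YtY)) ERSS <- ERSS + ss$YtY
  val <- -0.5 * n * r * log(2 * pi) - 0.5 * n * ldetV -
    0.5 * sum(Vinv * ERSS) + neg_kl
  if (!is.finite(val)) stop("non-finite ELBO")
  as.numeric(val)
}
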