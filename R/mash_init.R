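#' Greedy LD pruning
#'
#' Scans variants in priority order and retains a variant iff its squared
#' correlation with every previously retained variant is at most
#' `r2_threshold`, yielding a semi-independent subset.  Deterministic given
#' its inputs.
#'
#' @param ld An [ld_matrix()] (or plain correlation matrix).
#' @param r2_threshold Squared-correlation threshold in (0, 1] (default
#'   0.1).
#' @param z Optional p x r z-score matrix; when given, variants are visited
#'   in decreasing max |z| (so the strongest signals are kept), otherwise in
#'   position order.
#' @return Integer vector of retained variant indices (in retention order),
#'   with attribute `r2_threshold`.
#' @export
ld_prune <- function(ld, r2_threshold = 0.1, z = NULL) {
  R <- if (inherits(ld, "ld_matrix")) ld$R else as.matrix(ld)
  p <- nrow(R)
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("'r2_threshold' must be in (0, 1]")
  ord <- if (is.null(z)) seq_len(p) else
    order(apply(abs(as.matrix(z)), 1, max), decreasing = TRUE)
  keep <- integer(0)
  for (j in ord) {
    if (!length(keep) || all(R[j, keep]^2 <= r2_threshold))
      keep <- c(keep, j)
  }
  structure(keep, r2_threshold = r2_threshold)
}

#' Mixture weights from approximately independent summary statistics
#'
#' Estimates the mixture weights of a fixed set of prior covariance
#' components by maximum likelihood on (approximately) independent strong
#' signals, ignoring LD: maximizes
#' \eqn{\sum_j \log \sum_k w_k N(\hat b_j; 0, S_{0k} + \hat S_j)} over the
#' simplex with \eqn{\hat S_j = diag(se_j^2)}, by EM on the weights.  This
#' is the adaptive-shrinkage weight-estimation step used to initialize the
#' full LD-aware fit for dense architectures.
#'
#' @param bhat,se m x r effect-size and standard-error matrices for the
#'   pruned strong signals.
#' @param S0 List of r x r prior covariance components (null first), or a
#'   [mixture_prior()].
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Relative objective-change tolerance (default 1e-10).
#' @return Weight vector on the simplex, with attributes `objective`
#'   (per-iteration log-likelihood trace, nondecreasing) and `converged`
#'   (a warning is issued when the EM hits `max_iter`).
#' @export
fit_mash_weights <- function(bhat, se, S0, max_iter = 1000, tol = 1e-10) {
  if (inherits(S0, "mixture_prior")) S0 <- S0$S0
  bhat <- as.matrix(bhat); se <- as.matrix(se)
  stopifnot(all(dim(bhat) == dim(se)), all(se > 0))
  r <- ncol(bhat); K <- length(S0)
  S0a <- array(unlist(lapply(S0, as.matrix)), dim = c(r, r, K))
  L <- mix_loglik_cpp(bhat, se, S0a)
  if (K == 1L)
    return(structure(1, objective = sum(L), converged = TRUE))
  w <- rep(1 / K, K)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- sweep(L, 2, log(w), "+")
    mx <- apply(lg, 1, max)
    lse <- mx + log(rowSums(exp(lg - mx)))
    obj <- c(obj, sum(lse))
    gamma <- exp(lg - lse)
    w <- colMeans(gamma)
    w <- w / sum(w)
    if (it > 1 && abs(obj[it] - obj[it - 1]) <
        tol * max(1, abs(obj[it]))) { converged <- TRUE; break }
  }
  if (!converged)
    warning("weight EM did not converge in ", max_iter,
            " iterations; returning current weights")
  structure(w, objective = obj, converged = converged)
}

#' Rescale mixture weights to a fixed null weight
#'
#' Sets the weight of the null component (index 1) to `null_weight` and
#' rescales the remaining weights proportionally so the result stays on the
#' simplex.  Used after the LD-free weight fit, which underestimates the
#' null weight when run on a small pruned subset of variants.
#'
#' @param w Weight vector on the simplex, null component first.
#' @param null_weight Target null weight in (0, 1) (default 0.5).
#' @return Rescaled weight vector.
#' @export
rescale_null <- function(w, null_weight = 0.5) {
  w <- as.numeric(w)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("'w' must be on the simplex")
  if (null_weight <= 0 || null_weight >= 1)
    stop("'null_weight' must be in (0, 1)")
  rest <- sum(w[-1])
  if (rest <= 0) stop("all non-null weights are zero; cannot rescale")
  c(null_weight, (1 - null_weight) * w[-1] / rest)
}

#' Mash-style weight initialization for dense architectures
#'
#' The two-step initialization that guards the empirical-Bayes fit against
#' over-shrinkage on highly polygenic traits: (1) LD-prune to a
#' semi-independent variant subset; (2) estimate the mixture weights on that
#' subset ignoring LD ([fit_mash_weights()]); (3) reset the null weight to
#' `null_weight` and rescale the rest ([rescale_null()]).  The returned
#' prior is then passed to [mr_mash_rss()] with
#' `control = mr_mash_control(w0_max_updates = 10)` so the weights stay
#' adaptive only for the first sweeps.
#'
#' @param gwas A [gwas_summary()].
#' @param ld An [ld_matrix()] aligned with `gwas`.
#' @param prior A [mixture_prior()] whose weights are to be initialized.
#' @param r2_threshold LD-pruning threshold (default 0.1).
#' @param null_weight Rescaled null weight (default 0.5).
#' @return The prior with initialized weights; attribute `pruned` holds the
#'   retained variant indices.
#' @export
mash_init_weights <- function(gwas, ld, prior, r2_threshold = 0.1,
                              null_weight = 0.5) {
  stopifnot(inherits(gwas, "gwas_summary"), inherits(prior, "mixture_prior"))
  z <- gwas$betahat / gwas$se
  keep <- ld_prune(ld, r2_threshold = r2_threshold, z = z)
  w <- fit_mash_weights(gwas$betahat[keep, , drop = FALSE],
                        gwas$se[keep, , drop = FALSE], prior$S0)
  w <- rescale_null(as.numeric(w), null_weight)
  out <- mixture_prior(prior$S0, w0 = w, labels = prior$labels)
  attr(out, "pruned") <- as.integer(keep)
  out
}
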