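#' Mixture-of-multivariate-normals prior on effect sizes
#'
#' The effects of each variant across the r phenotypes are modelled as
#' exchangeable draws from a K-component mixture of r-variate normals,
#' \eqn{b_j ~ \sum_k w_{0k} N_r(0, S_{0k})}.  The covariance components
#' encode patterns of effect sharing across phenotypes (null, independent,
#' equal, phenotype-specific, data-driven, ...), each usually crossed with a
#' grid of scales; the weights are adapted to the data by empirical Bayes.
#'
#' The first component must be the null component (zero matrix); every
#' component must be symmetric positive semidefinite; components equal
#' within tolerance 1e-12 are deduplicated (keeping the first label and
#' summing any supplied weights).
#'
#' @param S0 List of r x r symmetric PSD matrices; `S0[[1]]` must be the
#'   zero matrix.
#' @param w0 Optional weight vector on the simplex (default uniform).
#' @param labels Optional component labels; the first must be `"null"`.
#' @return An object of class `"mixture_prior"` with elements `S0`, `w0`,
#'   `labels`, `r`, `K`.
#' @export
mixture_prior <- function(S0, w0 = NULL, labels = NULL) {
  if (!is.list(S0) || !length(S0)) stop("'S0' must be a non-empty list")
  S0 <- lapply(S0, as.matrix)
  r <- nrow(S0[[1]])
  for (k in seq_along(S0)) {
    M <- S0[[k]]
    if (nrow(M) != r || ncol(M) != r) stop("all components must be r x r")
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
      stop("component ", k, " is not symmetric")
    S0[[k]] <- (M + t(M)) / 2
    ev <- min(eigen(S0[[k]], symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10 * max(1, max(abs(M))))
      stop("component ", k, " is not positive semidefinite (min eigenvalue ",
           format(ev), ")")
  }
  if (max(abs(S0[[1]])) != 0)
    stop("the first component must be the null (all-zero) matrix")
  K0 <- length(S0)
  if (is.null(labels)) {
    labels <- "null"
    if (K0 > 1L) labels <- c(labels, paste0("comp_", seq_len(K0 - 1L)))
  }
  labels <- as.character(labels)
  if (length(labels) != K0) stop("'labels' must have one entry per component")
  labels[1] <- "null"
  if (is.null(w0)) w0 <- rep(1 / K0, K0)
  w0 <- as.numeric(w0)
  if (length(w0) != K0 || any(w0 < 0) || abs(sum(w0) - 1) > 1e-12)
    stop("'w0' must be nonnegative and sum to 1 (|sum - 1| < 1e-12)")
  dd <- .dedupe_covs(S0, w0, labels)
  structure(list(S0 = dd$S0, w0 = dd$w0 / sum(dd$w0), labels = dd$labels,
                 r = r, K = length(dd$S0)),
            class = "mixture_prior")
}

.dedupe_covs <- function(S0, w0, labels, tol = 1e-12) {
  keep <- integer(0)
  wout <- numeric(0)
  for (k in seq_along(S0)) {
    dup <- 0L
    for (i in keep) {
      if (max(abs(S0[[k]] - S0[[i]])) <= tol) { dup <- i; break }
    }
    if (dup == 0L) {
      keep <- c(keep, k)
      wout <- c(wout, w0[k])
    } else {
      wout[match(dup, keep)] <- wout[match(dup, keep)] + w0[k]
    }
  }
  list(S0 = S0[keep], w0 = wout, labels = labels[keep])
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat("Mixture prior: K =", x$K, "components on r =", x$r, "phenotypes\n")
  cat("  null weight:", format(x$w0[1], digits = 4), "\n")
  top <- order(x$w0, decreasing = TRUE)[seq_len(min(5, x$K))]
  cat("  top components:",
      paste0(x$labels[top], " (", format(x$w0[top], digits = 3), ")",
             collapse = ", "), "\n")
  invisible(x)
}

#' Canonical prior covariance components
#'
#' Builds the unscaled canonical covariance patterns used in multivariate
#' adaptive shrinkage: the identity (independent effects across phenotypes),
#' one singleton matrix per phenotype (effect in that phenotype only), the
#' all-ones matrix (equal effects), and heterogeneous-sharing matrices with
#' unit diagonal and constant off-diagonal correlation from `rho`.
#' Components that coincide (e.g. everything at r = 1) are deduplicated.
#'
#' @param r Number of phenotypes (>= 1).
#' @param rho Off-diagonal correlations for the heterogeneous-sharing
#'   family (default `c(0.25, 0.5, 0.75)`); use `numeric(0)` to omit.
#' @param singletons Include per-phenotype singleton matrices?
#' @return A named list of r x r matrices.
#' @export
canonical_covs <- function(r, rho = c(0.25, 0.5, 0.75), singletons = TRUE) {
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("'r' must be a positive integer")
  covs <- list(identity = diag(r))
  if (singletons) {
    for (t in seq_len(r)) {
      M <- matrix(0, r, r); M[t, t] <- 1
      covs[[paste0("singleton_", t)]] <- M
    }
  }
  covs[["shared_equal"]] <- matrix(1, r, r)
  for (rr in rho) {
    if (rr <= 0 || rr >= 1) stop("'rho' values must be in (0, 1)")
    M <- matrix(rr, r, r); diag(M) <- 1
    covs[[paste0("shared_het_", format(rr))]] <- M
  }
  dd <- .dedupe_covs(covs, rep(1, length(covs)), names(covs))
  stats::setNames(dd$S0, dd$labels)
}

#' Expand covariance components over a scale grid
#'
#' Forms the Cartesian product of covariance patterns with a grid of
#' variance scales and prepends the null (zero) component, giving
#' `K = 1 + length(covs) * length(scale_grid)` components before
#' deduplication.
#'
#' @param covs Named list of r x r PSD matrices.
#' @param scale_grid Strictly positive, strictly increasing variance scales.
#' @return A named list of matrices: `null` first, then `sigma2 * C` for
#'   every combination.
#' @export
scale_expand <- function(covs, scale_grid) {
  if (!length(scale_grid)) stop("'scale_grid' must be non-empty")
  scale_grid <- as.numeric(scale_grid)
  if (any(scale_grid <= 0) || is.unsorted(scale_grid, strictly = TRUE))
    stop("'scale_grid' must be strictly positive and strictly increasing")
  if (!is.list(covs)) covs <- list(cov = covs)
  if (is.null(names(covs))) names(covs) <- paste0("cov_", seq_along(covs))
  r <- nrow(covs[[1]])
  out <- list(null = matrix(0, r, r))
  for (i in seq_along(covs))
    for (s in scale_grid)
      out[[paste0(names(covs)[i], "_s", format(s, digits = 6))]] <-
        s * covs[[i]]
  out
}

#' Default variance scale grid from summary statistics
#'
#' A logarithmically spaced grid of effect-variance scales auto-ranged from
#' the data, spanning roughly from well below the smallest standard error
#' (effects indistinguishable from zero) up to the largest squared effect
#' size.
#'
#' @param betahat,se Effect size and standard error matrices (or a
#'   [gwas_summary()] as `betahat`).
#' @param length Grid length (default 20).
#' @return Numeric vector of strictly increasing variance scales.
#' @export
default_scale_grid <- function(betahat, se = NULL, length = 20) {
  if (inherits(betahat, "gwas_summary")) {
    se <- betahat$se; betahat <- betahat$betahat
  }
  lo <- (min(se) / 10)^2
  hi <- max(betahat^2, lo * 100)
  exp(seq(log(lo), log(hi), length.out = length))
}

#' Data-driven prior covariance components from strong signals
#'
#' Estimates candidate effect-sharing covariance matrices from the z-scores
#' of strong, approximately independent signals (selected upstream, e.g. by
#' [ld_prune()] plus a |z| threshold).  Candidates come from (a) the top
#' rank-1 principal-component matrices of the noise-corrected second moment
#' `Z'Z/m - I`, clipped to PSD, and (b) those candidates refined by a fixed
#' number of extreme-deconvolution EM iterations under the model
#' \eqn{z_j ~ N(0, U + I)}, with symmetrization and PSD projection at each
#' step.
#'
#' @param Z m x r matrix of z-scores for m strong signals (m >= r).
#' @param n_components Number of leading principal components to turn into
#'   rank-1 candidates (default `min(3, r)`).
#' @param ed_iters Number of EM refinement iterations (default 50); 0
#'   returns the pure PCA candidates.
#' @return A named list of r x r PSD matrices (`pca_1`, ...,
#'   `ed_1`, ... when `ed_iters > 0`).
#' @export
data_driven_covs <- function(Z, n_components = NULL, ed_iters = 50) {
  Z <- as.matrix(Z)
  m <- nrow(Z); r <- ncol(Z)
  if (m < r)
    stop("need at least as many strong signals as phenotypes (m >= r); ",
         "with too few signals use the canonical prior only")
  if (is.null(n_components)) n_components <- min(3L, r)
  n_components <- min(as.integer(n_components), r)
  M <- crossprod(Z) / m - diag(r)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  out <- list()
  for (i in seq_len(n_components)) {
    lam <- max(ee$values[i], 0)
    out[[paste0("pca_", i)]] <- lam * tcrossprod(ee$vectors[, i])
  }
  if (ed_iters > 0) {
    for (i in seq_len(n_components)) {
      U <- out[[paste0("pca_", i)]]
      if (max(abs(U)) == 0) U <- 1e-4 * diag(r)  # escape the zero fixed point
      for (it in seq_len(ed_iters)) {
        A <- solve(U + diag(r), U)          # (U + I)^{-1} U
        Sig <- U - crossprod(A, U)          # posterior covariance of signal
        Mu <- Z %*% A                       # posterior means (m x r)
        U <- crossprod(Mu) / m + Sig
        U <- .psd_project((U + t(U)) / 2)
      }
      out[[paste0("ed_", i)]] <- U
    }
  }
  out
}

.psd_project <- function(M, floor = 0) {
  ee <- eigen(M, symmetric = TRUE)
  vals <- pmax(ee$values, floor)
  ee$vectors %*% (vals * t(ee$vectors))
}

#' Serialize a mixture prior to a text file
#'
#' Writes labels, weights and row-major matrices in a plain-text format so a
#' fitted prior can be reused (e.g. across chromosomes); [read_prior()]
#' inverts it.
#'
#' @param prior A [mixture_prior()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "mixture_prior"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mixture_prior r=%d K=%d", prior$r, prior$K), con)
  for (k in seq_len(prior$K)) {
    writeLines(sprintf(">%s\t%s", prior$labels[k],
                       format(prior$w0[k], digits = 17)), con)
    utils::write.table(format(prior$S0[[k]], digits = 17), con,
                       quote = FALSE, row.names = FALSE, col.names = FALSE,
                       sep = "\t")
  }
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#mixture_prior"))
    stop("not a mixture prior file: ", path)
  r <- as.integer(sub(".*r=([0-9]+).*", "\\1", hdr))
  heads <- which(startsWith(lines, ">"))
  S0 <- list(); w0 <- numeric(0); labels <- character(0)
  for (h in heads) {
    parts <- strsplit(sub("^>", "", lines[h]), "\t")[[1]]
    labels <- c(labels, parts[1])
    w0 <- c(w0, as.numeric(parts[2]))
    block <- lines[(h + 1):(h + r)]
    M <- do.call(rbind, lapply(strsplit(block, "\t"), as.numeric))
    S0[[length(S0) + 1L]] <- matrix(M, r, r)
  }
  # tolerate float drift from serialization, but let genuinely invalid
  # weights fail validation in mixture_prior()
  if (abs(sum(w0) - 1) < 1e-8) w0 <- w0 / sum(w0)
  mixture_prior(S0, w0 = w0, labels = labels)
}
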