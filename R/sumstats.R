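#' GWAS summary statistics for multiple phenotypes
#'
#' Container for per-variant, per-phenotype marginal effect sizes and
#' standard errors from single-variant association scans, together with the
#' GWAS sample size.  All downstream summary-data fitting starts from this
#' object plus an [ld_matrix()].
#'
#' @param betahat Numeric matrix (p variants x r phenotypes) of marginal
#'   effect sizes from simple linear regression of each phenotype on each
#'   variant.
#' @param se Numeric matrix, same shape as `betahat`, of standard errors;
#'   all entries must be strictly positive.
#' @param n GWAS sample size (single positive integer, at least 3; the
#'   sufficient-statistic recovery divides by `n - 2`).
#' @param variant_ids Character vector of length p; must be unique.
#' @param phenotype_ids Character vector of length r; must be unique.
#' @param chrom Optional chromosome label per variant (recycled if length 1).
#' @param pos_cm Optional genetic-map position per variant, in centimorgans.
#'
#' @return An object of class `"gwas_summary"`: a list with elements
#'   `betahat`, `se`, `n`, `variant_ids`, `phenotype_ids`, `chrom`, `pos_cm`.
#' @seealso [gwas_scan()] which produces this object from individual-level
#'   data, [recover_suffstats()] which consumes it.
#' @export
gwas_summary <- function(betahat, se, n, variant_ids = NULL,
                         phenotype_ids = NULL, chrom = NULL, pos_cm = NULL) {
  betahat <- as.matrix(betahat)
  se <- as.matrix(se)
  if (!all(dim(betahat) == dim(se)))
    stop("'betahat' and 'se' must have identical dimensions")
  if (!all(is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and strictly positive")
  if (!all(is.finite(betahat)))
    stop("'betahat' must be finite")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 3L)
    stop("'n' must be a single integer >= 3")
  p <- nrow(betahat); r <- ncol(betahat)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  if (is.null(phenotype_ids)) phenotype_ids <- paste0("pheno", seq_len(r))
  variant_ids <- as.character(variant_ids)
  phenotype_ids <- as.character(phenotype_ids)
  if (length(variant_ids) != p || anyDuplicated(variant_ids))
    stop("'variant_ids' must have length nrow(betahat) and be unique")
  if (length(phenotype_ids) != r || anyDuplicated(phenotype_ids))
    stop("'phenotype_ids' must have length ncol(betahat) and be unique")
  if (!is.null(chrom)) {
    chrom <- rep_len(as.character(chrom), p)
  }
  if (!is.null(pos_cm)) {
    pos_cm <- as.numeric(pos_cm)
    if (length(pos_cm) != p) stop("'pos_cm' must have length p")
  }
  dimnames(betahat) <- dimnames(se) <- list(variant_ids, phenotype_ids)
  structure(list(betahat = betahat, se = se, n = n,
                 variant_ids = variant_ids, phenotype_ids = phenotype_ids,
                 chrom = chrom, pos_cm = pos_cm),
            class = "gwas_summary")
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat("GWAS summary statistics:", nrow(x$betahat), "variants x",
      ncol(x$betahat), "phenotypes, n =", x$n, "\n")
  invisible(x)
}

#' Structure descriptors for LD matrices
#'
#' `ld_banded(window_cm)` describes an LD matrix in which correlations
#' between variants more than `window_cm` centimorgans apart (or on
#' different chromosomes) are set to zero; entries exactly at the window are
#' retained.  `ld_block_diagonal(blocks)` describes a block-diagonal LD
#' matrix with the given block memberships.
#'
#' @param window_cm Positive banding window in centimorgans (default 3, the
#'   conventional banding distance for biobank-scale LD); may be `Inf`.
#' @param blocks Either an integer vector of block labels (length p) or a
#'   list of index vectors partitioning `1:p`.
#' @return A list of class `"ld_structure"` describing the structure.
#' @export
ld_banded <- function(window_cm = 3) {
  if (!is.numeric(window_cm) || length(window_cm) != 1L || window_cm <= 0)
    stop("'window_cm' must be a single positive number")
  structure(list(type = "banded", window_cm = window_cm),
            class = "ld_structure")
}

#' @rdname ld_banded
#' @export
ld_block_diagonal <- function(blocks) {
  if (is.list(blocks)) {
    lab <- integer(sum(lengths(blocks)))
    for (b in seq_along(blocks)) lab[blocks[[b]]] <- b
    if (any(lab == 0L)) stop("'blocks' must partition 1:p")
    blocks <- lab
  }
  structure(list(type = "block_diagonal", blocks = as.integer(blocks)),
            class = "ld_structure")
}

ld_dense <- function() structure(list(type = "dense"), class = "ld_structure")

#' LD correlation matrix with variant metadata
#'
#' Stores a variant-by-variant correlation matrix together with genetic-map
#' positions (in centimorgans) and chromosome labels, and a structure
#' descriptor (dense, banded, or block-diagonal).
#'
#' @param R Symmetric correlation matrix (p x p) with unit diagonal.
#' @param positions_cm Genetic-map position (cM) per variant, nondecreasing
#'   within each chromosome.
#' @param chrom Chromosome label per variant (default all `"1"`).
#' @param variant_ids Character vector of unique variant ids.
#' @param structure An [ld_banded()]/[ld_block_diagonal()] descriptor or
#'   `NULL` for dense.  The structure is *applied* (entries zeroed) on
#'   construction.
#' @return An object of class `"ld_matrix"` with elements `R`,
#'   `positions_cm`, `chrom`, `variant_ids`, `structure`.
#' @export
ld_matrix <- function(R, positions_cm = NULL, chrom = NULL,
                      variant_ids = NULL, structure = NULL) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (ncol(R) != p) stop("'R' must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("'R' must be symmetric")
  R <- (R + t(R)) / 2
  if (max(abs(diag(R) - 1)) > 1e-8) stop("'R' must have unit diagonal")
  diag(R) <- 1
  if (max(abs(R)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  if (is.null(positions_cm)) positions_cm <- seq_len(p) - 1
  positions_cm <- as.numeric(positions_cm)
  if (length(positions_cm) != p) stop("'positions_cm' must have length p")
  if (is.null(chrom)) chrom <- rep("1", p)
  chrom <- rep_len(as.character(chrom), p)
  for (cc in unique(chrom)) {
    pos <- positions_cm[chrom == cc]
    if (is.unsorted(pos)) stop("positions must be nondecreasing within chromosome ", cc)
  }
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != p || anyDuplicated(variant_ids))
    stop("'variant_ids' must be unique and of length p")
  if (is.null(structure)) structure <- ld_dense()
  if (!inherits(structure, "ld_structure")) stop("invalid 'structure'")
  obj <- structure(list(R = R, positions_cm = positions_cm, chrom = chrom,
                        variant_ids = variant_ids, structure = structure),
                   class = "ld_matrix")
  if (structure$type != "dense")
    obj$R <- .zero_outside_structure(R, positions_cm, chrom, structure)
  obj
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix:", nrow(x$R), "variants,", x$structure$type, "structure\n")
  invisible(x)
}

.zero_outside_structure <- function(R, positions_cm, chrom, structure) {
  p <- nrow(R)
  if (structure$type == "banded") {
    w <- structure$window_cm
    if (is.finite(w)) {
      keep <- abs(outer(positions_cm, positions_cm, "-")) <= w
      keep <- keep & outer(chrom, chrom, "==")
      R[!keep] <- 0
    } else {
      R[outer(chrom, chrom, "!=")] <- 0
    }
  } else if (structure$type == "block_diagonal") {
    b <- structure$blocks
    if (length(b) != p) stop("block labels must have length p")
    R[outer(b, b, "!=")] <- 0
  }
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Impose banded or block-diagonal structure on an LD matrix
#'
#' Zeroes correlations outside a genetic-distance band (entries strictly
#' more than `window_cm` centimorgans apart, or on different chromosomes)
#' or outside blocks.  The diagonal is preserved and the result is
#' symmetric; the operation is idempotent.
#'
#' @param R A correlation matrix or an [ld_matrix()] object.
#' @param positions_cm,chrom Variant metadata (ignored when `R` is an
#'   `ld_matrix`, which carries its own).
#' @param structure An [ld_banded()] or [ld_block_diagonal()] descriptor.
#' @return An [ld_matrix()] with the structure applied and recorded.
#' @export
apply_ld_structure <- function(R, positions_cm = NULL, chrom = NULL,
                               structure) {
  if (inherits(R, "ld_matrix")) {
    return(ld_matrix(R$R, R$positions_cm, R$chrom, R$variant_ids,
                     structure = structure))
  }
  ld_matrix(R, positions_cm, chrom, structure = structure)
}

#' Sufficient statistics for the multivariate multiple regression
#'
#' The triple (X'X, X'Y, Y'Y) together with the sample size n; the fitting
#' engine's only data input.  `YtY` is optional: it is needed only when the
#' residual covariance V is estimated (or for an absolute evidence lower
#' bound).
#'
#' @param XtX Symmetric p x p cross-product matrix of (centered) genotypes;
#'   diagonal entries must be strictly positive.
#' @param XtY p x r cross-product of genotypes with phenotypes.
#' @param YtY Optional symmetric r x r phenotype cross-product matrix.
#' @param n Sample size (positive integer).
#' @param variant_ids,phenotype_ids Optional identifiers.
#' @param approximate_XtX Logical; `TRUE` when `XtX` was rebuilt from a
#'   reference-panel LD matrix (X'Y is recovered exactly from GWAS summary
#'   statistics but X'X is only approximated in that case).
#' @return An object of class `"suff_stats"` with elements `XtX`, `XtY`,
#'   `YtY`, `n`, `d` (the diagonal of `XtX`), ids, and `approximate_XtX`.
#' @export
suff_stats <- function(XtX, XtY, YtY = NULL, n, variant_ids = NULL,
                       phenotype_ids = NULL, approximate_XtX = FALSE) {
  XtX <- as.matrix(XtX); XtY <- as.matrix(XtY)
  p <- nrow(XtX)
  if (ncol(XtX) != p) stop("'XtX' must be square")
  if (max(abs(XtX - t(XtX))) > 1e-8 * max(1, max(abs(XtX))))
    stop("'XtX' must be symmetric")
  XtX <- (XtX + t(XtX)) / 2
  if (nrow(XtY) != p) stop("'XtY' must have nrow(XtX) rows")
  d <- diag(XtX)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diagonal of 'XtX' must be finite and strictly positive; ",
         "offending variant(s): ",
         paste(utils::head(which(!is.finite(d) | d <= 0), 5), collapse = ", "))
  r <- ncol(XtY)
  if (!is.null(YtY)) {
    YtY <- as.matrix(YtY)
    if (nrow(YtY) != r || ncol(YtY) != r) stop("'YtY' must be r x r")
    if (max(abs(YtY - t(YtY))) > 1e-8 * max(1, max(abs(YtY))))
      stop("'YtY' must be symmetric")
    YtY <- (YtY + t(YtY)) / 2
    if (any(diag(YtY) <= 0)) stop("'YtY' must have positive diagonal")
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (is.null(variant_ids)) variant_ids <- rownames(XtX)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  if (is.null(phenotype_ids)) phenotype_ids <- colnames(XtY)
  if (is.null(phenotype_ids)) phenotype_ids <- paste0("pheno", seq_len(r))
  structure(list(XtX = XtX, XtY = XtY, YtY = YtY, n = n, d = d,
                 variant_ids = as.character(variant_ids),
                 phenotype_ids = as.character(phenotype_ids),
                 approximate_XtX = isTRUE(approximate_XtX)),
            class = "suff_stats")
}

#' @export
print.suff_stats <- function(x, ...) {
  cat("Sufficient statistics: p =", nrow(x$XtX), ", r =", ncol(x$XtY),
      ", n =", x$n, if (is.null(x$YtY)) "(Y'Y absent)" else "(Y'Y present)",
      if (x$approximate_XtX) "[X'X approximate]" else "", "\n")
  invisible(x)
}

#' Sufficient statistics from individual-level data
#'
#' Computes X'X, X'Y and Y'Y after optional column centering and
#' standardization.  This is the individual-level ("oracle") path; the
#' summary-statistics path is [recover_suffstats()], and the two agree on
#' standardized data computed from the same individuals.
#'
#' @param X n x p genotype matrix, no missing values.
#' @param Y n x r phenotype matrix, no missing values.
#' @param center Center columns of `X` and `Y` (default `TRUE`).
#' @param standardize Scale columns of `X` to unit sample variance
#'   (default `FALSE`).  Phenotype columns are never rescaled here.
#' @return A [suff_stats()] object (Y'Y always present on this path).
#' @export
compute_suffstats <- function(X, Y, center = TRUE, standardize = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(X))
    stop("missing values are not supported here; compute summary statistics ",
         "per phenotype on complete cases (see gwas_scan()) instead -- the ",
         "model assumes the summary statistics come from the same individuals ",
         "for every phenotype")
  n <- nrow(X)
  if (n < 2L) stop("need n > 1")
  if (nrow(Y) != n) stop("'X' and 'Y' must have the same number of rows")
  if (center) {
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  if (standardize) {
    sdx <- sqrt(colSums(X^2) / (n - 1))
    if (any(sdx == 0)) stop("zero-variance column in 'X' (variant ",
                            paste(which(sdx == 0), collapse = ", "),
                            "): d_j = 0 violates the sufficient-statistic ",
                            "invariant")
    X <- sweep(X, 2, sdx, "/")
  }
  XtX <- crossprod(X)
  if (any(diag(XtX) <= 0))
    stop("zero-variance column in 'X' (variant ",
         paste(which(diag(XtX) <= 0), collapse = ", "),
         "): d_j = 0 violates the sufficient-statistic invariant")
  suff_stats(XtX = XtX, XtY = crossprod(X, Y), YtY = crossprod(Y), n = n,
             variant_ids = colnames(X), phenotype_ids = colnames(Y))
}

#' Recover sufficient statistics from GWAS summary statistics and LD
#'
#' Rebuilds the sufficient statistics (X'X, X'Y and optionally Y'Y) of the
#' multivariate multiple regression from single-variant effect sizes,
#' standard errors, the GWAS sample size and an LD matrix.  Per variant j
#' and phenotype t the diagonal cross-product is
#' \deqn{d_{jt} = y_t'y_t / (se_{jt}^2 (n-2) + \hat\beta_{jt}^2),}
#' with \eqn{y_t'y_t = n - 1} under the variance-standardized phenotype
#' convention.  The per-phenotype values are collapsed to a single
#' \eqn{d_j} by their median (they coincide under complete sample overlap;
#' disagreement is a QC symptom, see [qc_consistency()]).  Then
#' `XtY[j, t] = betahat[j, t] * d_j` and `XtX = D^{1/2} R D^{1/2}`.
#' X'Y is recovered exactly; X'X is only approximated when `ld` comes from
#' a reference panel rather than the GWAS sample.
#'
#' @param gwas A [gwas_summary()] object.
#' @param ld An [ld_matrix()] covering the same variants in the same order.
#' @param yty_mode `"standardized"` (phenotypes variance-standardized, so
#'   y'y = n - 1 per phenotype and Y'Y defaults to (n-1) times
#'   `cor_Y`), `"supplied"` (use the `YtY` argument), or `"absent"`
#'   (fit with V fixed).
#' @param YtY r x r phenotype cross-product, required for
#'   `yty_mode = "supplied"`.
#' @param cor_Y Optional phenotype correlation matrix used to fill the
#'   off-diagonal of Y'Y under the standardized convention.  When `NULL`
#'   it is estimated as the correlation of the z-scores across variants, a
#'   standard summary-level stand-in for the phenotypic correlation (exact
#'   phenotype covariance can be supplied instead via
#'   `yty_mode = "supplied"`).
#' @return A [suff_stats()] object with `approximate_XtX = TRUE`.
#' @export
recover_suffstats <- function(gwas, ld,
                              yty_mode = c("standardized", "supplied", "absent"),
                              YtY = NULL, cor_Y = NULL) {
  yty_mode <- match.arg(yty_mode)
  stopifnot(inherits(gwas, "gwas_summary"), inherits(ld, "ld_matrix"))
  p <- nrow(gwas$betahat); r <- ncol(gwas$betahat); n <- gwas$n
  if (nrow(ld$R) != p)
    stop("shape mismatch: gwas has ", p, " variants but ld has ", nrow(ld$R))
  if (!identical(gwas$variant_ids, ld$variant_ids))
    stop("gwas and ld must cover the same variants in the same order")
  yty_t <- switch(yty_mode,
                  standardized = rep(n - 1, r),
                  supplied = {
                    if (is.null(YtY)) stop("yty_mode = 'supplied' requires 'YtY'")
                    diag(as.matrix(YtY))
                  },
                  absent = rep(n - 1, r))
  djt <- sweep(1 / (gwas$se^2 * (n - 2) + gwas$betahat^2), 2, yty_t, "*")
  d <- apply(djt, 1, stats::median)
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad))
    stop("non-finite or non-positive recovered d_j for variant(s): ",
         paste(utils::head(gwas$variant_ids[bad], 5), collapse = ", "))
  XtY <- gwas$betahat * d
  sq <- sqrt(d)
  XtX <- ld$R * tcrossprod(sq)
  diag(XtX) <- d
  YtY_out <- switch(yty_mode,
                    standardized = {
                      if (is.null(cor_Y)) {
                        # z-score correlation across null-ish variants
                        # (max |z| < 2) estimates the phenotypic correlation
                        # without contamination from shared genetic signal
                        Z <- gwas$betahat / gwas$se
                        nullish <- apply(abs(Z), 1, max) < 2
                        if (sum(nullish) < max(10, r + 1)) nullish <- rep(TRUE, p)
                        cor_Y <- if (p >= 3 && r > 1)
                          suppressWarnings(stats::cor(Z[nullish, , drop = FALSE]))
                        else diag(r)
                        if (anyNA(cor_Y)) cor_Y <- diag(r)
                      }
                      (n - 1) * as.matrix(cor_Y)
                    },
                    supplied = as.matrix(YtY),
                    absent = NULL)
  suff_stats(XtX = XtX, XtY = XtY, YtY = YtY_out, n = n,
             variant_ids = gwas$variant_ids,
             phenotype_ids = gwas$phenotype_ids,
             approximate_XtX = TRUE)
}

#' Consistency checks on summary statistics and LD
#'
#' Reporting-only quality control ahead of model fitting.  Two symptoms are
#' flagged, without mutating the inputs: (1) variants whose per-phenotype
#' recovered diagonal cross-products \eqn{d_{jt}} disagree beyond a relative
#' tolerance (a sample-overlap or unit-mismatch symptom; under complete
#' sample overlap on standardized phenotypes they coincide); (2) variants
#' whose z-score is implausible given their strongest LD partner: for the
#' phenotype with the largest |z|, the statistic
#' \eqn{(z_j - R_{jk} z_k)/\sqrt{2(1 - R_{jk}^2)}} is approximately standard
#' normal when the pair carries no shared signal; a variant is flagged when
#' the statistic is large *and* its z disagrees in sign with the
#' LD-predicted value \eqn{R_{jk} z_k} — the allele-flip signature (true
#' shared signal produces sign-consistent large z pairs and is not
#' flagged).
#'
#' @param gwas A [gwas_summary()] object.
#' @param ld An [ld_matrix()] aligned with `gwas`.
#' @param d_rel_tol Relative tolerance on the spread of \eqn{d_{jt}} across
#'   phenotypes, `(max - min)/median` (default 0.05); `Inf` disables the
#'   check.
#' @param z_outlier_threshold Threshold on the neighborhood z-consistency
#'   statistic (default 5); `Inf` disables.
#' @param r2_min Minimum squared correlation for a variant pair to count as
#'   an LD neighborhood (default 0.5).
#' @return A data frame with one row per flagged variant: `variant_id`,
#'   `check` (`"d_dispersion"` or `"z_mismatch"`), and `statistic`.
#' @export
qc_consistency <- function(gwas, ld, d_rel_tol = 0.05,
                           z_outlier_threshold = 5, r2_min = 0.5) {
  stopifnot(inherits(gwas, "gwas_summary"), inherits(ld, "ld_matrix"))
  p <- nrow(gwas$betahat); n <- gwas$n
  if (!identical(gwas$variant_ids, ld$variant_ids))
    stop("gwas and ld must cover the same variants in the same order")
  flags <- list()
  djt <- (n - 1) / (gwas$se^2 * (n - 2) + gwas$betahat^2)
  if (is.finite(d_rel_tol)) {
    disp <- (apply(djt, 1, max) - apply(djt, 1, min)) /
      apply(djt, 1, stats::median)
    hit <- which(disp > d_rel_tol)
    if (length(hit))
      flags[[length(flags) + 1L]] <- data.frame(
        variant_id = gwas$variant_ids[hit], check = "d_dispersion",
        statistic = disp[hit], stringsAsFactors = FALSE)
  }
  if (is.finite(z_outlier_threshold) && p > 1L) {
    Z <- gwas$betahat / gwas$se
    zmax <- Z[cbind(seq_len(p), max.col(abs(Z)))]
    R <- ld$R
    diag(R) <- 0
    partner <- max.col(abs(R))
    rjk <- R[cbind(seq_len(p), partner)]
    ok <- rjk^2 >= r2_min & rjk^2 < 1 - 1e-12
    tstat <- rep(0, p)
    tstat[ok] <- (zmax[ok] - rjk[ok] * zmax[partner[ok]]) /
      sqrt(2 * (1 - rjk[ok]^2))
    discordant <- zmax * rjk * zmax[partner] < 0
    hit <- which(abs(tstat) > z_outlier_threshold & discordant)
    if (length(hit))
      flags[[length(flags) + 1L]] <- data.frame(
        variant_id = gwas$variant_ids[hit], check = "z_mismatch",
        statistic = tstat[hit], stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(variant_id = character(), check = character(),
                      statistic = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}
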