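#' Linear polygenic scoring
#'
#' Computes polygenic scores `yhat = X_test %*% B` for test individuals,
#' optionally summing scores across per-chromosome fits (models are
#' conventionally fitted one chromosome at a time, and the linear score is
#' additive across chromosomes).
#'
#' @param X_test n_test x p genotype matrix (columns named by variant id
#'   when alignment should be checked).
#' @param fit A fitted [mr_mash_rss()] object, a p x r coefficient matrix,
#'   or a list of either (per-chromosome parts; each part's variants are
#'   looked up in `X_test` by id, or the columns of `X_test` are split in
#'   order when ids are absent).
#' @param ... Unused.
#' @return n_test x r matrix of scores (phenotype ids as column names when
#'   known).
#' @export
pgs_score <- function(X_test, fit, ...) {
  X_test <- as.matrix(X_test)
  if (is.list(fit) && !inherits(fit, "mr_mash_rss")) {
    parts <- lapply(fit, function(f) pgs_score(X_test, f))
    out <- Reduce(`+`, parts)
    return(out)
  }
  if (inherits(fit, "mr_mash_rss")) {
    B <- fit$coefficients
  } else {
    B <- as.matrix(fit)
  }
  ids <- rownames(B)
  if (!is.null(ids) && !is.null(colnames(X_test))) {
    idx <- match(ids, colnames(X_test))
    if (anyNA(idx))
      stop("variant ids in the fit are missing from 'X_test': ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    X_test <- X_test[, idx, drop = FALSE]
  } else if (ncol(X_test) != nrow(B)) {
    stop("'X_test' has ", ncol(X_test), " columns but the fit has ",
         nrow(B), " variants and no ids to align by")
  }
  yhat <- X_test %*% B
  if (any(!is.finite(yhat))) stop("non-finite predictions")
  yhat
}

#' Prediction accuracy as regression R-squared
#'
#' The accuracy metric for polygenic scores: the R-squared from the linear
#' regression (with intercept) of the true phenotypes on the predicted
#' phenotypes, i.e. the squared Pearson correlation.  Its expectation is
#' bounded above by the genomic heritability of the simulated trait.  A
#' zero-variance prediction (e.g. from a null-prior fit) returns 0 by
#' convention, so degenerate fits evaluate cleanly.  The metric is
#' invariant to affine transforms of the prediction.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 3), or matrices
#'   with matching columns (evaluated per phenotype).
#' @return A scalar in \[0, 1\], or a named vector for matrix input.
#' @export
evaluate_r2 <- function(y_true, y_pred) {
  if (is.matrix(y_true) || is.matrix(y_pred)) {
    y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
    if (!all(dim(y_true) == dim(y_pred))) stop("dimension mismatch")
    return(vapply(seq_len(ncol(y_true)), function(t)
      evaluate_r2(y_true[, t], y_pred[, t]), numeric(1)) |>
        stats::setNames(colnames(y_true)))
  }
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have the same length")
  if (length(y_true) < 3L) stop("need at least 3 test individuals")
  if (stats::var(y_pred) == 0) return(0)
  stats::cor(y_true, y_pred)^2
}
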