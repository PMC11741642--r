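#' Read and write GWAS summary statistics as TSV
#'
#' The on-disk dialect is a tab-separated table with header columns
#' `variant_id`, `chrom`, `pos_cm`, `n`, then `beta_<phenotype>` and
#' `se_<phenotype>` for each phenotype; one row per variant.
#'
#' @param gwas A [gwas_summary()].
#' @param path File path.
#' @return `write_gwas_tsv()` returns `path` invisibly; `read_gwas_tsv()`
#'   returns a [gwas_summary()].
#' @export
write_gwas_tsv <- function(gwas, path) {
  stopifnot(inherits(gwas, "gwas_summary"))
  p <- nrow(gwas$betahat)
  df <- data.frame(variant_id = gwas$variant_ids,
                   chrom = if (is.null(gwas$chrom)) rep(NA, p) else gwas$chrom,
                   pos_cm = if (is.null(gwas$pos_cm)) rep(NA, p) else gwas$pos_cm,
                   n = rep(gwas$n, p),
                   stringsAsFactors = FALSE)
  for (t in seq_along(gwas$phenotype_ids)) {
    df[[paste0("beta_", gwas$phenotype_ids[t])]] <- gwas$betahat[, t]
    df[[paste0("se_", gwas$phenotype_ids[t])]] <- gwas$se[, t]
  }
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(variant_id = "character"))
  need <- c("variant_id", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed GWAS table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  beta_cols <- grep("^beta_", names(df), value = TRUE)
  if (!length(beta_cols)) stop("no beta_<phenotype> columns in ", path)
  phenos <- sub("^beta_", "", beta_cols)
  se_cols <- paste0("se_", phenos)
  miss <- setdiff(se_cols, names(df))
  if (length(miss))
    stop("malformed GWAS table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  betahat <- as.matrix(df[, beta_cols, drop = FALSE])
  se <- as.matrix(df[, se_cols, drop = FALSE])
  if (anyNA(se)) stop("NaN/NA standard errors in ", path)
  if (anyDuplicated(df$variant_id))
    stop("duplicated variant ids in ", path)
  gwas_summary(betahat, se, n = df$n[1], variant_ids = df$variant_id,
               phenotype_ids = phenos,
               chrom = if ("chrom" %in% names(df) && !all(is.na(df$chrom)))
                 as.character(df$chrom) else NULL,
               pos_cm = if ("pos_cm" %in% names(df) && !all(is.na(df$pos_cm)))
                 df$pos_cm else NULL)
}

#' Read and write LD matrices
#'
#' The LD matrix is written as a TSV of correlations (variant ids as
#' header), with a companion variant-metadata table at `<path>.vars.tsv`
#' (`variant_id`, `chrom`, `pos_cm`) and a JSON sidecar at `<path>.json`
#' recording the structure (dense / banded window / block labels), so
#' block bounds round-trip exactly.
#'
#' @param ld An [ld_matrix()].
#' @param path Path of the main matrix file.
#' @return `write_ld()` returns `path` invisibly; `read_ld()` an
#'   [ld_matrix()].
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  M <- ld$R
  colnames(M) <- ld$variant_ids
  utils::write.table(format(M, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant_id = ld$variant_ids, chrom = ld$chrom,
               pos_cm = format(ld$positions_cm, digits = 17),
               stringsAsFactors = FALSE),
    paste0(path, ".vars.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ld$structure[setdiff(names(ld$structure), "")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  R <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  meta <- utils::read.table(paste0(path, ".vars.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c(variant_id = "character",
                                           chrom = "character"))
  st <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure_obj <- switch(st$type,
                          dense = ld_dense(),
                          banded = ld_banded(st$window_cm),
                          block_diagonal = ld_block_diagonal(st$blocks))
  ld_matrix(R, positions_cm = meta$pos_cm, chrom = meta$chrom,
            variant_ids = meta$variant_id, structure = structure_obj)
}

#' Write a numeric matrix with ids as TSV (internal convention)
#' @noRd
.write_matrix_tsv <- function(M, path, id_col = "variant_id") {
  df <- data.frame(rownames(M), format(M, digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path, id_col = "variant_id") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = stats::setNames("character", id_col))
  M <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(M) <- df[[id_col]]
  M
}

#' Serialize a fitted model
#'
#' Writes the posterior mean effects as a TSV (variant ids + one column per
#' phenotype) and the remaining fit state (weights, labels, V, ELBO trace,
#' convergence metadata) as JSON at `<path>.state.json`.
#'
#' @param fit A [mr_mash_rss()] fit.
#' @param path Path of the effects TSV.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mr_mash_rss"))
  .write_matrix_tsv(fit$coefficients, path)
  state <- list(w0 = fit$w0, labels = fit$prior$labels, V = fit$V,
                elbo = fit$elbo, converged = fit$converged,
                n_iter = fit$n_iter, n = fit$n,
                phenotype_ids = fit$phenotype_ids)
  jsonlite::write_json(state, paste0(path, ".state.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit_effects <- function(path) {
  .read_matrix_tsv(path)
}
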