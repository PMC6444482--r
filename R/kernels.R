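#' Center and standardize SNP genotypes
#'
#' Missing dosages are imputed to the column mean, each column is centered
#' by twice the observed allele frequency and scaled to unit variance.
#' Two scaling conventions are offered: `"binomial"` divides by
#' \eqn{\sqrt{2\hat p(1-\hat p)}} with \eqn{\hat p} the observed B-allele
#' frequency (the VanRaden/Yang convention), while `"empirical"` divides
#' by the observed population (divide-by-n) standard deviation, for which
#' the mean diagonal of the resulting kernel is exactly 1 by construction.
#' Zero-variance columns are dropped with a message.
#'
#' @param g A [genotype_matrix()] or plain dosage matrix.
#' @param snp_subset Optional SNP ids or column indices.
#' @param scale Scaling convention, `"binomial"` (default) or
#'   `"empirical"`.
#' @return Numeric matrix S (samples x retained SNPs) with columns of mean
#'   0, plus attribute `dropped` listing removed zero-variance SNPs.
#' @export
standardize_genotypes <- function(g, snp_subset = NULL,
                                  scale = c("binomial", "empirical")) {
  scale <- match.arg(scale)
  X <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (!is.null(snp_subset)) {
    idx <- if (is.character(snp_subset)) match(snp_subset, colnames(X))
           else snp_subset
    if (anyNA(idx)) stop("unknown SNP id in snp_subset")
    X <- X[, idx, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no SNPs selected for standardization")
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- cm[nas[, 2]]
  X <- sweep(X, 2, cm)
  phat <- cm / 2
  denom <- switch(scale,
                  binomial = sqrt(2 * phat * (1 - phat)),
                  empirical = sqrt(colMeans(X^2)))
  ok <- is.finite(denom) & denom > 1e-12 & colMeans(X^2) > 1e-12
  if (!all(ok))
    message(sum(!ok), " zero-variance SNP column(s) dropped")
  if (!any(ok)) stop("no SNPs with non-zero variance remain")
  S <- sweep(X[, ok, drop = FALSE], 2, denom[ok], `/`)
  attr(S, "dropped") <- colnames(X)[!ok]
  S
}

#' Build a linear genomic kernel K = SS'/p
#'
#' With S the centered, standardized genotype matrix and p its number of
#' SNPs, this is the additive genomic relationship matrix of VanRaden.
#'
#' @param S Standardized genotype matrix from [standardize_genotypes()].
#' @param sample_ids Optional sample ids (defaults to rownames of S).
#' @return An object of class `kernel_matrix`: list with `values` (n x n
#'   symmetric PSD matrix), `sample_ids` and `n_snps_used`.
#' @export
build_kernel <- function(S, sample_ids = rownames(S)) {
  S <- as.matrix(S)
  p <- ncol(S)
  if (p < 1) stop("S must have at least one SNP column")
  K <- tcrossprod(S) / p
  K <- (K + t(K)) / 2
  structure(list(values = K,
                 sample_ids = sample_ids %||% as.character(seq_len(nrow(S))),
                 n_snps_used = p),
            class = "kernel_matrix")
}

#' Genomic relationship matrix from a genotype matrix
#'
#' Convenience wrapper: standardize then [build_kernel()].
#'
#' @inheritParams standardize_genotypes
#' @return A `kernel_matrix`.
#' @export
grm <- function(g, snp_subset = NULL, scale = c("binomial", "empirical")) {
  S <- standardize_genotypes(g, snp_subset, scale)
  ids <- if (inherits(g, "genotype_matrix")) g$sample_ids else rownames(S)
  build_kernel(S, ids)
}

#' One kernel per functional SNP class
#'
#' Builds a linear kernel for each class of a partition, each divided by
#' its own SNP count, so that the SNP-count-weighted average of the class
#' kernels equals the whole-genome kernel exactly. Classes with fewer than
#' two usable SNPs are skipped with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param partition A `snp_class_partition` from [partition_snps()].
#' @param scale Standardization convention, see [standardize_genotypes()].
#' @return Named list of `kernel_matrix` objects.
#' @export
build_class_kernels <- function(g, partition,
                                scale = c("binomial", "empirical")) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(partition, "snp_class_partition"))
  scale <- match.arg(scale)
  out <- list()
  for (cls in snp_class_levels()) {
    ids <- names(partition$class_of)[partition$class_of == cls]
    ids <- intersect(ids, g$snp_meta$id)
    if (length(ids) < 2) {
      if (length(ids) > 0 || cls %in% partition$class_of)
        warning("class '", cls, "' has fewer than 2 usable SNPs; skipped")
      next
    }
    out[[cls]] <- grm(g, snp_subset = ids, scale = scale)
  }
  out
}

#' Eigendecomposition of a kernel
#'
#' @param kernel A `kernel_matrix`.
#' @param tol Eigenvalues below `tol` are truncated (dropped).
#' @return List with `vectors` (n x m) and `values` (length m).
#' @export
kernel_eigen <- function(kernel, tol = 1e-10) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  if (!is.null(kernel$eigen)) return(kernel$eigen)
  ev <- eigen(kernel$values, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("kernel is not numerically positive semi-definite (min eigenvalue ",
         format(min(ev$values)), ")")
  keep <- ev$values > tol
  list(vectors = ev$vectors[, keep, drop = FALSE],
       values = ev$values[keep])
}

#' Attach a cached eigendecomposition to a kernel
#'
#' Useful before repeated fits (cross-validation) so the O(n^3)
#' decomposition is done once.
#'
#' @inheritParams kernel_eigen
#' @return The kernel with an `eigen` element that [kernel_eigen()] and
#'   [fit_rkhs()] reuse.
#' @export
cache_kernel_eigen <- function(kernel, tol = 1e-10) {
  kernel$eigen <- kernel_eigen(kernel, tol)
  kernel
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d from %d SNPs; mean diag %.4f\n",
              nrow(x$values), ncol(x$values), x$n_snps_used,
              mean(diag(x$values))))
  invisible(x)
}

#' Serialize a kernel to disk
#'
#' Writes the numeric array in R's binary serialization plus a sidecar TSV
#' of sample ids; [load_kernel()] restores it.
#'
#' @param kernel A `kernel_matrix`.
#' @param path File path for the binary array; the sidecar is
#'   `<path>.ids.tsv`.
#' @return `path`, invisibly.
#' @export
save_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  saveRDS(kernel$values, path)
  utils::write.table(data.frame(sample_id = kernel$sample_ids,
                                n_snps_used = kernel$n_snps_used),
                     paste0(path, ".ids.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_kernel
#' @export
load_kernel <- function(path) {
  vals <- readRDS(path)
  side <- utils::read.delim(paste0(path, ".ids.tsv"),
                            colClasses = c("character", "integer"))
  structure(list(values = vals, sample_ids = side$sample_id,
                 n_snps_used = side$n_snps_used[1]),
            class = "kernel_matrix")
}
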