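#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages (counts of the B allele, coded 0/1/2,
#' `NA` for missing calls) together with per-SNP metadata and sample ids.
#'
#' @param dosages Integer matrix, samples in rows, SNPs in columns. Values in
#'   \{0, 1, 2\} or `NA`.
#' @param snp_meta Data frame with one row per SNP: columns `id`, `chrom`,
#'   `pos` (non-negative, 0-based), `alleleA`, `alleleB`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1 || ncol(dosages) < 1)
    stop("dosage matrix must have at least one sample and one SNP")
  if (nrow(snp_meta) != ncol(dosages))
    stop("snp_meta must have one row per SNP column")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids must match the number of rows")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique")
  if (any(snp_meta$pos < 0)) stop("SNP positions must be non-negative")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$id
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_meta$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Observed allele frequency of the B allele per SNP
#'
#' Computed from non-missing calls only.
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of length p, named by SNP id.
#' @export
allele_freq <- function(g) {
  colMeans(g$dosages, na.rm = TRUE) / 2
}

#' Per-SNP call rate
#'
#' @param g A [genotype_matrix()].
#' @return Fraction of non-missing calls per SNP.
#' @export
call_rate <- function(g) {
  colMeans(!is.na(g$dosages))
}

#' Subset a genotype matrix by SNPs and/or samples
#'
#' @param g A [genotype_matrix()].
#' @param snps SNP ids or column indices (optional).
#' @param samples Sample ids or row indices (optional).
#' @return A `genotype_matrix` restricted to the selection, order preserved
#'   as given.
#' @export
subset_genotypes <- function(g, snps = NULL, samples = NULL) {
  ridx <- if (is.null(samples)) seq_len(nrow(g$dosages)) else samples
  cidx <- if (is.null(snps)) seq_len(ncol(g$dosages)) else snps
  if (is.character(cidx)) cidx <- match(cidx, g$snp_meta$id)
  if (is.character(ridx)) ridx <- match(ridx, g$sample_ids)
  if (anyNA(cidx)) stop("unknown SNP id in subset")
  if (anyNA(ridx)) stop("unknown sample id in subset")
  genotype_matrix(g$dosages[ridx, cidx, drop = FALSE],
                  g$snp_meta[cidx, , drop = FALSE],
                  g$sample_ids[ridx])
}
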