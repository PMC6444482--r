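# Physical spacing (bp) between simulated SNPs. Large relative to the 5 kb
# regulatory window so that a gene emitted for one SNP cannot change the
# annotation of its neighbours.
.SNP_SPACING <- 25000L

# Deterministic SNP map implied by a configuration: SNPs split evenly
# across chromosomes, evenly spaced positions. Shared by the genotype and
# gene-model generators so their coordinates always agree.
snp_map <- function(config) {
  p <- config$n_snps
  n_chr <- min(config$n_chromosomes, p)
  chrom <- rep(seq_len(n_chr), length.out = p)
  chrom <- sort(chrom)
  idx_in_chrom <- stats::ave(seq_len(p), chrom, FUN = seq_along)
  data.frame(id = sprintf("snp%05d", seq_len(p)),
             chrom = as.character(chrom),
             pos = idx_in_chrom * .SNP_SPACING,
             alleleA = "A", alleleB = "B",
             stringsAsFactors = FALSE)
}

#' Simulate biallelic SNP genotypes
#'
#' Draws per-SNP population B-allele frequencies uniformly from
#' `config$maf_range` and generates diploid dosages from two latent
#' haplotypes per individual. Within a linkage-disequilibrium block
#' (`ld_block_size` consecutive SNPs) haplotype alleles share a latent
#' Gaussian AR(1) process (rho = 0.9), so adjacent SNPs are positively
#' correlated while every SNP keeps its drawn marginal frequency; block
#' (and chromosome) boundaries reset the process, so `ld_block_size = 1`
#' yields independent SNPs. Missing calls are placed independently at
#' `missing_rate`. SNP positions are evenly spaced along the chromosomes.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with an attribute `true_freq` holding the
#'   population allele frequencies used.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  p <- config$n_snps
  meta <- snp_map(config)
  freq <- stats::runif(p, config$maf_range[1], config$maf_range[2])

  rho <- 0.9
  n_hap <- 2L * n
  # latent AR(1) per haplotype, restarted at block/chromosome boundaries
  idx_in_chrom <- stats::ave(seq_len(p), meta$chrom, FUN = seq_along)
  new_block <- (idx_in_chrom - 1L) %% config$ld_block_size == 0L
  Z <- matrix(0, n_hap, p)
  eps <- matrix(stats::rnorm(n_hap * p), n_hap, p)
  Z[, 1] <- eps[, 1]
  if (p > 1) {
    for (j in 2:p) {
      if (new_block[j]) Z[, j] <- eps[, j]
      else Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * eps[, j]
    }
  }
  thr <- stats::qnorm(freq)
  carriers <- sweep(Z, 2, thr, `<`)
  dos <- carriers[seq(1, n_hap, by = 2), , drop = FALSE] +
    carriers[seq(2, n_hap, by = 2), , drop = FALSE]
  storage.mode(dos) <- "integer"
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    dos[miss] <- NA_integer_
  }
  g <- genotype_matrix(dos, meta,
                       sprintf("bull%05d", seq_len(n)))
  attr(g, "true_freq") <- stats::setNames(freq, meta$id)
  g
}
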