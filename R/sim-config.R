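#' Simulation configuration for the synthetic SCR study
#'
#' Defines the conditions under which synthetic genotypes, gene models and
#' sire-conception-rate (SCR) phenotypes are generated. Defaults emulate the
#' structure of a US Holstein sire fertility evaluation at desk scale:
#' 29 evaluation classes, an additive polygenic background with narrow-sense
#' heritability 0.30, a handful of large-effect dominance QTL coded as
#' carrier shifts, and functional-class labels over five annotation classes
#' (5region, 3region, non_synonymous, synonymous, ncRNA) plus intergenic,
#' with per-class SNP proportions matching a 312k Holstein genotyping panel.
#'
#' @param n_individuals Number of bulls to simulate.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chromosomes Number of autosomes SNPs are spread over (29 for
#'   cattle).
#' @param maf_range Pair of minor-allele frequencies in (0, 0.5]; each SNP's
#'   population B-allele frequency is drawn uniformly from this interval.
#' @param ld_block_size SNPs per linkage-disequilibrium block; 1 gives
#'   independent SNPs. Within a block adjacent SNPs are positively
#'   correlated via latent AR(1) haplotypes.
#' @param missing_rate Fraction of genotype calls set missing, in [0, 0.05].
#' @param h2_additive Fraction of phenotypic variance explained by the
#'   additive polygenic background.
#' @param n_dominance_qtl Number of large-effect dominance QTL.
#' @param dominance_variance_fraction Fraction of phenotypic variance
#'   contributed by each dominance QTL (carrier-shift coding).
#' @param n_eval_classes Number of evaluation release classes (fixed effect).
#' @param eval_class_sd Standard deviation of evaluation-class effects, in
#'   phenotype (SCR percentage-point) units.
#' @param class_proportions Named fractions of SNPs assigned to each
#'   functional class; the remainder is intergenic. Must sum to at most 1.
#' @param class_enrichment Named multipliers on the per-SNP additive effect
#'   variance for each functional class (intergenic implicitly 1).
#' @param total_variance Target phenotypic variance (additive + dominance +
#'   residual), in squared SCR units. SCR is reported in percentage points
#'   with an SD around 2, hence the default of 4.
#' @param mu Grand mean of the phenotype (SCR is a deviation, so 0).
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000,
                       n_snps = 2000,
                       n_chromosomes = 29,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1,
                       missing_rate = 0.01,
                       h2_additive = 0.30,
                       n_dominance_qtl = 5,
                       dominance_variance_fraction = 0.04,
                       n_eval_classes = 29,
                       eval_class_sd = 0.5,
                       class_proportions = holstein_class_proportions(),
                       class_enrichment = c("5region" = 5, "3region" = 5,
                                            non_synonymous = 5,
                                            synonymous = 5, ncRNA = 5),
                       total_variance = 4,
                       mu = 0,
                       seed = 1) {
  n_individuals <- assert_count(n_individuals, "n_individuals", min = 2)
  n_snps <- assert_count(n_snps, "n_snps", min = 1)
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", min = 1)
  ld_block_size <- assert_count(ld_block_size, "ld_block_size", min = 1)
  n_dominance_qtl <- assert_count(n_dominance_qtl, "n_dominance_qtl")
  n_eval_classes <- assert_count(n_eval_classes, "n_eval_classes", min = 1)
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within (0, 0.5]")
  assert_fraction(missing_rate, "missing_rate", 0, 0.05)
  assert_fraction(h2_additive, "h2_additive")
  assert_fraction(dominance_variance_fraction, "dominance_variance_fraction")
  if (eval_class_sd < 0) stop("eval_class_sd must be non-negative")
  if (total_variance <= 0) stop("total_variance must be positive")
  known <- c("5region", "3region", "non_synonymous", "synonymous", "ncRNA")
  if (length(class_proportions)) {
    if (is.null(names(class_proportions)) ||
        !all(names(class_proportions) %in% known))
      stop("class_proportions must be named by functional class: ",
           paste(known, collapse = ", "))
    if (any(class_proportions < 0) || sum(class_proportions) > 1)
      stop("class_proportions must be non-negative and sum to at most 1 ",
           "(the remainder is intergenic)")
  }
  if (length(class_enrichment) &&
      (is.null(names(class_enrichment)) ||
       !all(names(class_enrichment) %in% known) ||
       any(class_enrichment < 0)))
    stop("class_enrichment must be non-negative and named by functional class")
  budget <- h2_additive + n_dominance_qtl * dominance_variance_fraction
  if (budget >= 1)
    stop(sprintf(paste0("variance budget infeasible: h2_additive + ",
                        "n_dominance_qtl * dominance_variance_fraction = ",
                        "%.3f must be < 1"), budget))
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 n_chromosomes = n_chromosomes, maf_range = maf_range,
                 ld_block_size = ld_block_size, missing_rate = missing_rate,
                 h2_additive = h2_additive,
                 n_dominance_qtl = n_dominance_qtl,
                 dominance_variance_fraction = dominance_variance_fraction,
                 n_eval_classes = n_eval_classes,
                 eval_class_sd = eval_class_sd,
                 class_proportions = class_proportions,
                 class_enrichment = class_enrichment,
                 total_variance = total_variance, mu = mu,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Functional-class SNP proportions of a high-density Holstein panel
#'
#' Class shares observed on a 295,159-SNP post-QC bovine genotyping panel:
#' 7280 5region, 4122 3region, 1144 non-synonymous, 2090 synonymous and
#' 1556 ncRNA variants, the rest intergenic.
#'
#' @return Named numeric vector of per-class fractions (excluding
#'   intergenic).
#' @export
holstein_class_proportions <- function() {
  counts <- c("5region" = 7280, "3region" = 4122, non_synonymous = 1144,
              synonymous = 2090, ncRNA = 1556)
  counts / 295159
}

#' Functional class levels used throughout the pipeline
#' @return Character vector of the six class labels.
#' @export
snp_class_levels <- function() {
  c("5region", "3region", "non_synonymous", "synonymous", "ncRNA",
    "intergenic")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d bulls x %d SNPs (%d chromosomes), ",
                     "MAF U(%.2f, %.2f)\n"),
              x$n_individuals, x$n_snps, x$n_chromosomes,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  h2_additive = %.2f; %d dominance QTL x %.2f of variance\n",
              x$h2_additive, x$n_dominance_qtl,
              x$dominance_variance_fraction))
  cat(sprintf("  %d evaluation classes (sd %.2f); seed %d\n",
              x$n_eval_classes, x$eval_class_sd, x$seed))
  invisible(x)
}
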