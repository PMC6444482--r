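#' Quality-control filter for SNPs
#'
#' Removes SNPs mapped to excluded chromosomes (sex chromosomes by
#' default), with minor allele frequency strictly below `maf_min`, or with
#' call rate strictly below `call_rate_min`. The boundary is kept: a SNP
#' with MAF exactly `maf_min` (or call rate exactly `call_rate_min`)
#' passes, reading "below 5%" literally. MAF is computed on non-missing
#' calls only. SNP order is preserved and no dosage is modified.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum per-SNP call rate (default 0.95).
#' @param excluded_chroms Chromosome labels to drop (default X, Y).
#' @return A filtered `genotype_matrix` with attribute `qc_tally`, a named
#'   count of SNPs removed per criterion (applied in the order chromosome,
#'   MAF, call rate).
#' @export
filter_snps <- function(g, maf_min = 0.05, call_rate_min = 0.95,
                        excluded_chroms = c("X", "Y")) {
  stopifnot(inherits(g, "genotype_matrix"))
  assert_fraction(maf_min, "maf_min")
  assert_fraction(call_rate_min, "call_rate_min")
  freq <- allele_freq(g)
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0  # SNPs with zero calls
  cr <- call_rate(g)
  on_excl <- g$snp_meta$chrom %in% excluded_chroms
  low_maf <- !on_excl & maf < maf_min
  low_cr <- !on_excl & !low_maf & cr < call_rate_min
  keep <- !(on_excl | low_maf | low_cr)
  tally <- c(excluded_chrom = sum(on_excl), low_maf = sum(low_maf),
             low_call_rate = sum(low_cr))
  if (!any(keep)) {
    warning("no SNPs remain after QC filtering")
    out <- structure(list(dosages = g$dosages[, 0, drop = FALSE],
                          snp_meta = g$snp_meta[0, , drop = FALSE],
                          sample_ids = g$sample_ids),
                     class = "genotype_matrix")
  } else {
    out <- subset_genotypes(g, snps = which(keep))
  }
  attr(out, "qc_tally") <- tally
  out
}

#' De-duplicate phenotype records
#'
#' Keeps exactly one record per animal: the one with the most breedings
#' (the most reliable evaluation). Ties on breedings are broken
#' deterministically by the latest (lexicographically largest) evaluation
#' id, with a message.
#'
#' @param records Data frame with columns `animal_id`, `scr`, `evaluation`,
#'   `breedings` (`breedings >= 1`).
#' @return The de-duplicated data frame, one row per distinct `animal_id`,
#'   in order of first appearance.
#' @export
dedupe_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "scr", "evaluation", "breedings") %in%
                  names(records)))
  if (any(records$breedings < 1)) stop("breedings must be >= 1")
  if (nrow(records) == 0) return(records)
  ord <- order(match(records$animal_id, unique(records$animal_id)),
               -records$breedings,
               -xtfrm(records$evaluation))
  sorted <- records[ord, , drop = FALSE]
  dup <- duplicated(sorted$animal_id)
  # report ties broken by evaluation id
  ties <- with(sorted, tapply(breedings, animal_id,
                              function(b) length(b) > 1 && b[1] == b[2]))
  if (any(unlist(ties)))
    message(sum(unlist(ties)),
            " animal(s) had tied breeding counts; kept the latest evaluation")
  out <- sorted[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}
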