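#!/usr/bin/env Rscript
# Stage 2: quality control and record de-duplication.
#
# SNPs on sex chromosomes, with MAF below 5% or call rate below 95% are
# removed (boundaries kept, reading the filters literally); where a bull
# has several SCR records, the one with most breedings is kept.

library(sirefert)

out <- "results"
g <- read_dosage_tsv("results/data/genotypes.tsv")
ph <- read_phenotype_tsv("results/data/phenotypes.tsv")

gq <- filter_snps(g, maf_min = 0.05, call_rate_min = 0.95,
                  excluded_chroms = c("X", "Y"))
tally <- attr(gq, "qc_tally")
phd <- dedupe_records(ph)

write_dosage_tsv(gq, file.path(out, "genotypes_qc.tsv"))
write_phenotype_tsv(phd, file.path(out, "phenotypes_dedup.tsv"))
write.table(data.frame(criterion = names(tally), removed = tally),
            file.path(out, "qc_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("QC: %d -> %d SNPs (removed: %s)\n",
            ncol(g$dosages), ncol(gq$dosages),
            paste(names(tally), tally, sep = "=", collapse = ", ")))
cat(sprintf("records: %d -> %d after keeping the most-bred record per bull\n",
            nrow(ph), nrow(phd)))
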