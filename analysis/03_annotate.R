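#!/usr/bin/env Rscript
# Stage 3: partition SNPs into functional classes.
#
# Coding and ncRNA classes come from the variant-effect labels; the
# 5region / 3region classes are re-derived positionally from the gene
# models (within 5 kb of the strand-aware 5' or 3' end); everything else
# is intergenic.

library(sirefert)

g <- read_dosage_tsv("results/genotypes_qc.tsv")
genes <- read_gene_bed("results/data/gene_models.bed")
labels <- read.delim("results/data/effect_labels.tsv",
                     colClasses = "character")

part <- partition_snps(g, genes, labels = labels)
write_partition_tsv(part, "results/snp_classes.tsv")
write.table(data.frame(class = names(part$counts), n_snps = part$counts),
            "results/class_counts.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("functional class sizes after QC:\n")
print(part$counts)
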