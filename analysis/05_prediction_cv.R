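#!/usr/bin/env Rscript
# Stage 5: cross-validated genomic prediction.
#
# 5-fold cross-validation repeated twice (the full design uses ten
# repeats; two keep this driver quick) for four models:
#   Base                              one kernel, all SNPs
#   Base + 5 SNP                      plus the selected markers as fixed
#                                     0/1 effects
#   Intergenic + Functional           six class kernels
#   Intergenic + 5 SNP + Functional   six kernels plus fixed markers
# and a size-matched random-SNP baseline for the 5region class.
# Test-fold phenotypes are masked and predicted by data augmentation;
# CORR and MSEP are computed on the held-out records.

library(sirefert)

g <- read_dosage_tsv("results/genotypes_qc.tsv")
ph <- read_phenotype_tsv("results/phenotypes_dedup.tsv")
ph <- ph[match(g$sample_ids, ph$animal_id), ]
classes <- read.delim("results/snp_classes.tsv", colClasses = "character")
part <- structure(list(class_of = setNames(classes$class, classes$snp_id),
                       counts = setNames(as.integer(
                         table(factor(classes$class,
                                      levels = snp_class_levels()))),
                         snp_class_levels())),
                  class = "snp_class_partition")
sel <- unlist(yaml::read_yaml("results/scan_summary.yaml")$selected)

folds <- kfold_split(g$sample_ids, k = 5, n_repeats = 2, seed = 71)
mc <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 5, seed = 72)
functional <- setdiff(snp_class_levels(), "intergenic")

specs <- list(
  model_spec("Base"),
  model_spec("Base + 5 SNP", fixed_snps = sel),
  model_spec("Intergenic + Functional", classes = snp_class_levels()),
  model_spec("Intergenic + 5 SNP + Functional",
             classes = snp_class_levels(), fixed_snps = sel))

res <- lapply(specs, function(sp) {
  cat("evaluating:", sp$label, "\n")
  as.data.frame(evaluate_model(sp, g, ph, folds, mc, partition = part))
})

cat("evaluating: random baseline for the 5region class size\n")
rnd <- random_snp_baseline(part$counts[["5region"]], n_samplings = 3,
                           genotypes = g, phenotypes = ph, folds = folds,
                           mcmc = mc, seed = 73)
cls5 <- evaluate_model(model_spec("5region", classes = "5region"),
                       g, ph, folds, mc, partition = part)

all_res <- rbind(do.call(rbind, res),
                 as.data.frame(cls5),
                 subset(as.data.frame(rnd), select = -sampling))
write.table(all_res, "results/cv_estimates.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
summ <- summarize_cv(all_res)
write.table(summ, "results/cv_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
print(summ[, c("model", "mean_corr", "sd_corr", "pooled_msep")])
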