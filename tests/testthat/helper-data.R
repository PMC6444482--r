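# Build a post-QC, de-duplicated, genotype-aligned study data set from a
# simulation config: the common entry point for scan and prediction tests.
make_study_data <- function(cfg, with_classes = FALSE) {
  g <- simulate_genotypes(cfg)
  gm <- if (with_classes) simulate_gene_models(cfg, g) else NULL
  sim <- simulate_phenotypes(g, cfg,
                             snp_classes = if (with_classes) gm$true_class)
  gq <- filter_snps(g)
  ph <- dedupe_records(sim$phenotypes)
  ph <- ph[match(gq$sample_ids, ph$animal_id), ]
  list(genotypes = gq, raw_genotypes = g, gene_models = gm,
       phenotypes = ph, truth = sim$truth,
       y = ph$scr,
       X = eval_class_design(ph))
}

# Small random PSD relationship matrix with unit-ish diagonal.
random_grm <- function(n, p = 2 * n, seed = 1) {
  set.seed(seed)
  S <- scale(matrix(stats::rbinom(n * p, 2, 0.3), n, p))
  K <- tcrossprod(S) / p
  (K + t(K)) / 2 + diag(1e-6, n)
}
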