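test_that("config invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_additive = 0.8, n_dominance_qtl = 5,
                          dominance_variance_fraction = 0.05),
               "variance budget")
  expect_error(sim_config(class_proportions = c("5region" = 0.7,
                                                "3region" = 0.4)),
               "sum")
  expect_error(sim_config(class_proportions = c(promoter = 0.1)),
               "named by functional class")
})

test_that("genotypes hit the requested allele frequencies and missingness", {
  cfg <- sim_config(n_individuals = 400, n_snps = 50,
                    maf_range = c(0.5, 0.5), missing_rate = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$dosages))
  f <- allele_freq(g)
  # binomial sampling error around the forced 0.5 (sd ~ 0.0177 at 2n=800)
  expect_true(all(abs(f - 0.5) < 5 * sqrt(0.25 / (2 * 400))))

  cfg2 <- sim_config(n_individuals = 300, n_snps = 200,
                     missing_rate = 0.03, seed = 3)
  g2 <- simulate_genotypes(cfg2)
  expect_gt(mean(is.na(g2$dosages)), 0.02)
  expect_lt(mean(is.na(g2$dosages)), 0.04)
})

test_that("ld_block_size = 1 gives independent adjacent SNPs", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 1000, ld_block_size = 1,
                    n_chromosomes = 1, missing_rate = 0, seed = 4)
  g <- simulate_genotypes(cfg)
  r <- sapply(seq_len(999), function(j)
    cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("SNPs within an LD block are positively correlated", {
  cfg <- sim_config(n_individuals = 800, n_snps = 200, ld_block_size = 5,
                    n_chromosomes = 1, missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  in_block <- which(seq_len(199) %% 5 != 0)  # pairs not straddling blocks
  r <- sapply(in_block, function(j) cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_gt(mean(r), 0.2)
  # block boundaries reset the process
  across <- which(seq_len(199) %% 5 == 0)
  r2 <- sapply(across, function(j) cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_lt(mean(abs(r2)), 0.15)
})

test_that("regeneration under one seed is byte-identical", {
  cfg <- sim_config(n_individuals = 120, n_snps = 150, seed = 6)
  a <- simulate_genotypes(cfg); b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  ga <- simulate_gene_models(cfg, a); gb <- simulate_gene_models(cfg, b)
  expect_identical(ga, gb)
  pa <- simulate_phenotypes(a, cfg, ga$true_class)
  pb <- simulate_phenotypes(b, cfg, gb$true_class)
  expect_identical(pa, pb)
})

test_that("phenotype variance decomposition matches the budget", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 1000,
                    n_dominance_qtl = 0, h2_additive = 0.30,
                    missing_rate = 0, seed = 7)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  expect_gte(sim$truth$realized_h2, 0.25)
  expect_lte(sim$truth$realized_h2, 0.35)
  comp <- sim$truth$components
  # additive variance is scaled exactly to the budget; residual within MC
  expect_equal(var(comp$additive), 0.30 * 4, tolerance = 1e-10)
  s2e <- 0.70 * 4
  expect_lt(abs(var(comp$residual) - s2e), 5 * s2e * sqrt(2 / 2000))
})

test_that("all effects zero reduces to mean + class + residual", {
  cfg <- sim_config(n_individuals = 300, n_snps = 100, h2_additive = 0,
                    n_dominance_qtl = 0, seed = 8, mu = 1.5)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  comp <- sim$truth$components
  first <- sim$phenotypes[seq_len(300), ]  # primary records
  recon <- 1.5 + comp$eval_class + comp$residual
  # primary records not hit by the duplicate swap match exactly
  expect_true(mean(abs(first$scr - recon) < 1e-12) > 0.85)
  expect_identical(unname(sim$truth$additive_effects),
                   rep(0, 100))
})

test_that("dominance QTLs shift carriers by d and are additive-free", {
  cfg <- sim_config(n_individuals = 1500, n_snps = 300,
                    n_dominance_qtl = 2, dominance_variance_fraction = 0.06,
                    h2_additive = 0.2, eval_class_sd = 0, missing_rate = 0,
                    seed = 9)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  y <- sim$phenotypes$scr[seq_len(1500)]
  for (q in sim$truth$dominance_qtl_ids) {
    x <- g$dosages[, q]
    d <- sim$truth$dominance_effects[[q]]
    gap <- mean(y[x >= 1]) - mean(y[x == 0])
    se <- sqrt(var(y[x >= 1]) / sum(x >= 1) + var(y[x == 0]) / sum(x == 0))
    expect_lt(abs(gap - d), 4 * se)
    # carrier-shift coding: AB and BB group means coincide
    gap12 <- mean(y[x == 1]) - mean(y[x == 2])
    se12 <- sqrt(var(y[x == 1]) / sum(x == 1) + var(y[x == 2]) / sum(x == 2))
    expect_lt(abs(gap12), 4 * se12)
    expect_identical(sim$truth$additive_effects[[q]], 0)
  }
})

test_that("a tenth of the bulls get duplicate records without ties", {
  cfg <- sim_config(n_individuals = 400, n_snps = 50, seed = 10)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 440)
  dup_ids <- names(which(table(ph$animal_id) == 2))
  expect_length(dup_ids, 40)
  for (id in dup_ids) {
    b <- ph$breedings[ph$animal_id == id]
    expect_false(b[1] == b[2])
  }
})
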