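test_that("k-fold assignments are near-equal, exhaustive and seeded", {
  ids10 <- paste0("b", 1:10)
  f <- kfold_split(ids10, k = 5, n_repeats = 1, seed = 1)
  expect_true(all(table(f$fold) == 2))

  ids11 <- paste0("b", 1:11)
  f11 <- kfold_split(ids11, k = 5, n_repeats = 1, seed = 1)
  expect_equal(sort(as.integer(table(f11$fold)), decreasing = TRUE),
               c(3, 2, 2, 2, 2))

  f3 <- kfold_split(ids11, k = 5, n_repeats = 4, seed = 9)
  # every sample tested exactly once per repeat
  expect_true(all(table(f3$repeat_id, f3$sample_id) == 1))
  expect_identical(kfold_split(ids11, 5, 4, seed = 9), f3)
  expect_false(identical(kfold_split(ids11, 5, 4, seed = 10), f3))
  expect_error(kfold_split(paste0("b", 1:3), k = 5), "at least k")
})

test_that("accuracy conversion and percent change reproduce the arithmetic", {
  expect_equal(accuracy_from_correlation(0.403, 0.30), 0.403 / sqrt(0.30))
  expect_equal(accuracy_from_correlation(0.403, 0.30, truncate_digits = 3),
               0.735)
  expect_equal(accuracy_from_correlation(0, 0.3), 0)
  expect_equal(accuracy_from_correlation(0.62, 1), 0.62)
  expect_error(accuracy_from_correlation(0.4, 0), "h2")
  expect_equal(percent_change(0.340, 0.403), 100 * 0.063 / 0.340)
  expect_equal(percent_change(2, 2), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("model specs validate their class and SNP arguments", {
  expect_error(model_spec("x", classes = "promoter"), "unknown functional")
  expect_error(model_spec("x", classes = "ncRNA", snp_ids = "s1"),
               "not both")
  sp <- model_spec("Base + 5 SNP", fixed_snps = c("s1", "s2"))
  expect_s3_class(sp, "model_spec")
  expect_identical(sp$fixed_snps, c("s1", "s2"))
})

test_that("an intercept-only, zero-variance model predicts the fold mean", {
  cfg <- sim_config(n_individuals = 200, n_snps = 150, h2_additive = 0,
                    n_dominance_qtl = 0, eval_class_sd = 0,
                    n_eval_classes = 1, missing_rate = 0, seed = 46)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  mask <- seq_along(dat$y) <= 50
  fit <- fit_rkhs(dat$y, cbind(rep(1, 200)), K,
                  mcmc_config(3000, 500, 5, seed = 47),
                  missing_mask = mask,
                  fixed_variances = list(sigma2_g = 0,
                                         sigma2_e = var(dat$y)))
  msep <- mean((dat$y[mask] - fit$predicted[mask])^2)
  # grand-mean predictor: MSEP equals the test-set variance up to the
  # mean-estimation correction
  vtest <- mean((dat$y[mask] - mean(dat$y[!mask]))^2)
  expect_equal(msep, vtest, tolerance = 0.05)
})

test_that("cross-validation summaries have the right shape and bounds", {
  cfg <- sim_config(n_individuals = 150, n_snps = 300,
                    n_dominance_qtl = 2, dominance_variance_fraction = 0.08,
                    missing_rate = 0, seed = 48)
  dat <- make_study_data(cfg)
  folds <- kfold_split(dat$genotypes$sample_ids, k = 5, n_repeats = 2,
                       seed = 49)
  mc <- mcmc_config(800, 300, 5, seed = 50)
  res <- evaluate_model(model_spec("Base"), dat$genotypes, dat$phenotypes,
                        folds, mc)
  expect_equal(nrow(res), 10)
  expect_true(all(res$corr >= -1 & res$corr <= 1, na.rm = TRUE))
  expect_true(all(res$msep >= 0))
  expect_true(all(res$n_test %in% c(30)))
  s <- attr(res, "summary")
  expect_equal(s$n_estimates, 10)
  expect_equal(s$pooled_msep,
               sum(res$msep * res$n_test) / sum(res$n_test))
})

test_that("a whole-genome random draw reproduces the Base model exactly", {
  cfg <- sim_config(n_individuals = 120, n_snps = 200, missing_rate = 0,
                    seed = 51)
  dat <- make_study_data(cfg)
  folds <- kfold_split(dat$genotypes$sample_ids, k = 4, n_repeats = 1,
                       seed = 52)
  mc <- mcmc_config(600, 200, 5, seed = 53)
  base <- evaluate_model(model_spec("Base"), dat$genotypes, dat$phenotypes,
                         folds, mc)
  p <- ncol(dat$genotypes$dosages)
  rnd <- random_snp_baseline(p, 1, dat$genotypes, dat$phenotypes, folds,
                             mc, seed = 54)
  # drawing all p SNPs is the whole genome: identical kernel, same seeds
  expect_equal(rnd$corr, base$corr, tolerance = 1e-12)
  expect_equal(rnd$msep, base$msep, tolerance = 1e-12)
})

test_that("random baselines record sampling indices and differ by seed", {
  cfg <- sim_config(n_individuals = 100, n_snps = 300, missing_rate = 0,
                    seed = 55)
  dat <- make_study_data(cfg)
  folds <- kfold_split(dat$genotypes$sample_ids, k = 5, n_repeats = 1,
                       seed = 56)
  mc <- mcmc_config(400, 100, 5, seed = 57)
  rnd <- random_snp_baseline(50, 2, dat$genotypes, dat$phenotypes, folds,
                             mc, seed = 58)
  expect_equal(nrow(rnd), 10)           # 2 samplings x 5 folds
  expect_equal(sort(unique(rnd$sampling)), c(1, 2))
  d1 <- attr(rnd, "snp_draws")
  rnd2 <- random_snp_baseline(50, 2, dat$genotypes, dat$phenotypes, folds,
                              mc, seed = 59)
  expect_false(identical(d1, attr(rnd2, "snp_draws")))
})
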