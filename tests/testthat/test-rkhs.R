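test_that("mcmc schedules are validated and bookkeeping is exact", {
  expect_error(mcmc_config(burn_in = 5000, n_iter = 4000), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(prior_df = 0), "prior_df")
  expect_equal(retained_samples(mcmc_config(1300, 300, 7)), 142)
  expect_equal(nrow(fit_rkhs(rnorm(30), cbind(rep(1, 30)),
                             build_kernel(matrix(rnorm(30 * 40), 30)),
                             mcmc_config(600, 100, 5, seed = 1)
                             )$var_samples), 100)
})

test_that("fixed-variance Gibbs matches the closed-form BLUP/ridge oracle", {
  cfg <- sim_config(n_individuals = 120, n_snps = 300, n_dominance_qtl = 0,
                    missing_rate = 0, seed = 33)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  s2g <- 1.2; s2e <- 2.8
  fit <- fit_rkhs(dat$y, dat$X, K,
                  mcmc_config(22000, 2000, 2, seed = 34),
                  fixed_variances = list(sigma2_g = s2g, sigma2_e = s2e))
  n <- length(dat$y)
  V <- K$values * s2g + diag(s2e, n)
  Vi <- solve(V)
  bh <- solve(t(dat$X) %*% Vi %*% dat$X, t(dat$X) %*% Vi %*% dat$y)
  g_blup <- drop(s2g * K$values %*% Vi %*% (dat$y - dat$X %*% bh))
  # agreement within Monte-Carlo error of the 10k retained samples
  expect_gt(cor(fit$g_mean[[1]], g_blup), 0.999)
  expect_lt(mean(abs(fit$g_mean[[1]] - g_blup)), 0.02)
  expect_lt(max(abs(fit$g_mean[[1]] - g_blup)), 0.06)
})

test_that("zero genetic variance reduces predictions to the GLS fit", {
  cfg <- sim_config(n_individuals = 100, n_snps = 150, n_dominance_qtl = 0,
                    missing_rate = 0, seed = 35)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  fit <- fit_rkhs(dat$y, dat$X, K, mcmc_config(4000, 500, 2, seed = 36),
                  fixed_variances = list(sigma2_g = 0, sigma2_e = 3))
  ols <- drop(dat$X %*% qr.solve(dat$X, dat$y))
  expect_lt(mean(abs(fit$predicted - ols)), 0.05)
  expect_true(all(fit$g_mean[[1]] == 0))
})

test_that("duplicated kernels split the variance but keep the predictions", {
  cfg <- sim_config(n_individuals = 150, n_snps = 400, n_dominance_qtl = 0,
                    missing_rate = 0, seed = 37)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  mc <- mcmc_config(8000, 1000, 2, seed = 38)
  one <- fit_rkhs(dat$y, dat$X, K, mc)
  two <- fit_rkhs(dat$y, dat$X, list(a = K, b = K), mc)
  expect_gt(cor(one$predicted, two$predicted), 0.99)
  # two independent chains: posterior-mean predictions agree within MC
  # error (phenotype SD is about 2 here)
  expect_lt(mean(abs(one$predicted - two$predicted)), 0.15)
  expect_equal(unname(sum(two$sigma2_g)), unname(one$sigma2_g),
               tolerance = 0.25)
})

test_that("chains are bit-identical under one seed", {
  cfg <- sim_config(n_individuals = 60, n_snps = 100, seed = 39)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  mc <- mcmc_config(500, 100, 2, seed = 40)
  a <- fit_rkhs(dat$y, dat$X, K, mc)
  b <- fit_rkhs(dat$y, dat$X, K, mc)
  expect_identical(a$var_samples, b$var_samples)
  expect_identical(a$predicted, b$predicted)
  c <- fit_rkhs(dat$y, dat$X, K, mcmc_config(500, 100, 2, seed = 41))
  expect_false(identical(a$var_samples, c$var_samples))
})

test_that("held-out phenotypes are ignored by the likelihood", {
  cfg <- sim_config(n_individuals = 120, n_snps = 200, n_dominance_qtl = 0,
                    missing_rate = 0, seed = 42)
  dat <- make_study_data(cfg)
  K <- grm(dat$genotypes)
  mask <- seq_along(dat$y) <= 30
  mc <- mcmc_config(1500, 500, 5, seed = 43)
  a <- fit_rkhs(dat$y, dat$X, K, mc, missing_mask = mask)
  y2 <- dat$y
  y2[mask] <- 999  # arbitrary values under the mask must not matter
  b <- fit_rkhs(y2, dat$X, K, mc, missing_mask = mask)
  expect_identical(a$predicted, b$predicted)
  expect_identical(a$var_samples, b$var_samples)
})

test_that("degenerate inputs are rejected", {
  y <- rnorm(20)
  K <- build_kernel(matrix(rnorm(20 * 30), 20))
  bad <- K; bad$values <- diag(c(rep(1, 19), -1))
  expect_error(fit_rkhs(y, cbind(rep(1, 20)), bad, mcmc_config(200, 50)),
               "positive semi-definite")
  expect_error(fit_rkhs(y, cbind(1, rep(1, 20)), K, mcmc_config(200, 50)),
               "full column rank")
  expect_error(fit_rkhs(rep(NA_real_, 20), cbind(rep(1, 20)), K,
                        mcmc_config(200, 50),
                        missing_mask = rep(TRUE, 20)),
               "no observed phenotypes")
})

test_that("major markers augment the design and collinear columns drop", {
  cfg <- sim_config(n_individuals = 80, n_snps = 60, missing_rate = 0,
                    seed = 44)
  g <- simulate_genotypes(cfg)
  X <- cbind(intercept = rep(1, 80))
  ids <- g$snp_meta$id[1:5]
  Xa <- add_fixed_markers(X, g, ids)
  expect_equal(ncol(Xa), 6)
  expect_identical(colnames(Xa)[-1], ids)
  expect_identical(add_fixed_markers(X, g, character(0)), X)
  # a marker twice: second copy is collinear
  expect_warning(Xb <- add_fixed_markers(X, g, c(ids[1], ids[1])),
                 "collinear")
  expect_equal(ncol(Xb), 2)
  # constant column dropped
  g$dosages[, 2] <- 0L
  expect_warning(Xc <- add_fixed_markers(X, g, g$snp_meta$id[2]),
                 "constant")
  expect_equal(ncol(Xc), 1)
  expect_error(add_fixed_markers(X, g, "nope"), "unknown SNP")
})

test_that("geweke flags non-stationarity and passes stationary chains", {
  set.seed(45)
  expect_equal(geweke_diagnostic(rep(3.2, 500)), 0)
  expect_warning(short <- geweke_diagnostic(rnorm(50)), "too short")
  expect_true(is.na(short))
  expect_gt(abs(geweke_diagnostic(c(rnorm(1000), rnorm(1000, 3)))), 4)
  z <- replicate(200, geweke_diagnostic(rnorm(1000)))
  expect_gt(mean(abs(z) < 2), 0.9)
})
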