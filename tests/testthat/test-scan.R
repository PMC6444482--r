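dense_restricted_ll <- function(h, y, X, G) {
  # independent dense evaluation of the restricted likelihood, profiled
  # over the total variance at a given ratio h
  n <- length(y); q <- ncol(X)
  V <- h * G + (1 - h) * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  s2 <- drop(t(r) %*% Vi %*% r) / (n - q)
  Vs <- V * s2
  Vsi <- Vi / s2
  XtVsX <- t(X) %*% Vsi %*% X
  -0.5 * (determinant(Vs)$modulus + determinant(XtVsX)$modulus +
            drop(t(r) %*% Vsi %*% r))
}

test_that("REML optimum matches a dense grid search on a toy system", {
  set.seed(25)
  n <- 6
  G <- random_grm(n, 20, seed = 25)
  X <- cbind(1, c(0, 0, 1, 1, 0, 1))
  u <- drop(chol(G + diag(1e-8, n)) %*% rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + u + rnorm(n, 0, 0.5)
  fit <- fit_null_model(y, X, G)
  grid <- seq(0.01, 0.99, by = 0.01)
  ll_grid <- vapply(grid, function(h) dense_restricted_ll(h, y, X, G),
                    numeric(1))
  ll_fit <- dense_restricted_ll(fit$h2, y, X, G)
  expect_gte(ll_fit, max(ll_grid) - 1e-6)
})

test_that("pure noise yields a near-zero heritability estimate", {
  set.seed(26)
  n <- 400
  G <- random_grm(n, 200, seed = 26)
  y <- rnorm(n)
  fit <- fit_null_model(y, cbind(rep(1, n)), G)
  expect_lt(fit$h2, 0.1)
})

test_that("non-PSD G and rank-deficient X are rejected", {
  expect_error(fit_null_model(rnorm(3), cbind(rep(1, 3)),
                              diag(c(1, 1, -1))),
               "positive semi-definite")
  n <- 20
  G <- random_grm(n, seed = 27)
  X <- cbind(rep(1, n), rep(1, n))
  expect_error(fit_null_model(rnorm(n), X, G), "full column rank")
})

test_that("carrier coding maps dosages and mean-imputes missing", {
  expect_equal(dominance_code(c(0, 1, 2)), c(0, 1, 1))
  expect_equal(dominance_code(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(dominance_code(c(0, 2, NA)), c(0, 1, 0.5))
  m <- dominance_code(cbind(a = c(0, 1, NA), b = c(2, 2, 0)))
  expect_equal(unname(m[, "a"]), c(0, 1, 0.5))
  expect_equal(unname(m[, "b"]), c(1, 1, 0))
})

test_that("score_snp equals a dense GLS oracle to 10+ significant figures", {
  set.seed(28)
  n <- 50
  G <- random_grm(n, 100, seed = 28)
  X <- model.matrix(~ factor(sample(1:4, n, TRUE)))
  y <- drop(chol(G + diag(0.5, n)) %*% rnorm(n)) + rnorm(n)
  fit <- fit_null_model(y, X, G)
  V0 <- fit$sigma2_u * G + diag(fit$sigma2_e, n)
  Vi <- solve(V0)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% bh
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  for (i in 1:10) {
    x <- dominance_code(rbinom(n, 2, runif(1, 0.1, 0.5)))
    if (sd(x) == 0) next
    z <- score_snp(x, fit)
    z_oracle <- drop(t(x) %*% Vi %*% r) / sqrt(drop(t(x) %*% P %*% x))
    expect_equal(z, z_oracle, tolerance = 1e-10)
  }
})

test_that("with V0 proportional to identity the score is the OLS score", {
  set.seed(29)
  n <- 40
  G <- diag(n)  # V0 = (s2u + s2e) I
  X <- cbind(rep(1, n))
  y <- rnorm(n)
  fit <- fit_null_model(y, X, G)
  x <- dominance_code(rbinom(n, 2, 0.3))
  s2 <- fit$sigma2_u + fit$sigma2_e
  xc <- x - mean(x)                       # adjusted for the intercept
  z_ols <- sum(xc * (y - mean(y))) / sqrt(sum(xc^2) * s2)
  expect_equal(score_snp(x, fit), z_ols, tolerance = 1e-10)
})

test_that("constant carrier codes score zero and are flagged", {
  set.seed(30)
  n <- 30
  fit <- fit_null_model(rnorm(n), cbind(rep(1, n)), random_grm(n, seed = 30))
  z <- score_snp(rep(1, n), fit)
  expect_equal(unname(as.numeric(z)), 0)
  expect_true(attr(z, "monomorphic"))
})

test_that("genomic control recovers scale inflation and truncates below 1", {
  set.seed(31)
  z <- rnorm(10000)
  gc0 <- genomic_control(z)
  expect_gte(gc0$lambda, 0.95); expect_lte(gc0$lambda, 1.05)
  gc2 <- genomic_control(z * sqrt(2))
  expect_equal(gc2$lambda, 2, tolerance = 0.05)
  expect_equal(gc2$z_corrected, z * sqrt(2) / sqrt(gc2$lambda),
               tolerance = 1e-12)
  expect_lt(max(abs(gc2$z_corrected - z)), 0.05 * max(abs(z)))
  gc_zero <- genomic_control(rep(0, 200))
  expect_equal(gc_zero$lambda, 1)
  expect_true(all(gc_zero$z_corrected == 0))
  expect_warning(gc_small <- genomic_control(rnorm(50)), "fewer than 100")
  expect_equal(gc_small$lambda, 1)
})

test_that("a strong dominance QTL is found genome-wide", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 1000,
                    n_dominance_qtl = 1, dominance_variance_fraction = 0.05,
                    seed = 32)
  dat <- make_study_data(cfg)
  fit <- fit_null_model(dat$y, dat$X, grm(dat$genotypes))
  scan <- scan_dominance(dat$genotypes, fit)
  expect_true(dat$truth$dominance_qtl_ids %in% attr(scan, "selected"))
  expect_true(all(scan$p_corrected > 0 & scan$p_corrected <= 1))
  expect_gt(attr(scan, "lambda_gc"), 0)
})

test_that("alpha = 0 selects nothing", {
  df <- data.frame(snp_id = paste0("s", 1:200),
                   p_corrected = runif(200, 1e-30, 1))
  expect_length(select_major_snps(df, alpha = 0), 0)
  top <- select_major_snps(df, alpha = 1)
  expect_equal(top[1], df$snp_id[which.min(df$p_corrected)])
})
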