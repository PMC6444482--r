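#' MCMC configuration for the RKHS Gibbs sampler
#'
#' The full-scale schedule of the study design is 100,000 iterations,
#' 30,000 burn-in, thinning 5 (14,000 retained samples); the default here
#' is a desk-scale chain of 12,000 / 2,000 / 5 suitable for repeated
#' cross-validation.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before retention (`< n_iter`).
#' @param thin Retain every `thin`-th post-burn-in sample.
#' @param seed RNG seed: same seed and inputs give bit-identical chains.
#' @param prior_df Degrees of freedom of every scaled-inverse-chi-square
#'   variance prior.
#' @param prior_R2 Fraction of phenotypic variance assigned a priori to
#'   genetics (split equally across kernels); sets the prior scales so the
#'   prior mode matches this split.
#' @return A validated list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 12000, burn_in = 2000, thin = 5,
                        seed = 1, prior_df = 5, prior_R2 = 0.5) {
  n_iter <- assert_count(n_iter, "n_iter", min = 1)
  burn_in <- assert_count(burn_in, "burn_in", min = 0)
  thin <- assert_count(thin, "thin", min = 1)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (prior_df <= 0) stop("prior_df must be positive")
  assert_fraction(prior_R2, "prior_R2", 1e-6, 1 - 1e-6)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), prior_df = prior_df,
                 prior_R2 = prior_R2),
            class = "mcmc_config")
}

#' Number of retained posterior samples implied by a schedule
#'
#' `floor((n_iter - burn_in) / thin)`; the study-scale schedule
#' 100,000 / 30,000 / 5 yields exactly 14,000.
#'
#' @param mcmc An [mcmc_config()].
#' @return Integer count of retained samples.
#' @export
retained_samples <- function(mcmc) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
}

#' Bayesian RKHS regression by Gibbs sampling
#'
#' Fits \eqn{y = Xb + \sum_j g_j + e} with per-kernel genetic values
#' \eqn{g_j \sim N(0, K_j \sigma^2_{gj})}, flat prior on the fixed effects
#' and scaled-inverse-chi-square priors on all variances. Each kernel is
#' eigendecomposed once (\eqn{K_j = U_j D_j U_j'}, eigenvalues below 1e-10
#' truncated) and the genetic values are reparameterized as
#' \eqn{g_j = U_j \delta_j} with independent \eqn{\delta_{jk} \sim
#' N(0, d_{jk}\sigma^2_{gj})}, so every update is element-wise.
#' Phenotypes flagged in `missing_mask` are data-augmented each iteration
#' from their conditional normal and ignored in the likelihood summaries,
#' which is how held-out animals are predicted.
#'
#' With a linear kernel \eqn{K = SS'/p} the posterior mean of \eqn{g}
#' equals the GBLUP solution; with variances held fixed
#' (`fixed_variances`) the sampler draws from the conditional posterior
#' whose mean is the kernel ridge solution minimising
#' \eqn{(y - K\alpha)'(y - K\alpha) + \lambda \alpha' K \alpha}.
#'
#' @param y Phenotype vector (length n); entries under `missing_mask` may
#'   be `NA`.
#' @param X Fixed-effects design matrix (n x q), full column rank.
#' @param kernels A `kernel_matrix` or (named) list of them, sharing the
#'   sample order of `y`.
#' @param mcmc An [mcmc_config()].
#' @param missing_mask Logical vector: `TRUE` marks phenotypes to treat as
#'   unknown (test animals). Defaults to `is.na(y)`.
#' @param fixed_variances Optional list with elements `sigma2_g` (scalar
#'   or per-kernel vector) and `sigma2_e`; when supplied the variance
#'   updates are skipped (conditional mode).
#' @return Object of class `rkhs_fit`: posterior means/SDs of fixed
#'   effects, per-kernel genetic values and variances, residual variance,
#'   per-animal predictions (posterior mean of \eqn{Xb + \sum g_j}),
#'   retained variance samples, and a Geweke z per variance chain.
#' @export
fit_rkhs <- function(y, X, kernels, mcmc = mcmc_config(),
                     missing_mask = NULL, fixed_variances = NULL) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  if (inherits(kernels, "kernel_matrix")) kernels <- list(k1 = kernels)
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- paste0("k", seq_along(kernels))
  nk <- length(kernels)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  ids0 <- kernels[[1]]$sample_ids
  for (k in kernels) {
    stopifnot(inherits(k, "kernel_matrix"), nrow(k$values) == n)
    if (!identical(k$sample_ids, ids0))
      stop("kernels must share one sample order")
  }
  missing_mask <- missing_mask %||% is.na(y)
  stopifnot(length(missing_mask) == n)
  obs <- !missing_mask
  if (!any(obs)) stop("no observed phenotypes")
  if (anyNA(y[obs])) stop("NA phenotype outside missing_mask")

  eg <- lapply(kernels, kernel_eigen)     # errors if not PSD
  set.seed(mcmc$seed)

  vary <- stats::var(y[obs])
  df0 <- mcmc$prior_df
  Sg0 <- mcmc$prior_R2 * vary / nk * (df0 + 2) / df0
  Se0 <- (1 - mcmc$prior_R2) * vary * (df0 + 2) / df0

  fixed <- !is.null(fixed_variances)
  if (fixed) {
    s2g <- rep(fixed_variances$sigma2_g, length.out = nk)
    s2e <- fixed_variances$sigma2_e
  } else {
    s2g <- rep(mcmc$prior_R2 * vary / nk, nk)
    s2e <- (1 - mcmc$prior_R2) * vary
  }

  ycur <- y
  ycur[missing_mask] <- mean(y[obs])
  XtX <- crossprod(X)
  cXtX <- chol(XtX)
  b <- drop(backsolve(cXtX, forwardsolve(t(cXtX), crossprod(X, ycur))))
  delta <- lapply(eg, function(e) rep(0, length(e$values)))
  gvals <- lapply(eg, function(e) rep(0, n))
  gsum <- rep(0, n)

  n_keep <- retained_samples(mcmc)
  var_samp <- matrix(NA_real_, n_keep, nk + 1,
                     dimnames = list(NULL, c(paste0("sigma2_g_",
                                                    names(kernels)),
                                             "sigma2_e")))
  b_sum <- b_sq <- rep(0, ncol(X))
  g_sum <- g_sq <- lapply(seq_len(nk), function(i) rep(0, n))
  pred_sum <- pred_sq <- rep(0, n)
  kept <- 0L

  for (it in seq_len(mcmc$n_iter)) {
    # fixed effects: flat prior
    rhs <- crossprod(X, ycur - gsum)
    bhat <- backsolve(cXtX, forwardsolve(t(cXtX), rhs))
    b <- drop(bhat + backsolve(cXtX, stats::rnorm(ncol(X))) * sqrt(s2e))
    xb <- drop(X %*% b)
    e <- ycur - xb - gsum

    # per-kernel genetic values, element-wise in the eigenbasis
    for (j in seq_len(nk)) {
      if (s2g[j] <= 0) {
        gsum <- gsum - gvals[[j]]
        e <- e + gvals[[j]]
        delta[[j]][] <- 0
        gvals[[j]] <- rep(0, n)
        next
      }
      rj <- e + gvals[[j]]
      t_j <- drop(crossprod(eg[[j]]$vectors, rj))
      prec <- 1 / s2e + 1 / (eg[[j]]$values * s2g[j])
      mu_j <- (t_j / s2e) / prec
      delta[[j]] <- mu_j + stats::rnorm(length(mu_j)) / sqrt(prec)
      gnew <- drop(eg[[j]]$vectors %*% delta[[j]])
      gsum <- gsum - gvals[[j]] + gnew
      e <- rj - gnew
      gvals[[j]] <- gnew
      if (!fixed) {
        ss <- sum(delta[[j]]^2 / eg[[j]]$values)
        s2g[j] <- (ss + df0 * Sg0) /
          stats::rchisq(1, length(delta[[j]]) + df0)
      }
    }

    if (!fixed)
      s2e <- (sum(e^2) + df0 * Se0) / stats::rchisq(1, n + df0)
    if (!all(is.finite(c(b, s2g, s2e))))
      stop("sampler diverged (non-finite state) at iteration ", it)

    # data augmentation for held-out phenotypes
    if (any(missing_mask)) {
      mu_miss <- xb[missing_mask] + gsum[missing_mask]
      ycur[missing_mask] <- mu_miss +
        stats::rnorm(sum(missing_mask)) * sqrt(s2e)
    }

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
      kept <- kept + 1L
      var_samp[kept, ] <- c(s2g, s2e)
      b_sum <- b_sum + b; b_sq <- b_sq + b^2
      syst <- xb + gsum
      pred_sum <- pred_sum + syst; pred_sq <- pred_sq + syst^2
      for (j in seq_len(nk)) {
        g_sum[[j]] <- g_sum[[j]] + gvals[[j]]
        g_sq[[j]] <- g_sq[[j]] + gvals[[j]]^2
      }
    }
  }

  post_sd <- function(s, sq, m) sqrt(pmax(sq / m - (s / m)^2, 0))
  gw <- if (kept >= 100) apply(var_samp, 2, geweke_diagnostic)
        else stats::setNames(rep(NA_real_, nk + 1), colnames(var_samp))
  structure(list(
    b_mean = b_sum / kept, b_sd = post_sd(b_sum, b_sq, kept),
    g_mean = lapply(g_sum, function(s) s / kept),
    g_sd = mapply(post_sd, g_sum, g_sq, MoreArgs = list(m = kept),
                  SIMPLIFY = FALSE),
    sigma2_g = colMeans(var_samp[, seq_len(nk), drop = FALSE]),
    sigma2_e = mean(var_samp[, nk + 1]),
    var_samples = var_samp,
    predicted = pred_sum / kept,
    predicted_sd = post_sd(pred_sum, pred_sq, kept),
    geweke_z = gw,
    kernel_names = names(kernels),
    n_retained = kept, mcmc = mcmc,
    missing_mask = missing_mask),
    class = "rkhs_fit")
}

#' @export
print.rkhs_fit <- function(x, ...) {
  nk <- length(x$kernel_names)
  cat(sprintf("rkhs_fit: %d kernel(s), %d retained samples\n",
              nk, x$n_retained))
  cat("  sigma2_g:", paste(sprintf("%s = %.4f", x$kernel_names,
                                   x$sigma2_g), collapse = ", "), "\n")
  cat(sprintf("  sigma2_e = %.4f\n", x$sigma2_e))
  cat("  geweke |z|:",
      paste(sprintf("%.2f", abs(x$geweke_z)), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior-summary table of an RKHS fit
#'
#' @param object An `rkhs_fit`.
#' @param ... Unused.
#' @return Data frame (`parameter`, `mean`, `sd`, `geweke_z`).
#' @export
summary.rkhs_fit <- function(object, ...) {
  nk <- length(object$kernel_names)
  data.frame(
    parameter = c(paste0("sigma2_g_", object$kernel_names), "sigma2_e"),
    mean = c(object$sigma2_g, object$sigma2_e),
    sd = apply(object$var_samples, 2, stats::sd),
    geweke_z = object$geweke_z,
    row.names = NULL)
}

#' Append major markers to a fixed-effects design
#'
#' Adds one carrier-coded (0/1, mean-imputed) column per selected SNP.
#' Constant columns are dropped with a warning, as are columns collinear
#' with the design built so far (rank check).
#'
#' @param X Fixed-effects design matrix.
#' @param genotypes A [genotype_matrix()] in the same sample order.
#' @param snp_ids SNP ids to add (may be empty).
#' @return The augmented design matrix; added columns are named by SNP id.
#' @export
add_fixed_markers <- function(X, genotypes, snp_ids) {
  X <- as.matrix(X)
  if (length(snp_ids) == 0) return(X)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  miss <- setdiff(snp_ids, genotypes$snp_meta$id)
  if (length(miss)) stop("unknown SNP id(s): ", paste(miss, collapse = ", "))
  for (id in snp_ids) {
    cx <- dominance_code(genotypes$dosages[, id])
    if (stats::sd(cx) == 0) {
      warning("marker ", id, " is constant under carrier coding; dropped")
      next
    }
    cand <- cbind(X, cx)
    if (qr(cand)$rank > qr(X)$rank) {
      colnames(cand)[ncol(cand)] <- id
      X <- cand
    } else {
      warning("marker ", id, " is collinear with the design; dropped")
    }
  }
  X
}
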