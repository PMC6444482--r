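#' Repeated k-fold assignments
#'
#' Randomly partitions the samples into `k` near-equal folds (sizes differ
#' by at most 1), independently for each repeat; deterministic under
#' `seed`. Every sample appears in the test set exactly once per repeat.
#'
#' @param sample_ids Character vector of sample ids.
#' @param k Number of folds (>= 2).
#' @param n_repeats Number of independent repetitions.
#' @param seed RNG seed.
#' @return Data frame (`repeat_id`, `fold`, `sample_id`).
#' @export
kfold_split <- function(sample_ids, k = 5, n_repeats = 10, seed = 1) {
  n <- length(sample_ids)
  k <- assert_count(k, "k", min = 2)
  n_repeats <- assert_count(n_repeats, "n_repeats", min = 1)
  if (n < k) stop("need at least k samples for k folds")
  set.seed(as.integer(seed))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    shuffled <- sample(sample_ids)
    out[[r]] <- data.frame(repeat_id = r,
                           fold = rep(seq_len(k), times = sizes),
                           sample_id = shuffled,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Specify a prediction model
#'
#' A model is one or more linear genomic kernels plus optional major
#' markers fitted as fixed effects:
#' * whole genome (`classes = NULL`, `snp_ids = NULL`): one kernel from
#'   all SNPs (the 'Base' model; add `fixed_snps` for 'Base + 5 SNP');
#' * `classes`: one kernel per named functional class (a single class
#'   gives a single-kernel class model, several give a multi-kernel
#'   model such as 'Intergenic + Functional');
#' * `snp_ids`: one kernel from an explicit SNP set (random-set
#'   baselines).
#'
#' @param label Human-readable model label.
#' @param classes Optional character vector of functional classes.
#' @param snp_ids Optional explicit SNP ids for a single kernel.
#' @param fixed_snps SNP ids entered as 0/1 carrier-coded fixed effects.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(label, classes = NULL, snp_ids = NULL,
                       fixed_snps = character(0)) {
  if (!is.null(classes) && !is.null(snp_ids))
    stop("give either classes or snp_ids, not both")
  if (!is.null(classes) &&
      !all(classes %in% snp_class_levels()))
    stop("unknown functional class in `classes`")
  structure(list(label = label, classes = classes, snp_ids = snp_ids,
                 fixed_snps = as.character(fixed_snps)),
            class = "model_spec")
}

# Resolve a model_spec to kernels + augmented design for a data set.
.resolve_model <- function(spec, genotypes, X, partition = NULL,
                           scale = "binomial") {
  if (!is.null(spec$classes)) {
    if (is.null(partition)) stop("class model requires a partition")
    ks <- build_class_kernels(genotypes, partition, scale = scale)
    missing_cls <- setdiff(spec$classes, names(ks))
    if (length(missing_cls))
      warning("empty class(es) skipped: ",
              paste(missing_cls, collapse = ", "))
    kernels <- ks[intersect(spec$classes, names(ks))]
    if (length(kernels) == 0) stop("no usable kernels for model ",
                                   spec$label)
  } else if (!is.null(spec$snp_ids)) {
    kernels <- list(set = grm(genotypes, snp_subset = spec$snp_ids,
                              scale = scale))
  } else {
    kernels <- list(genome = grm(genotypes, scale = scale))
  }
  Xa <- add_fixed_markers(X, genotypes, spec$fixed_snps)
  list(kernels = kernels, X = Xa)
}

#' Fixed-effects design for the evaluation classes
#'
#' Intercept plus one contrast per additional evaluation release class;
#' a single class degenerates to the intercept alone.
#'
#' @param phenotypes Data frame with an `evaluation` column.
#' @return Model matrix with one row per record.
#' @export
eval_class_design <- function(phenotypes) {
  if (length(unique(phenotypes$evaluation)) < 2)
    return(cbind(`(Intercept)` = rep(1, nrow(phenotypes))))
  stats::model.matrix(~ factor(evaluation), data = phenotypes)
}

#' Cross-validated evaluation of a prediction model
#'
#' For every repeat and fold, the test animals' phenotypes are masked and
#' the model is refit by [fit_rkhs()] (fixed effects, including the
#' evaluation classes, are re-estimated on each training set through the
#' masking); predictive performance on the test set is summarised by the
#' Pearson correlation between observed and predicted phenotypes (CORR)
#' and the mean squared error of prediction (MSEP, total squared error
#' over all test predictions divided by their number). Folds in which the
#' predictions are constant give an undefined correlation, recorded as
#' `NA` with a warning and excluded from the summary mean.
#'
#' @param spec A [model_spec()].
#' @param genotypes A [genotype_matrix()] (post-QC).
#' @param phenotypes De-duplicated phenotype data frame (`animal_id`,
#'   `scr`, `evaluation`, `breedings`), one row per genotyped animal.
#' @param folds Fold assignments from [kfold_split()].
#' @param mcmc An [mcmc_config()]; the per-fit seed is varied
#'   deterministically per repeat and fold.
#' @param partition Optional `snp_class_partition` (required for class
#'   models).
#' @param scale Kernel standardization convention.
#' @return Object of class `cv_result`: data frame (`model`, `repeat_id`,
#'   `fold`, `n_test`, `corr`, `msep`) with a `summary` attribute
#'   (mean/SD of CORR and MSEP over all estimates).
#' @export
evaluate_model <- function(spec, genotypes, phenotypes, folds,
                           mcmc = mcmc_config(), partition = NULL,
                           scale = "binomial") {
  stopifnot(inherits(spec, "model_spec"),
            inherits(genotypes, "genotype_matrix"))
  ids <- genotypes$sample_ids
  ph <- phenotypes[match(ids, phenotypes$animal_id), , drop = FALSE]
  if (anyNA(ph$animal_id))
    stop("phenotypes must cover every genotyped animal exactly once ",
         "(run dedupe_records first)")
  y <- ph$scr
  X <- eval_class_design(ph)
  resolved <- .resolve_model(spec, genotypes, X, partition, scale)
  resolved$kernels <- lapply(resolved$kernels, cache_kernel_eigen)

  rows <- list()
  for (r in sort(unique(folds$repeat_id))) {
    fr <- folds[folds$repeat_id == r, ]
    for (f in sort(unique(fr$fold))) {
      test_ids <- fr$sample_id[fr$fold == f]
      mask <- ids %in% test_ids
      fit_mcmc <- mcmc
      fit_mcmc$seed <- (mcmc$seed + 1000L * r + f) %%
        .Machine$integer.max
      fit <- fit_rkhs(y, resolved$X, resolved$kernels, fit_mcmc,
                      missing_mask = mask)
      yhat <- fit$predicted[mask]
      yobs <- y[mask]
      corr <- if (stats::sd(yhat) == 0) {
        warning("constant predictions in repeat ", r, " fold ", f,
                "; correlation undefined")
        NA_real_
      } else stats::cor(yobs, yhat)
      rows[[length(rows) + 1L]] <-
        data.frame(model = spec$label, repeat_id = r, fold = f,
                   n_test = sum(mask), corr = corr,
                   msep = mean((yobs - yhat)^2),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  structure(res, summary = summarize_cv(res),
            class = c("cv_result", "data.frame"))
}

#' Summary of cross-validation estimates
#'
#' @param res A `cv_result` data frame (possibly several models bound
#'   together).
#' @return Data frame per model: mean/SD CORR (undefined correlations
#'   excluded, with a count), mean/SD MSEP, and the pooled MSEP
#'   (total SSE over all test predictions / total predictions).
#' @export
summarize_cv <- function(res) {
  sp <- split(as.data.frame(res), res$model)
  out <- lapply(sp, function(d) {
    data.frame(model = d$model[1],
               n_estimates = nrow(d),
               n_undefined_corr = sum(is.na(d$corr)),
               mean_corr = mean(d$corr, na.rm = TRUE),
               sd_corr = stats::sd(d$corr, na.rm = TRUE),
               mean_msep = mean(d$msep),
               sd_msep = stats::sd(d$msep),
               pooled_msep = sum(d$msep * d$n_test) / sum(d$n_test),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Random-SNP-set baselines for a class size
#'
#' Draws `n_samplings` independent SNP sets of `class_size` uniformly
#' without replacement from the genome and evaluates each with the same
#' cross-validation design; at the study scale (10 samplings x 5 folds x
#' 10 repeats) this yields 500 estimates.
#'
#' @param class_size Number of SNPs per random set (`<= p`).
#' @param n_samplings Number of independent random sets.
#' @param genotypes,phenotypes,folds,mcmc,scale As in [evaluate_model()].
#' @param seed Seed for the SNP draws.
#' @return A `cv_result` with an extra `sampling` column.
#' @export
random_snp_baseline <- function(class_size, n_samplings, genotypes,
                                phenotypes, folds, mcmc = mcmc_config(),
                                seed = 1, scale = "binomial") {
  p <- ncol(genotypes$dosages)
  class_size <- assert_count(class_size, "class_size", min = 2)
  if (class_size > p) stop("class_size exceeds the number of SNPs")
  set.seed(as.integer(seed))
  # draws are sets: keep genome order so a full-size draw is exactly the
  # whole-genome kernel
  draws <- lapply(seq_len(n_samplings), function(i) {
    ids <- sample(genotypes$snp_meta$id, class_size)
    ids[order(match(ids, genotypes$snp_meta$id))]
  })
  rows <- lapply(seq_len(n_samplings), function(i) {
    spec <- model_spec(sprintf("random_set_%02d", i), snp_ids = draws[[i]])
    r <- evaluate_model(spec, genotypes, phenotypes, folds, mcmc,
                        scale = scale)
    r$sampling <- i
    r$model <- "random_set"
    as.data.frame(r)
  })
  res <- do.call(rbind, rows)
  structure(res, summary = summarize_cv(res), snp_draws = draws,
            class = c("cv_result", "data.frame"))
}

#' Selection accuracy from a predictive correlation
#'
#' Converts the predictive correlation between observed and predicted
#' phenotypes into an accuracy of selection on the genetic scale by
#' dividing by the square root of the heritability.
#'
#' @param corr Predictive correlation.
#' @param h2 Trait heritability, in (0, 1].
#' @param truncate_digits Optionally truncate (not round) the result to
#'   this many decimals, the convention under which 0.403 / sqrt(0.30) is
#'   reported as 0.735.
#' @return `corr / sqrt(h2)`, optionally truncated.
#' @export
accuracy_from_correlation <- function(corr, h2, truncate_digits = NULL) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must be in (0, 1]")
  acc <- corr / sqrt(h2)
  if (!is.null(truncate_digits))
    acc <- trunc(acc * 10^truncate_digits) / 10^truncate_digits
  acc
}

#' Percent change from a to b
#'
#' @param a Reference value (non-zero).
#' @param b New value.
#' @return `100 * (b - a) / a`.
#' @export
percent_change <- function(a, b) {
  if (any(a == 0)) stop("percent change undefined for a = 0")
  100 * (b - a) / a
}
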