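#' Simulate SCR-like phenotype records with a known truth ledger
#'
#' Generates per-bull sire-conception-rate values
#' \deqn{y_i = \mu + c_{e(i)} + \sum_j s_{ij} a_j +
#'       \sum_q d_q 1[x_{iq} \ge 1] + e_i,}
#' where \eqn{c} are evaluation-class effects, \eqn{s_{ij}} are
#' standardized dosages with additive effects \eqn{a_j} scaled so the
#' additive variance equals `h2_additive * total_variance`, each dominance
#' QTL is a carrier shift (AA vs \{AB, BB\}) contributing
#' `dominance_variance_fraction * total_variance`, and the residual fills
#' the remaining budget. Dominance QTL carry no additive effect, so their
#' AB and BB genotype means coincide (pure dominance in the carrier
#' coding). When `snp_classes` is supplied, per-SNP additive effect
#' variances are multiplied by `config$class_enrichment` for the SNP's
#' functional class, concentrating signal in enriched classes.
#'
#' Each bull receives a breeding count, and a random 10% of bulls get a
#' duplicate record from a different evaluation with a distinct breeding
#' count and a noisier SCR value; the record with most breedings carries
#' the model value, so record de-duplication is exercised deterministically.
#'
#' @param genotypes A [genotype_matrix()].
#' @param config The [sim_config()] used to generate it.
#' @param snp_classes Optional named character vector (SNP id ->
#'   functional class), e.g. `simulate_gene_models(config)$true_class`;
#'   when `NULL` all SNPs share one effect-variance.
#' @return A list of class `scr_simulation`: `phenotypes` (data frame
#'   `animal_id`, `scr`, `evaluation`, `breedings`, possibly with
#'   duplicated animals) and `truth` (class `true_parameters`: additive
#'   effects, dominance QTL ids and shifts, evaluation-class effects,
#'   realized heritability and the per-animal variance components).
#' @export
simulate_phenotypes <- function(genotypes, config, snp_classes = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "phenotypes"))
  n <- nrow(genotypes$dosages)
  p <- ncol(genotypes$dosages)
  vtot <- config$total_variance
  h2 <- config$h2_additive
  n_qtl <- config$n_dominance_qtl
  dvf <- config$dominance_variance_fraction
  if (h2 + n_qtl * dvf >= 1)
    stop("variance budget infeasible")

  # dominance QTL: intermediate-frequency SNPs so carrier groups are sizeable
  f_obs <- allele_freq(genotypes)
  qtl_ids <- character(0)
  if (n_qtl > 0) {
    eligible <- names(f_obs)[f_obs >= 0.15 & f_obs <= 0.5]
    if (length(eligible) < n_qtl)
      eligible <- names(sort(abs(f_obs - 0.3)))[seq_len(max(n_qtl, 1))]
    qtl_ids <- sample(eligible, n_qtl)
  }

  # additive polygenic background (dominance QTL excluded: pure dominance)
  per_snp_var <- rep(1, p)
  names(per_snp_var) <- genotypes$snp_meta$id
  if (!is.null(snp_classes) && length(config$class_enrichment)) {
    cls <- snp_classes[genotypes$snp_meta$id]
    mult <- config$class_enrichment[cls]
    mult[is.na(mult)] <- 1
    per_snp_var <- per_snp_var * as.numeric(mult)
  }
  per_snp_var[qtl_ids] <- 0
  a <- stats::rnorm(p, 0, sqrt(per_snp_var))
  add <- rep(0, n)
  if (h2 > 0 && any(a != 0)) {
    S <- standardize_genotypes(genotypes, scale = "empirical")
    a_use <- a[match(colnames(S), genotypes$snp_meta$id)]
    raw <- drop(S %*% a_use)
    sc <- sqrt(h2 * vtot / stats::var(raw))
    a <- a * sc
    add <- raw * sc
  } else a <- rep(0, p)
  names(a) <- genotypes$snp_meta$id

  # dominance: phenotype shift shared by all carriers of >= 1 B allele
  dom <- rep(0, n)
  d_eff <- stats::setNames(numeric(0), character(0))
  if (n_qtl > 0 && dvf > 0) {
    d_eff <- stats::setNames(numeric(n_qtl), qtl_ids)
    for (q in qtl_ids) {
      x <- genotypes$dosages[, q]
      x[is.na(x)] <- round(mean(x, na.rm = TRUE))
      carrier <- as.numeric(x >= 1)
      fc <- mean(carrier)
      d <- -sqrt(dvf * vtot / (fc * (1 - fc)))  # carriers shifted downwards
      d_eff[q] <- d
      dom <- dom + d * (carrier - fc)
    }
  }

  cls_eff <- stats::rnorm(config$n_eval_classes, 0, config$eval_class_sd)
  eval_of <- sample.int(config$n_eval_classes, n, replace = TRUE)
  sigma2_e <- vtot * (1 - h2 - n_qtl * dvf)
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- config$mu + cls_eff[eval_of] + add + dom + e

  v_add <- stats::var(add); v_dom <- stats::var(dom); v_e <- stats::var(e)
  realized_h2 <- v_add / (v_add + v_dom + v_e)

  breed <- 1L + stats::rnbinom(n, size = 2, mu = 500)
  pheno <- data.frame(animal_id = genotypes$sample_ids, scr = y,
                      evaluation = sprintf("eval%02d", eval_of),
                      breedings = breed, stringsAsFactors = FALSE)

  # duplicate records for 10% of bulls, breeding counts drawn without ties
  n_dup <- floor(0.10 * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    dup_breed <- breed[dup_idx] +
      sample(c(-1L, 1L), n_dup, replace = TRUE) *
      (1L + stats::rpois(n_dup, 50))
    dup_breed <- pmax(dup_breed, 1L)
    tie <- dup_breed == breed[dup_idx]
    dup_breed[tie] <- dup_breed[tie] + 1L
    other_eval <- vapply(eval_of[dup_idx], function(ec) {
      pool <- setdiff(seq_len(config$n_eval_classes), ec)
      if (length(pool) == 0) ec else pool[sample.int(length(pool), 1)]
    }, integer(1))
    # every record's scr is consistent with its own evaluation class; the
    # record with fewer breedings gets extra evaluation noise on top
    base_dup <- y[dup_idx] - cls_eff[eval_of[dup_idx]]
    dup_model <- base_dup + cls_eff[other_eval]
    extra <- stats::rnorm(n_dup, 0, 0.5)
    dup_wins <- dup_breed > breed[dup_idx]
    dup_scr <- ifelse(dup_wins, dup_model, dup_model + extra)
    pheno$scr[dup_idx[!dup_wins]] <- y[dup_idx[!dup_wins]]  # unchanged
    pheno$scr[dup_idx[dup_wins]] <- y[dup_idx[dup_wins]] + extra[dup_wins]
    dup_rows <- data.frame(animal_id = genotypes$sample_ids[dup_idx],
                           scr = dup_scr,
                           evaluation = sprintf("eval%02d", other_eval),
                           breedings = dup_breed, stringsAsFactors = FALSE)
    pheno <- rbind(pheno, dup_rows)
  }

  truth <- structure(list(additive_effects = a,
                          dominance_qtl_ids = qtl_ids,
                          dominance_effects = d_eff,
                          eval_class_effects = stats::setNames(
                            cls_eff, sprintf("eval%02d",
                                             seq_len(config$n_eval_classes))),
                          realized_h2 = realized_h2,
                          components = data.frame(
                            animal_id = genotypes$sample_ids,
                            additive = add, dominance = dom,
                            eval_class = cls_eff[eval_of], residual = e,
                            stringsAsFactors = FALSE)),
                     class = "true_parameters")
  structure(list(phenotypes = pheno, truth = truth),
            class = "scr_simulation")
}

#' @export
print.true_parameters <- function(x, ...) {
  cat(sprintf("true_parameters: realized h2 = %.3f; %d dominance QTL (%s)\n",
              x$realized_h2, length(x$dominance_qtl_ids),
              paste(x$dominance_qtl_ids, collapse = ", ")))
  invisible(x)
}

#' @export
print.scr_simulation <- function(x, ...) {
  cat(sprintf("scr_simulation: %d records for %d bulls\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$animal_id))))
  print(x$truth)
  invisible(x)
}
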