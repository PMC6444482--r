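#' Carrier (dominance) coding of SNP dosages
#'
#' Codes genotypes 0 for AA and 1 for AB or BB, testing whether one copy
#' of the B allele has the same phenotypic effect as two. Missing calls
#' are imputed to the mean of the observed codes.
#'
#' @param dosages Numeric vector or matrix of dosages in \{0, 1, 2, NA\}.
#' @return Numeric vector/matrix of codes in [0, 1].
#' @export
dominance_code <- function(dosages) {
  code <- function(x) {
    cx <- as.numeric(x >= 1)
    if (anyNA(cx)) cx[is.na(cx)] <- mean(cx, na.rm = TRUE)
    cx
  }
  if (is.matrix(dosages)) {
    out <- apply(dosages, 2, code)
    dimnames(out) <- dimnames(dosages)
    out
  } else code(dosages)
}

#' Score one SNP for a dominance effect
#'
#' Wald-type score statistic of the two-step mixed-model scan:
#' \deqn{z = \frac{\tilde x' V_0^{-1} (y - X\hat\beta)}
#'               {\sqrt{\tilde x' V_0^{-1} \tilde x}},}
#' where \eqn{\tilde x} is the carrier code adjusted for the fixed
#' effects in the \eqn{V_0^{-1}} metric (the marker column is residualised
#' on X before scoring, as mixed-model score implementations do when they
#' center the genotype). The adjustment leaves the numerator unchanged
#' (the GLS residual is already orthogonal to X) but is required in the
#' denominator for the statistic to be asymptotically standard normal
#' under the null. Computed through the stored eigen-factorization of
#' \eqn{V_0}; no dense inverse is formed. A carrier code that is constant
#' across animals yields `z = 0` with the attribute `monomorphic = TRUE`.
#'
#' @param x_snp Carrier-coded vector from [dominance_code()].
#' @param null_fit A [fit_null_model()] object (holds y, X and the
#'   factorized V0).
#' @return The z statistic (scalar).
#' @export
score_snp <- function(x_snp, null_fit) {
  stopifnot(inherits(null_fit, "null_model_fit"),
            length(x_snp) == null_fit$n)
  if (stats::sd(x_snp) == 0) {
    z <- 0
    attr(z, "monomorphic") <- TRUE
    return(z)
  }
  xt <- crossprod(null_fit$U, x_snp)
  num <- sum(xt * null_fit$wresid_rot)
  s <- crossprod(null_fit$Xt, xt / null_fit$v0diag)
  adj <- sum(backsolve(null_fit$XtV0iX_chol, s, transpose = TRUE)^2)
  den <- sum(xt^2 / null_fit$v0diag) - adj
  drop(num / sqrt(den))
}

#' Genomic-control correction of scan statistics
#'
#' Estimates the variance inflation factor \eqn{\lambda} as the
#' no-intercept regression slope of the sorted observed \eqn{\chi^2_1}
#' statistics on their expected order quantiles, then divides every z by
#' \eqn{\sqrt\lambda}. \eqn{\lambda < 1} is truncated to 1 so the
#' correction is never anti-conservative. Fewer than 100 statistics give
#' \eqn{\lambda = 1} with a warning.
#'
#' @param z_values Numeric vector of raw z statistics.
#' @return List with `z_corrected` and `lambda`.
#' @export
genomic_control <- function(z_values) {
  z_values <- as.numeric(z_values)
  m <- length(z_values)
  if (m < 100) {
    warning("fewer than 100 statistics; lambda set to 1")
    return(list(z_corrected = z_values, lambda = 1))
  }
  obs <- sort(z_values^2)
  expd <- stats::qchisq(stats::ppoints(m), df = 1)
  lambda <- sum(obs * expd) / sum(expd^2)
  lambda <- max(lambda, 1)
  list(z_corrected = z_values / sqrt(lambda), lambda = lambda)
}

#' Genome-wide dominance scan
#'
#' Runs [dominance_code()] and the score statistic over every SNP,
#' applies [genomic_control()], converts corrected statistics to
#' two-sided normal p-values, and selects major markers by Bonferroni.
#' Per-SNP cost is O(n) after the null model's one-time factorization.
#'
#' @param g A [genotype_matrix()] (post-QC).
#' @param null_fit A [fit_null_model()] object in the same sample order.
#' @param alpha Family-wise significance level for marker selection
#'   (Bonferroni over the number of scored SNPs), default 0.05.
#' @return Object of class `scan_result`: data frame (`snp_id`, `chrom`,
#'   `pos`, `carrier_freq`, `z_raw`, `z_corrected`, `p_corrected`,
#'   `monomorphic`, `selected`) with attributes `lambda_gc`, `selected`
#'   (ids sorted by significance) and `alpha`.
#' @export
scan_dominance <- function(g, null_fit, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(null_fit, "null_model_fit"))
  n <- nrow(g$dosages)
  stopifnot(null_fit$n == n)
  C <- dominance_code(g$dosages)
  mono <- apply(C, 2, stats::sd) == 0
  Ct <- crossprod(null_fit$U, C)                       # n x p rotation
  num <- drop(crossprod(Ct, null_fit$wresid_rot))
  S <- crossprod(null_fit$Xt, Ct / null_fit$v0diag)    # q x p
  adj <- colSums(backsolve(null_fit$XtV0iX_chol, S, transpose = TRUE)^2)
  den <- colSums(Ct^2 / null_fit$v0diag) - adj
  z <- ifelse(mono, 0, num / sqrt(pmax(den, .Machine$double.eps)))
  gc <- genomic_control(z)
  p_corr <- 2 * stats::pnorm(-abs(gc$z_corrected))
  p_corr <- pmax(p_corr, .Machine$double.xmin)  # keep in (0, 1]
  res <- data.frame(snp_id = g$snp_meta$id, chrom = g$snp_meta$chrom,
                    pos = g$snp_meta$pos,
                    carrier_freq = colMeans(C),
                    z_raw = z, z_corrected = gc$z_corrected,
                    p_corrected = p_corr, monomorphic = mono,
                    stringsAsFactors = FALSE)
  sel <- select_major_snps(res, alpha)
  res$selected <- res$snp_id %in% sel
  structure(res, lambda_gc = gc$lambda, selected = sel, alpha = alpha,
            class = c("scan_result", "data.frame"))
}

#' Select major markers from a scan
#'
#' SNPs whose genomic-control-corrected p-value passes Bonferroni:
#' `p_corrected < alpha / p_total`, sorted by significance. `alpha = 0`
#' returns an empty list.
#'
#' @param scan A `scan_result` or data frame with `snp_id` and
#'   `p_corrected`.
#' @param alpha Family-wise significance level.
#' @return Character vector of selected SNP ids (possibly empty).
#' @export
select_major_snps <- function(scan, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  thr <- alpha / nrow(scan)
  hit <- which(scan$p_corrected < thr)
  hit <- hit[order(scan$p_corrected[hit])]
  scan$snp_id[hit]
}

#' @export
print.scan_result <- function(x, ...) {
  lam <- attr(x, "lambda_gc")
  if (is.null(lam)) {  # subset without attributes: plain table
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat(sprintf("scan_result: %d SNPs, lambda_gc = %.3f, %d selected\n",
              nrow(x), lam, length(attr(x, "selected"))))
  if (length(attr(x, "selected")))
    print(utils::head(x[x$selected,
                        c("snp_id", "chrom", "pos", "z_corrected",
                          "p_corrected")], 10))
  invisible(x)
}
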