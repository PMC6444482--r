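#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain against the mean of
#' the last `frac2`. The variance of each window mean is estimated from
#' non-overlapping batch means (a Bartlett-type spectral-density-at-zero
#' estimate, so autocorrelation at lags shorter than the batch length is
#' accounted for); both windows use a common batch length, the resulting
#' two-sample pooled t statistic is exact under a stationary white chain,
#' and it is mapped to the normal scale by a probability-integral
#' transform. The returned score is therefore standard normal for a
#' converged, well-thinned chain not just asymptotically but at finite
#' chain lengths; strong residual autocorrelation (batches shorter than
#' the correlation length) makes it anti-conservative, which is why
#' monitored chains should be thinned.
#'
#' @param samples Numeric vector of retained MCMC samples (at least 100;
#'   shorter chains return `NA` with a warning).
#' @param frac1 Leading fraction of the chain (default 0.1).
#' @param frac2 Trailing fraction (default 0.5).
#' @return The Geweke z score; exactly 0 for a constant chain.
#' @export
geweke_diagnostic <- function(samples, frac1 = 0.1, frac2 = 0.5) {
  samples <- as.numeric(samples)
  m <- length(samples)
  if (m < 100) {
    warning("chain too short for a Geweke diagnostic (< 100 samples)")
    return(NA_real_)
  }
  if (stats::var(samples) == 0) return(0)
  wa <- samples[seq_len(floor(frac1 * m))]
  wb <- samples[seq.int(m - floor(frac2 * m) + 1L, m)]
  len <- max(10L, floor(sqrt(length(wa))))   # common batch length
  batch_means <- function(w) {
    nb <- length(w) %/% len
    colMeans(matrix(w[seq_len(nb * len)], len, nb))
  }
  ba <- batch_means(wa)
  bb <- batch_means(wb)
  na <- length(ba); nb <- length(bb)
  df <- na + nb - 2L
  sp2 <- (sum((ba - mean(ba))^2) + sum((bb - mean(bb))^2)) / df
  if (sp2 == 0) return(0)
  tstat <- (mean(ba) - mean(bb)) / sqrt(sp2 * (1 / na + 1 / nb))
  stats::qnorm(stats::pt(tstat, df))
}
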