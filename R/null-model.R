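#' REML fit of the no-SNP animal model
#'
#' Fits \eqn{y = Xb + u + e} with \eqn{u \sim N(0, G\sigma^2_u)} and
#' \eqn{e \sim N(0, I\sigma^2_e)} by restricted maximum likelihood. The
#' eigendecomposition \eqn{G = U D U'} rotates the model so that
#' \eqn{V_0 = GD\sigma^2_u + I\sigma^2_e} is diagonal, reducing REML to a
#' one-dimensional optimization over the heritability ratio
#' \eqn{h = \sigma^2_u / (\sigma^2_u + \sigma^2_e)}; the residual scale is
#' profiled out analytically. The returned factorization applies
#' \eqn{V_0^{-1}} in O(n) per vector after the one-time O(n^3)
#' decomposition.
#'
#' @param y Numeric phenotype vector (one record per animal).
#' @param X Fixed-effects design matrix (intercept and evaluation
#'   classes), full column rank.
#' @param G Genomic relationship matrix ([kernel_matrix()] or plain
#'   symmetric PSD matrix) in the same sample order as `y`.
#' @return Object of class `null_model_fit` with REML variances
#'   `sigma2_u`, `sigma2_e`, heritability `h2`, GLS `beta_hat`, the
#'   eigenvectors/values of G, the diagonal of the rotated V0, rotated
#'   working residual, and a `boundary` flag set when the additive
#'   variance is estimated at (numerically) zero.
#' @export
fit_null_model <- function(y, X, G) {
  if (inherits(G, "kernel_matrix")) G <- G$values
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  if (max(abs(G - t(G))) > 1e-8) stop("G must be symmetric")
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("G is not positive semi-definite (min eigenvalue ",
         format(min(ev$values)), ")")
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  q <- ncol(X)

  # profiled REML log-likelihood in h = s2u / (s2u + s2e)
  reml_ll <- function(h) {
    v <- h * d + (1 - h)
    w <- 1 / v
    A <- crossprod(Xt, Xt * w)
    b <- solve(A, crossprod(Xt, yt * w))
    r <- yt - Xt %*% b
    rss <- sum(r^2 * w)
    -0.5 * (sum(log(v)) + (n - q) * log(rss) +
              determinant(A, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_ll, c(1e-6, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-9)
  h <- opt$maximum
  v <- h * d + (1 - h)
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  beta <- solve(A, crossprod(Xt, yt * w))
  r <- yt - Xt %*% beta
  s2tot <- sum(r^2 * w) / (n - q)
  sigma2_u <- h * s2tot
  sigma2_e <- (1 - h) * s2tot
  boundary <- h < 1e-3
  v0diag <- sigma2_u * d + sigma2_e
  structure(list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 h2 = h, beta_hat = drop(beta),
                 U = U, d = d, v0diag = v0diag,
                 resid_rot = drop(r),          # U'(y - X beta)
                 wresid_rot = drop(r) / v0diag,  # V0^{-1} residual, rotated
                 X = X, y = y, n = n,
                 Xt = Xt, XtV0iX_chol = chol(crossprod(Xt, Xt / v0diag)),
                 reml_loglik = opt$objective, boundary = boundary),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(paste0("null_model_fit: sigma2_u = %.4f, sigma2_e = %.4f ",
                     "(h2 = %.3f)%s\n"),
              x$sigma2_u, x$sigma2_e, x$h2,
              if (x$boundary) " [boundary: additive variance ~ 0]" else ""))
  invisible(x)
}
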