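#' Per-component Wald statistics for a genotype
#'
#' Regresses each PC score column on an intercept, optional covariates and
#' the additive genotype, and returns the vector of Wald statistics
#' \eqn{T_j = \hat\beta_j / se(\hat\beta_j)} in eigenvalue order.  The
#' standard error uses the residual variance with finite-sample degrees of
#' freedom; under the null each \eqn{T_j} is asymptotically standard
#' normal and the \eqn{T_j} are mutually independent.
#'
#' A PC with exactly zero variance (rank-deficient traits) gets
#' \eqn{T_j = 0} with a warning; a near-perfect fit is capped with a
#' warning instead of returning infinity.
#'
#' @param pca a `"trait_pca"` object from [trait_pca()].
#' @param g additive genotype dosage vector (length `n`, not constant).
#' @param covariates optional numeric matrix of covariates (`n` rows),
#'   included as columns in each per-PC regression.
#' @return numeric vector of length `m` with attributes `dof_resid`
#'   (residual degrees of freedom) and `maf` (folded minor allele
#'   frequency of `g`).
#' @export
pc_wald <- function(pca, g, covariates = NULL) {
  stopifnot(inherits(pca, "trait_pca"))
  g <- .check_genotype(g, pca$n)
  x <- cbind(`(Intercept)` = 1, covariates, g = g)
  if (nrow(x) != pca$n) .stop_invalid("covariate rows do not match sample count")
  qx <- qr(x)
  if (qx$rank < ncol(x))
    .stop_invalid("design matrix is rank deficient (collinear covariates and genotype)")
  z <- pca$scores
  dof <- pca$n - ncol(x)
  if (dof < 1L) .stop_invalid("not enough residual degrees of freedom")
  coefs <- qr.coef(qx, z)
  res <- qr.resid(qx, z)
  sigma2 <- colSums(res^2) / dof
  xtxi <- chol2inv(qr.R(qx))
  vg <- xtxi[ncol(x), ncol(x)]
  bg <- coefs[ncol(x), ]
  t <- numeric(pca$m)
  zerovar <- pca$values <= 0
  if (any(zerovar))
    warning(sum(zerovar), " zero-variance principal component(s); their Wald statistics are set to 0",
            call. = FALSE)
  ok <- !zerovar
  se <- sqrt(sigma2 * vg)
  tiny <- se < sqrt(.Machine$double.eps) * pmax(abs(bg), 1)
  if (any(tiny & ok)) {
    warning("near-perfect fit for some principal components; Wald statistics capped",
            call. = FALSE)
    t[tiny & ok] <- sign(bg[tiny & ok]) * sqrt(.XI_CAP) * 10
    ok <- ok & !tiny
  }
  t[ok] <- bg[ok] / se[ok]
  structure(t, dof_resid = dof, maf = .fold_maf(g))
}
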