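# TATES: trait-based association test that uses an extended Simes
# procedure with effective numbers of tests derived from the correlation
# matrix of the per-trait p-values.

.gatetest_env <- new.env(parent = emptyenv())

#' Correlation between two-sided p-values of correlated test statistics
#'
#' For two standard-normal test statistics with correlation `r`, the
#' two-sided p-values \eqn{p = 2\Phi(-|Z|)} are themselves correlated.
#' This maps statistic correlation to p-value correlation by direct
#' bivariate-normal quadrature (dense grid on a precomputed table,
#' spline-interpolated); the mapping is even in `r` and fixed at the
#' endpoints \eqn{\rho_p(0) = 0}, \eqn{\rho_p(\pm 1) = 1}.
#'
#' @param r numeric vector of statistic (trait) correlations in `[-1, 1]`.
#' @return vector of p-value correlations.
#' @export
pvalue_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-8)) .stop_invalid("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  f <- .gatetest_env$pcor_spline
  if (is.null(f)) {
    z <- seq(-8, 8, length.out = 321)
    dz <- z[2L] - z[1L]
    a <- pnorm(-abs(z))                       # Phi(-|z|) on the grid
    w <- dnorm(z) * dz                        # marginal weights
    grid <- seq(0, 0.995, by = 0.005)
    ep <- vapply(grid, function(rr) {
      s <- sqrt(1 - rr^2)
      # E[ Phi(-|Z1|) * Phi(-|Z2|) ] with Z2 | Z1 ~ N(r Z1, 1 - r^2)
      condm <- outer(z, z, function(z2, z1) dnorm((z2 - rr * z1) / s) / s) * dz
      inner <- as.numeric(crossprod(a, condm))  # E[Phi(-|Z2|) | z1]
      sum(w * a * inner)
    }, 0)
    # normalise by the same quadrature rule's r = 0 and r = 1 limits so the
    # discretisation bias cancels and the endpoints are exact
    ep0 <- sum(w * a)^2
    ep1 <- sum(w * a^2)
    rho <- (ep - ep0) / (ep1 - ep0)
    f <- splinefun(c(grid, 1), c(rho, 1), method = "hyman")
    .gatetest_env$pcor_spline <- f
  }
  pmin(pmax(f(abs(r)), 0), 1)
}

# effective number of tests from eigenvalues of a correlation matrix
# (Li & Ji rule: integer part indicator plus fractional remainder)
.m_eff <- function(cmat) {
  lam <- abs(eigen(cmat, symmetric = TRUE, only.values = TRUE)$values)
  lam <- round(lam, 8)  # the floor() rule is discontinuous at integers
  sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
}

#' TATES extended-Simes combination of per-trait p-values
#'
#' Sorts the univariate trait p-values, computes for each top set the
#' effective number of tests from the eigenvalues of the corresponding
#' block of the p-value correlation matrix (obtained from the trait
#' correlations via [pvalue_correlation()]), and returns
#' \eqn{\min_j m_e \, p_{(j)} / m_{e(j)}}.  With independent traits this
#' is the classical Simes test; with perfectly correlated traits it
#' degenerates to the minimum p-value.
#'
#' @param p numeric vector of `m` per-trait p-values (e.g. from
#'   [univariate_trait_tests()]).
#' @param trait_correlations `m x m` trait correlation matrix.
#' @return an `"htest"` object; `$detail` carries the per-set effective
#'   test counts.
#' @export
tates_test <- function(p, trait_correlations) {
  m <- length(p)
  cm <- as.matrix(trait_correlations)
  if (!all(dim(cm) == m)) .stop_invalid("correlation matrix does not match length(p)")
  if (max(abs(cm - t(cm))) > 1e-8) .stop_invalid("correlation matrix must be symmetric")
  rp <- pvalue_correlation(cm)
  dim(rp) <- dim(cm)
  diag(rp) <- 1
  ev <- eigen(rp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) .stop_invalid("p-value correlation matrix is not positive semi-definite")
  ord <- order(p)
  me <- vapply(seq_len(m), function(j) .m_eff(rp[ord[seq_len(j)], ord[seq_len(j)], drop = FALSE]), 0)
  stat <- min(me[m] * p[ord] / me)
  .htest(c(p_TATES = stat), stat,
         "TATES (extended Simes with effective numbers of tests)",
         parameter = c(m = m, m_eff = me[m]),
         detail = list(m_eff_per_set = me, order = ord))
}
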