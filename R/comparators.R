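# Comparator tests: FCT, mCPC, MANOVA, MultiPhen, univariate per-trait
# regressions.  Each returns a base "htest" object so print() is familiar.

.htest <- function(statistic, p.value, method, parameter = NULL, detail = NULL) {
  out <- list(statistic = statistic, p.value = min(max(p.value, 0), 1),
              method = method, parameter = parameter,
              data.name = "multivariate traits vs genotype")
  if (!is.null(detail)) out$detail <- detail
  structure(out, class = "htest")
}

#' Fisher-combined test over all principal components
#'
#' \eqn{FCT = \sum_j T_j^2}, referred to a chi-squared distribution with
#' `m` degrees of freedom.
#'
#' @param t Wald vector from [pc_wald()] (or any numeric vector).
#' @return an `"htest"` object.
#' @export
fct_test <- function(t) {
  stat <- sum(t^2)
  m <- length(t)
  .htest(c(FCT = stat), pchisq(stat, m, lower.tail = FALSE),
         "Fisher-combined test of per-PC Wald statistics",
         parameter = c(df = m))
}

#' Split point for the multistep combined PC test
#'
#' The smallest `s` with cumulative eigenvalue share at least 80%.
#'
#' @param eigenvalues non-negative eigenvalues, descending.
#' @param threshold cumulative-variance threshold (default 0.8).
#' @return integer `s` in `1..m`.
#' @export
mcpc_split <- function(eigenvalues, threshold = 0.8) {
  eigenvalues <- pmax(eigenvalues, 0)
  if (is.unsorted(-eigenvalues)) .stop_invalid("eigenvalues must be sorted descending")
  tot <- sum(eigenvalues)
  if (tot <= 0) .stop_invalid("all eigenvalues are zero")
  which(cumsum(eigenvalues) / tot >= threshold - 1e-12)[1L]
}

#' Multistep combined principal component test (mCPC)
#'
#' Splits the eigenvalue-ordered Wald statistics after the top `s` PCs
#' covering at least 80% of variance and combines the two group
#' chi-squared tails by Fisher's method; the statistic is referred to
#' \eqn{\chi^2_4}.  Identical to [xi_statistic()] with composition
#' `(s, m - s)`.  If `s = m` the second group is empty and the test
#' falls back to [fct_test()] with a warning.
#'
#' @param t Wald vector in eigenvalue order.
#' @param eigenvalues the matching eigenvalues (for the split).
#' @return an `"htest"` object with the split `s` in `$detail`.
#' @export
mcpc_test <- function(t, eigenvalues) {
  s <- mcpc_split(eigenvalues)
  m <- length(t)
  if (s >= m) {
    warning("top group already covers all PCs (s = m); falling back to FCT", call. = FALSE)
    out <- fct_test(t)
    out$detail <- list(s = s, fallback = "FCT")
    return(out)
  }
  stat <- xi_statistic(t, c(s, m - s))
  .htest(c(mCPC = stat), pchisq(stat, 4, lower.tail = FALSE),
         "Multistep combined PC test (two groups at 80% variance)",
         parameter = c(df = 4), detail = list(s = s))
}

#' One-way MANOVA of traits on an additive genotype
#'
#' Wilks' lambda for the multivariate regression of the traits on the
#' additive dosage (a single continuous predictor, equivalent to the
#' canonical-correlation test); the F transform is exact for a rank-one
#' hypothesis.
#'
#' @param y trait matrix (`n` by `m`).
#' @param g additive genotype vector.
#' @param as_factor if `TRUE`, treat genotype as a factor (2 df) instead
#'   of the additive coding.
#' @return an `"htest"` object.
#' @export
manova_test <- function(y, g, as_factor = FALSE) {
  y <- .as_trait_matrix(y, min_traits = 1L)
  g <- .check_genotype(g, nrow(y))
  n <- nrow(y); m <- ncol(y)
  if (n <= m + 2L) .stop_invalid("need n > m + 2 samples for MANOVA")
  if (as_factor) {
    fit <- stats::manova(y ~ factor(g))
    tab <- summary(fit, test = "Wilks")$stats
    return(.htest(c(Wilks = tab[1L, "Wilks"]), tab[1L, "Pr(>F)"],
                  "One-way MANOVA (genotype as factor), Wilks' lambda"))
  }
  yc <- sweep(y, 2L, colMeans(y))
  gc <- g - mean(g)
  sg <- sum(gc^2)
  b <- crossprod(yc, gc) / sg           # m x 1 regression coefficients
  h <- b * sqrt(sg)                     # rank-1 hypothesis root
  e <- crossprod(yc) - tcrossprod(h)    # error SSCP
  q <- tryCatch(solve(e, h), error = function(err)
    .stop_invalid("singular error matrix in MANOVA"))
  lambda <- 1 / (1 + sum(h * q))        # det(E)/det(E + hh')
  df2 <- n - m - 1L
  fstat <- (1 - lambda) / lambda * df2 / m
  .htest(c(Wilks = lambda), pf(fstat, m, df2, lower.tail = FALSE),
         "One-way MANOVA (additive genotype), Wilks' lambda / exact F",
         parameter = c(df1 = m, df2 = df2))
}

#' Per-trait univariate regressions on the genotype
#'
#' Ordinary least squares of each raw trait on intercept + genotype;
#' two-sided t-test p-values.  These feed [tates_test()].
#'
#' @param y trait matrix.
#' @param g additive genotype vector.
#' @param covariates optional covariate matrix.
#' @return numeric vector of `m` p-values (named by trait).
#' @export
univariate_trait_tests <- function(y, g, covariates = NULL) {
  y <- .as_trait_matrix(y, min_traits = 1L)
  g <- .check_genotype(g, nrow(y))
  x <- cbind(1, covariates, g)
  qx <- qr(x)
  if (qx$rank < ncol(x)) .stop_invalid("rank-deficient design")
  dof <- nrow(y) - ncol(x)
  coefs <- qr.coef(qx, y)[ncol(x), ]
  sigma2 <- colSums(qr.resid(qx, y)^2) / dof
  vg <- chol2inv(qr.R(qx))[ncol(x), ncol(x)]
  tt <- coefs / sqrt(sigma2 * vg)
  setNames(2 * stats::pt(abs(tt), dof, lower.tail = FALSE), colnames(y))
}

#' MultiPhen-style proportional-odds reverse regression
#'
#' Regresses the ordinal genotype (0/1/2) on all traits jointly with a
#' proportional-odds model and tests the `m` trait coefficients with a
#' likelihood-ratio test against the intercept-only model.  With only two
#' observed genotype levels this reduces to binary logistic regression.
#'
#' @param y trait matrix.
#' @param g additive genotype vector with at least two observed levels.
#' @return an `"htest"` object.  Non-convergence raises a condition of
#'   class `"gate_fit_failure"` so simulation drivers can count it.
#' @export
multiphen_test <- function(y, g) {
  y <- .as_trait_matrix(y)
  g <- .check_genotype(g, nrow(y))
  n <- nrow(y); m <- ncol(y)
  if (n <= m + 5L) .stop_invalid("need n > m + 5 samples")
  gi <- round(g)
  lev <- sort(unique(gi))
  tab <- tabulate(match(gi, lev))
  nulldev <- -2 * sum(tab * log(tab / n))
  dev <- tryCatch({
    if (length(lev) == 2L) {
      fit <- stats::glm.fit(cbind(1, y), as.integer(gi == lev[2L]),
                            family = stats::binomial())
      if (!fit$converged) stop("glm did not converge")
      fit$deviance
    } else {
      fit <- MASS::polr(factor(gi, levels = lev, ordered = TRUE) ~ y,
                        method = "logistic")
      if (fit$convergence != 0) stop("polr did not converge")
      fit$deviance
    }
  }, error = function(err) {
    stop(structure(class = c("gate_fit_failure", "error", "condition"),
                   list(message = paste("proportional-odds fit failed:",
                                        conditionMessage(err)),
                        call = sys.call(-1))))
  })
  lrt <- max(nulldev - dev, 0)
  .htest(c(LRT = lrt), pchisq(lrt, m, lower.tail = FALSE),
         "MultiPhen-style proportional-odds LRT (genotype on traits)",
         parameter = c(df = m))
}
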