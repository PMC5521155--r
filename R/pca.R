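#' Sample covariance matrix of a trait matrix
#'
#' Computes the \eqn{m \times m} covariance matrix of the traits with the
#' usual \eqn{n - 1} denominator.  A constant trait column is allowed (it
#' contributes a zero eigenvalue) but triggers a warning.
#'
#' @param y numeric matrix, \eqn{n} samples by \eqn{m} traits, no missing
#'   values.
#' @return symmetric \eqn{m \times m} matrix.
#' @examples
#' y <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' trait_covariance(y)  # [[1, -1], [-1, 1]]
#' @export
trait_covariance <- function(y) {
  y <- .as_trait_matrix(y)
  v <- apply(y, 2L, var)
  if (any(v == 0))
    warning("constant trait column(s): ", paste(colnames(y)[v == 0], collapse = ", "),
            call. = FALSE)
  cov(y)
}

#' Principal component decomposition of the trait covariance
#'
#' Eigendecomposes the trait covariance matrix and projects the
#' column-centered traits onto the eigenvectors, giving the PC score
#' matrix \eqn{Z = Y Q}.  Eigenvalues are sorted in descending order;
#' small negative eigenvalues (within `-1e-8 * lambda_1`) are clamped to
#' zero.
#'
#' @param y numeric trait matrix (samples by traits).
#' @param cov optional pre-computed covariance matrix; defaults to
#'   [trait_covariance()] of `y`.
#' @return an object of class `"trait_pca"`: a list with `values`
#'   (eigenvalues, descending), `vectors` (orthogonal matrix `Q`, columns
#'   are eigenvectors), `scores` (`n x m` matrix of centered PC scores),
#'   `center` (column means) and `m`, `n`.
#' @examples
#' y <- matrix(rnorm(300), 100, 3)
#' p <- trait_pca(y)
#' zapsmall(cov(p$scores) - diag(p$values))  # scores are uncorrelated
#' @export
trait_pca <- function(y, cov = NULL) {
  y <- .as_trait_matrix(y)
  if (is.null(cov)) cov <- trait_covariance(y)
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || nrow(cov) != ncol(y))
    .stop_invalid("covariance matrix dimensions do not match the trait matrix")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    .stop_invalid("covariance matrix is not symmetric")
  e <- eigen(cov, symmetric = TRUE)   # eigen() already sorts descending
  lam <- e$values
  if (lam[1L] > 0 && any(lam < -1e-8 * lam[1L]))
    .stop_invalid("covariance matrix is not positive semi-definite")
  lam[lam < 0] <- 0
  ctr <- colMeans(y)
  z <- sweep(y, 2L, ctr) %*% e$vectors
  structure(list(values = lam, vectors = e$vectors, scores = z,
                 center = ctr, m = ncol(y), n = nrow(y)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA:", x$n, "samples,", x$m, "traits\n")
  cat("Eigenvalues:", format(signif(x$values, 4)), "\n")
  pct <- cumsum(x$values) / sum(x$values)
  cat("Cumulative variance explained:", paste0(format(round(100 * pct, 1)), "%"), "\n")
  invisible(x)
}
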