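#' Contiguous compositions of m into K positive parts
#'
#' Enumerates, in lexicographic order, every ordered split
#' \eqn{(m_1,\dots,m_K)} of `m` into `K` positive integers.  These index
#' the contiguous groupings of the eigenvalue-ordered Wald statistics;
#' there are \eqn{\binom{m-1}{K-1}} of them.
#'
#' @param m total number of components.
#' @param K number of groups, `1 <= K <= m`.
#' @param max_count guard on the number of compositions; exceeding it is
#'   an error unless raised by the caller.
#' @return integer matrix with `K` columns, one composition per row.
#' @examples
#' compositions(5, 2)  # (1,4) (2,3) (3,2) (4,1)
#' @export
compositions <- function(m, K, max_count = 1e6) {
  m <- as.integer(m); K <- as.integer(K)
  if (K < 1L || K > m) .stop_invalid("need 1 <= K <= m")
  n_comp <- choose(m - 1L, K - 1L)
  if (n_comp > max_count)
    .stop_invalid("composition count ", n_comp, " exceeds guard of ", max_count)
  if (K == 1L) return(matrix(m, 1L, 1L))
  # cut points: choose K-1 ordered positions in 1..m-1
  cuts <- utils::combn(m - 1L, K - 1L)
  parts <- t(rbind(cuts, m) - rbind(0L, cuts))
  dimnames(parts) <- NULL
  parts
}

#' Grouped Fisher combination statistic
#'
#' For a composition \eqn{(m_1,\dots,m_K)} of the `m` eigenvalue-ordered
#' Wald statistics, sums \eqn{-2\log} of the chi-squared tail probability
#' of each group's sum of squares:
#' \deqn{\xi = \sum_t -2\log\{1 - F_{m_t}(\textstyle\sum_{j \in t} T_j^2)\}.}
#' Under the null \eqn{\xi} is asymptotically \eqn{\chi^2_{2K}}.  The tail
#' is evaluated on the log scale so strong signals never underflow.
#'
#' @param t numeric vector of Wald statistics, eigenvalue order.
#' @param parts integer vector of group sizes summing to `length(t)`.
#' @return the scalar \eqn{\xi \ge 0}.
#' @export
xi_statistic <- function(t, parts) {
  parts <- as.integer(parts)
  if (any(parts <= 0L)) .stop_invalid("group sizes must be positive")
  if (sum(parts) != length(t)) .stop_invalid("group sizes must sum to length(t)")
  ends <- cumsum(parts)
  cs <- c(0, cumsum(t^2))
  gs <- cs[ends + 1L] - cs[c(1L, ends[-length(ends)] + 1L)]
  .cap_xi(sum(-2 * .lsf_chisq(gs, parts)))
}

#' Maximum grouped Fisher statistic over all K-part compositions
#'
#' @inheritParams xi_statistic
#' @param K number of contiguous groups.
#' @param max_count passed to [compositions()] for `K > 2`.
#' @return list with `xi` (the maximum) and `parts` (the first maximizing
#'   composition in lexicographic order).
#' @export
max_xi <- function(t, K, max_count = 1e6) {
  m <- length(t)
  K <- as.integer(K)
  if (K < 1L || K > m) .stop_invalid("need 1 <= K <= m")
  if (K == 1L)
    return(list(xi = xi_statistic(t, m), parts = m))
  if (K == 2L) {
    cs <- cumsum(t^2)
    s <- seq_len(m - 1L)
    xi <- .cap_xi(-2 * (.lsf_chisq(cs[s], s) + .lsf_chisq(cs[m] - cs[s], m - s)))
    best <- which.max(xi)
    return(list(xi = xi[best], parts = c(best, m - best)))
  }
  cmp <- compositions(m, K, max_count = max_count)
  xi <- apply(cmp, 1L, function(p) xi_statistic(t, p))
  best <- which.max(xi)
  list(xi = xi[best], parts = cmp[best, ])
}

# per-draw max-xi values for each K on a B x m matrix of statistics;
# vectorized over draws (K = 1, 2 have closed index forms)
.maxxi_matrix <- function(tmat, k_max, max_count = 1e6) {
  B <- nrow(tmat); m <- ncol(tmat)
  cs <- tmat^2 %*% upper.tri(diag(m), diag = TRUE)  # cs[b, s] = sum_{j<=s} T^2
  out <- matrix(NA_real_, B, k_max)
  out[, 1L] <- -2 * .lsf_chisq(cs[, m], m)
  if (k_max >= 2L) {
    best <- rep(-Inf, B)
    for (s in seq_len(m - 1L)) {
      xi <- -2 * (.lsf_chisq(cs[, s], s) + .lsf_chisq(cs[, m] - cs[, s], m - s))
      best <- pmax(best, xi)
    }
    out[, 2L] <- best
  }
  if (k_max >= 3L) {
    for (K in 3:k_max) {
      cmp <- compositions(m, K, max_count = max_count)
      ends <- t(apply(cmp, 1L, cumsum))
      best <- rep(-Inf, B)
      for (r in seq_len(nrow(cmp))) {
        e <- ends[r, ]
        gs <- cbind(cs[, e[1L]], cs[, e[-1L], drop = FALSE] - cs[, e[-K], drop = FALSE])
        xi <- rowSums(-2 * .lsf_chisq(gs, rep(cmp[r, ], each = B)))
        best <- pmax(best, xi)
      }
      out[, K] <- best
    }
  }
  out[!is.finite(out)] <- .XI_CAP
  out
}

#' One-layer resampling null distribution for GATE
#'
#' Draws `B` independent sets of `m` standard-normal statistics, computes
#' for each draw and each group count `K` the maximum grouped Fisher
#' statistic over all contiguous compositions, and forms (i) the empirical
#' CDFs \eqn{\hat H_K} of those maxima and (ii) the null GATE draws
#' \eqn{\eta^{(b)}}, each evaluated against the same empirical CDFs (the
#' one-layer reuse).  The result depends only on `(m, k_max, B, seed)` --
#' never on genotype or traits -- so one null serves every variant of a
#' scan with the same number of traits.
#'
#' @param m number of traits / principal components.
#' @param k_max largest group count considered (default 2; with more than
#'   four traits two groups give the smallest pseudo degrees of freedom,
#'   so larger values rarely pay for their composition count).
#' @param B number of resampling draws, at least 1000 (default 10000).
#' @param seed integer seed; the builder uses its own RNG scope and
#'   restores the caller's stream.
#' @param cache optional directory; the null is stored there under a key
#'   derived from `(m, k_max, B, seed)` and reloaded on a later call.
#' @param max_count composition-count guard for `K > 2`.
#' @return object of class `"gate_null"`: list with `m`, `k_max`, `B`,
#'   `seed`, `maxxi` (`B x k_max` matrix), `hk` (list of sorted per-K
#'   draws defining \eqn{\hat H_K}), `eta` (the `B` null GATE values) and
#'   `eta_sorted`.
#' @export
gate_null <- function(m, k_max = 2L, B = 10000L, seed = 1L,
                      cache = NULL, max_count = 1e6) {
  m <- as.integer(m); k_max <- as.integer(k_max); B <- as.integer(B)
  if (B < 1000L) .stop_invalid("B must be at least 1000")
  if (k_max < 1L || k_max > max(1L, m - 1L)) .stop_invalid("need 1 <= k_max <= m - 1")
  key <- sprintf("gate_null_m%d_k%d_B%d_s%d.rds", m, k_max, B, as.integer(seed))
  if (!is.null(cache)) {
    path <- file.path(cache, key)
    if (file.exists(path)) {
      nd <- readRDS(path)
      if (inherits(nd, "gate_null")) return(nd)
    }
  }
  maxxi <- withr::with_seed(as.integer(seed), {
    tmat <- matrix(rnorm(B * m), B, m)
    .maxxi_matrix(tmat, k_max, max_count = max_count)
  })
  # eta^(b): min over K of the tail #{draws > x}/B, draw b included in the ECDF
  tails <- apply(maxxi, 2L, function(v) (B - rank(v, ties.method = "max")) / B)
  eta <- do.call(pmin, as.data.frame(tails))
  nd <- structure(list(m = m, k_max = k_max, B = B, seed = as.integer(seed),
                       maxxi = maxxi,
                       hk = lapply(seq_len(k_max), function(k) sort(maxxi[, k])),
                       eta = eta, eta_sorted = sort(eta)),
                  class = "gate_null")
  if (!is.null(cache)) {
    dir.create(cache, showWarnings = FALSE, recursive = TRUE)
    saveRDS(nd, file.path(cache, key))
  }
  nd
}

#' @export
print.gate_null <- function(x, ...) {
  cat("GATE resampling null: m =", x$m, ", k_max =", x$k_max,
      ", B =", x$B, ", seed =", x$seed, "\n")
  invisible(x)
}

# empirical tail 1 - H_K(x) = #{draws > x}/B against the sorted draws
.tail_prob <- function(x, sorted, B) (B - findInterval(x, sorted)) / B

#' GATE statistic and resampling p-value from Wald statistics
#'
#' Computes \eqn{\eta^{(0)} = \min_K \{1 - \hat H_K(\max \xi)\}} for the
#' observed Wald vector against a pre-built null, and its p-value from
#' the null GATE draws.  Small \eqn{\eta^{(0)}} is strong evidence, so
#' the default p-value counts \eqn{\#\{\eta^{(b)} \le \eta^{(0)}\}/B}
#' (ties included); `paper_formula = TRUE` instead counts strictly
#' greater draws, the literal published counting rule, kept for audit.
#'
#' @param t numeric Wald vector (eigenvalue order) of length `null$m`.
#' @param null a `"gate_null"` from [gate_null()].
#' @param paper_formula logical; see above.
#' @param midp logical; if `TRUE` use the `(r + 1)/(B + 1)` correction so
#'   the p-value can never be exactly zero.
#' @return list with `eta0`, `p_value`, `per_k` (data frame of the
#'   maximizing composition and \eqn{\xi} per `K`), `B`.
#' @export
gate_from_wald <- function(t, null, paper_formula = FALSE, midp = FALSE) {
  stopifnot(inherits(null, "gate_null"))
  if (length(t) != null$m)
    .stop_invalid("Wald vector length ", length(t), " does not match null m = ", null$m)
  per <- lapply(seq_len(null$k_max), function(k) max_xi(t, k))
  xis <- vapply(per, `[[`, 0, "xi")
  tails <- vapply(seq_len(null$k_max), function(k)
    .tail_prob(xis[k], null$hk[[k]], null$B), 0)
  eta0 <- min(tails)
  r <- if (paper_formula) sum(null$eta > eta0) else sum(null$eta <= eta0)
  p <- if (midp) (r + 1) / (null$B + 1) else r / null$B
  list(eta0 = eta0, p_value = p,
       per_k = data.frame(K = seq_len(null$k_max), xi = xis, tail = tails,
                          parts = vapply(per, function(z) paste(z$parts, collapse = "+"), "")),
       B = null$B)
}

#' Test association between multiple traits and one variant with GATE
#'
#' The full pipeline for a single variant: PCA of the trait covariance,
#' per-PC Wald statistics for the genotype (optionally adjusted for
#' covariates), the GATE statistic, and its one-layer resampling p-value.
#'
#' @param y numeric trait matrix (`n` samples by `m` traits, complete).
#' @param g additive genotype dosage vector of length `n`.
#' @param covariates optional covariate matrix (`n` rows).
#' @param null optional pre-built [gate_null()]; building it once and
#'   passing it in is essential when testing many variants.
#' @param k_max,B,seed used to build the null when `null` is `NULL`.
#' @param paper_formula,midp passed to [gate_from_wald()].
#' @return object of class `"gate"`, with a `print()` method; fields
#'   include `statistic` (\eqn{\eta^{(0)}}), `p.value`, `per_k`, `wald`,
#'   `pca`, `B`.
#' @examples
#' sim <- simulate_dataset("S1", n = 500, maf = 0.3, seed = 7)
#' nd <- gate_null(m = 20, B = 1000 * 2, seed = 11)
#' gate_test(sim$y, sim$g, null = nd)
#' @export
gate_test <- function(y, g, covariates = NULL, null = NULL,
                      k_max = 2L, B = 10000L, seed = 1L,
                      paper_formula = FALSE, midp = FALSE) {
  y <- .as_trait_matrix(y)
  if (is.null(null)) null <- gate_null(ncol(y), k_max = k_max, B = B, seed = seed)
  pca <- trait_pca(y)
  t <- pc_wald(pca, g, covariates)
  res <- gate_from_wald(t, null, paper_formula = paper_formula, midp = midp)
  structure(list(statistic = res$eta0, p.value = res$p_value, per_k = res$per_k,
                 wald = t, pca = pca, B = null$B, k_max = null$k_max,
                 method = "GATE (group accumulated test evidence)"),
            class = "gate")
}

#' @export
print.gate <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("traits m =", x$pca$m, ", samples n =", x$pca$n,
      ", resampling B =", x$B, ", k_max =", x$k_max, "\n")
  cat("eta0 =", format(x$statistic, digits = digits), "\n")
  if (x$p.value == 0)
    cat("p-value < ", format(1 / x$B), " (0 of ", x$B, " null draws as extreme)\n", sep = "")
  else cat("p-value =", format(x$p.value, digits = digits), "\n")
  cat("\nPer-K maximizing compositions:\n")
  print(x$per_k, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gate <- function(object, ...) {
  cat("Wald statistics (eigenvalue order):\n")
  print(round(unclass(object$wald), 3))
  print(object)
  invisible(object)
}
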