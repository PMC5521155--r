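# Latent-factor simulation models for correlated quantitative traits.
#
# Model 1 (indirect): the variant acts on block latent factors,
#   U_l = G beta_l + e_l,  Y_i = U_{ceil(i/4)} gamma_i + eps_i,
# giving a block-diagonal trait correlation matrix under the null.
# Model 2 (direct): one shared latent factor plus direct effects,
#   Y_i = U gamma_i + G beta_i + eps_i.
# All error terms are standard normal.

.STRUCTURES <- local({
  g20 <- function(gt) rep(gt, each = 4L)
  list(
    S1  = list(model = 1L, m = 20L,  gamma_tilde = rep(0.5, 5)),
    S2  = list(model = 1L, m = 20L,  gamma_tilde = rep(2.0, 5)),
    S3  = list(model = 1L, m = 20L,  gamma_tilde = c(1.0, 0.8, 0.6, 0.4, 0.2)),
    S4  = list(model = 1L, m = 20L,  gamma_tilde = c(1.5, 1.3, 1.1, 0.9, 0.7)),
    S5  = list(model = 1L, m = 100L, gamma_tilde = rep(0.5, 25)),
    S6  = list(model = 1L, m = 100L, gamma_tilde = rep(2.0, 25)),
    S7  = list(model = 1L, m = 100L, gamma_tilde = 1.0 - 0.04 * (0:24)),
    S8  = list(model = 1L, m = 100L, gamma_tilde = 1.5 - 0.04 * (0:24)),
    S9  = list(model = 2L, m = 20L,  gamma = rep(0.5, 20)),
    S10 = list(model = 2L, m = 20L,  gamma = rep(2.0, 20)),
    S11 = list(model = 2L, m = 20L,  gamma = 1.00 - 0.05 * (0:19)),
    S12 = list(model = 2L, m = 20L,  gamma = 1.50 - 0.05 * (0:19)),
    S13 = list(model = 2L, m = 100L, gamma = rep(0.5, 100)),
    S14 = list(model = 2L, m = 100L, gamma = rep(2.0, 100)),
    # gradients spanning the same range as S11/S12, spread over 100 traits
    S15 = list(model = 2L, m = 100L, gamma = seq(1.00, 0.05, length.out = 100)),
    S16 = list(model = 2L, m = 100L, gamma = seq(1.50, 0.55, length.out = 100))
  )
})

#' Named latent-coefficient structures S1-S16
#'
#' Returns the configuration of one of the sixteen canonical correlation
#' structures: S1-S8 are indirect (Model 1, blocks of four traits per
#' latent factor), S9-S16 direct (Model 2, one shared latent factor);
#' odd/even pairs alternate uniform-low, uniform-strong, and two gradient
#' patterns, for 20 or 100 traits.
#'
#' @param name one of `"S1"` ... `"S16"`, or an existing spec (returned
#'   unchanged).
#' @return object of class `"structure_spec"`: list with `name`, `model`
#'   (1 or 2), `m`, `L` (latent count), `gamma` (length-`m` trait
#'   loadings), `gamma_tilde` (per-latent loadings, Model 1),
#'   `blocks` (latent index per trait), `block_size`.
#' @examples
#' structure_spec("S3")$gamma_tilde
#' @export
structure_spec <- function(name) {
  if (inherits(name, "structure_spec")) return(name)
  if (!is.character(name) || !name %in% names(.STRUCTURES))
    .stop_invalid("unknown structure '", name, "'; expected S1..S16")
  s <- .STRUCTURES[[name]]
  if (s$model == 1L) {
    L <- length(s$gamma_tilde)
    spec <- list(name = name, model = 1L, m = s$m, L = L,
                 gamma = rep(s$gamma_tilde, each = s$m %/% L),
                 gamma_tilde = s$gamma_tilde,
                 blocks = rep(seq_len(L), each = s$m %/% L),
                 block_size = s$m %/% L)
  } else {
    spec <- list(name = name, model = 2L, m = s$m, L = 1L,
                 gamma = s$gamma, gamma_tilde = NULL,
                 blocks = rep(1L, s$m), block_size = s$m)
  }
  structure(spec, class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  cat("Structure", x$name, "- model", x$model, "(",
      if (x$model == 1L) "indirect, latent blocks" else "direct, one shared latent",
      "), m =", x$m, ", L =", x$L, "\n")
  invisible(x)
}

#' Analytic null trait correlation matrix of a structure
#'
#' Under the null (no genetic effect) the correlation between traits
#' `i`, `j` that share a latent factor is
#' \eqn{\gamma_i\gamma_j/\sqrt{(1+\gamma_i^2)(1+\gamma_j^2)}}; for
#' Model 1 the matrix is block diagonal (zero across latent blocks),
#' for Model 2 every pair shares the latent.
#'
#' @param spec a structure name or [structure_spec()] object.
#' @return `m x m` correlation matrix.
#' @examples
#' max(analytic_correlation("S3") - diag(20))  # 0.5
#' @export
analytic_correlation <- function(spec) {
  spec <- structure_spec(spec)
  g <- spec$gamma
  r <- outer(g, g) / sqrt(outer(1 + g^2, 1 + g^2))
  if (spec$model == 1L)
    r <- r * outer(spec$blocks, spec$blocks, `==`)
  diag(r) <- 1
  r
}

#' Effect sizes reproducing a target per-trait explained variance
#'
#' Inverts the closed-form explained-variance expressions of the two
#' models.  Model 1: a trait loading on latent `l` with coefficient
#' \eqn{\gamma} has explained variance
#' \eqn{h^2 = 2p(1-p)\beta^2\gamma^2 / (1 + \gamma^2 + 2p(1-p)\beta^2\gamma^2)},
#' so \eqn{\beta = \sqrt{h^2 (1+\gamma^2) / (2p(1-p)\gamma^2(1-h^2))}}.
#' Model 2: \eqn{h^2 = 2p(1-p)\beta^2 / (\sum_k \gamma_k^2 + 1 + 2p(1-p)\beta^2)},
#' so \eqn{\beta = \sqrt{h^2 (\sum_k\gamma_k^2 + 1) / (2p(1-p)(1-h^2))}}.
#'
#' @param h2 target explained-variance fraction in `[0, 1)`.
#' @param maf minor allele frequency `p` in `(0, 0.5]`.
#' @param gamma latent-to-trait coefficient(s); for `solve_beta_model2`
#'   the vector of loadings \eqn{\gamma_{ik}} of the trait.
#' @return the non-negative effect size `beta` (vectorized over `gamma`
#'   for Model 1).
#' @export
solve_beta_model1 <- function(h2, maf, gamma) {
  stopifnot(h2 >= 0, h2 < 1, maf > 0, maf <= 0.5)
  if (h2 == 0) return(rep(0, length(gamma)))
  if (any(gamma == 0)) .stop_invalid("gamma = 0 cannot carry a nonzero explained variance")
  sqrt(h2 * (1 + gamma^2) / (2 * maf * (1 - maf) * gamma^2 * (1 - h2)))
}

#' @rdname solve_beta_model1
#' @export
solve_beta_model2 <- function(h2, maf, gamma) {
  stopifnot(h2 >= 0, h2 < 1, maf > 0, maf <= 0.5)
  if (h2 == 0) return(0)
  sqrt(h2 * (sum(gamma^2) + 1) / (2 * maf * (1 - maf) * (1 - h2)))
}

#' Simulate additive genotypes under Hardy-Weinberg equilibrium
#'
#' Dosages 0/1/2 with probabilities \eqn{(1-p)^2, 2p(1-p), p^2}; a
#' monomorphic draw is resampled (with a message) so downstream
#' regressions are defined.
#'
#' @param n sample size.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param seed optional seed (local RNG scope).
#' @return integer vector of length `n`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) .stop_invalid("maf must be in (0, 0.5]")
  draw <- function() {
    g <- rbinom(n, 2L, maf)
    tries <- 0L
    while (var(g) == 0 && tries < 100L) {
      tries <- tries + 1L
      g <- rbinom(n, 2L, maf)
    }
    if (tries > 0L) message("monomorphic genotype draw resampled ", tries, " time(s)")
    g
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# choose which traits are associated; Model 1 activates whole latent blocks
.assoc_traits <- function(spec, lambda, assignment) {
  k <- round(lambda * spec$m)
  if (k == 0L) return(integer(0))
  if (spec$model == 1L && k %% spec$block_size != 0L)
    .stop_invalid("lambda * m must be a multiple of the block size (",
                  spec$block_size, ") for Model 1")
  if (assignment == "first") return(seq_len(k))
  if (spec$model == 1L) {
    latents <- sample(seq_len(spec$L), k %/% spec$block_size)
    return(which(spec$blocks %in% latents))
  }
  sort(sample(seq_len(spec$m), k))
}

#' Simulate one dataset of correlated traits and a genotype
#'
#' Draws a genotype under Hardy-Weinberg equilibrium and traits from the
#' structure's latent-factor model, with effect sizes solved so every
#' associated trait has explained variance `h2` ([solve_beta_model1()] /
#' [solve_beta_model2()]).  `h2 = 0` or `lambda = 0` gives a null
#' dataset.
#'
#' @param spec structure name (`"S1"`..`"S16"`) or [structure_spec()].
#' @param n sample size; default follows the grid convention of 1500 for
#'   `maf <= 0.15` and 1000 otherwise.
#' @param maf minor allele frequency.
#' @param h2 per-associated-trait explained variance in `[0, 1)`.
#' @param lambda fraction of traits associated (Model 1: activates whole
#'   latent blocks, so `lambda * m` must be a multiple of 4).
#' @param assignment `"first"` (first `lambda * m` traits) or `"random"`.
#' @param seed optional seed (local RNG scope).
#' @return list with `y` (trait matrix), `g` (genotype), `beta`
#'   (per-latent effects for Model 1, per-trait for Model 2),
#'   `associated` (trait indices) and `spec`.
#' @examples
#' d <- simulate_dataset("S9", n = 200, maf = 0.3, h2 = 0.01, lambda = 1, seed = 1)
#' dim(d$y)
#' @export
simulate_dataset <- function(spec, n = NULL, maf = 0.3, h2 = 0, lambda = 0,
                             assignment = c("first", "random"), seed = NULL) {
  spec <- structure_spec(spec)
  assignment <- match.arg(assignment)
  if (is.null(n)) n <- if (maf <= 0.15) 1500L else 1000L
  run <- function() {
    g <- simulate_genotypes(n, maf)
    assoc <- .assoc_traits(spec, lambda, assignment)
    if (spec$model == 1L) {
      beta <- rep(0, spec$L)
      if (length(assoc) && h2 > 0) {
        act <- unique(spec$blocks[assoc])
        beta[act] <- solve_beta_model1(h2, maf, spec$gamma_tilde[act])
      }
      u <- outer(g, beta) + matrix(rnorm(n * spec$L), n, spec$L)
      y <- u[, spec$blocks, drop = FALSE] *
        rep(spec$gamma, each = n) + matrix(rnorm(n * spec$m), n, spec$m)
    } else {
      beta <- rep(0, spec$m)
      if (length(assoc) && h2 > 0)
        beta[assoc] <- vapply(assoc, function(i)
          solve_beta_model2(h2, maf, spec$gamma[i]), 0)
      u <- rnorm(n)
      y <- outer(u, spec$gamma) + outer(g, beta) + matrix(rnorm(n * spec$m), n, spec$m)
    }
    colnames(y) <- paste0("trait", seq_len(spec$m))
    list(y = y, g = g, beta = beta, associated = assoc, spec = spec)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
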