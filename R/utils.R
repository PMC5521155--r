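# internal helpers shared across modules

# log survival of the central chi-squared distribution; the grouped Fisher
# statistic must never be formed as log(1 - pchisq(...)) or it underflows
# for strong signals
.lsf_chisq <- function(x, df) pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE)

# largest finite value a -2*log tail probability may take before we saturate
.XI_CAP <- -2 * log(.Machine$double.xmin)

.cap_xi <- function(xi) {
  if (!all(is.finite(xi))) {
    warning("grouped Fisher statistic saturated at the smallest representable tail",
            call. = FALSE)
    xi[!is.finite(xi)] <- .XI_CAP
  }
  xi
}

.stop_invalid <- function(...) stop(..., call. = FALSE)

# deterministic per-replicate seed derived from (master seed, scenario label,
# replicate index); kept below 2^31 - 1 so it is a valid R integer seed
.derive_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label)))) %% 99991
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + h * 131 + index) %% 2147483647L
}

.as_trait_matrix <- function(y, min_traits = 2L) {
  y <- as.matrix(y)
  if (!is.numeric(y)) .stop_invalid("trait matrix must be numeric")
  if (anyNA(y)) .stop_invalid("trait matrix contains missing values; resolve them with qc_filter() first")
  if (nrow(y) < 3L) .stop_invalid("need at least 3 samples")
  if (ncol(y) < min_traits) .stop_invalid("need at least ", min_traits, " traits")
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(ncol(y)))
  y
}

.check_genotype <- function(g, n = NULL) {
  g <- as.numeric(g)
  if (anyNA(g)) .stop_invalid("genotype vector contains missing values")
  if (!is.null(n) && length(g) != n)
    .stop_invalid("genotype length (", length(g), ") does not match sample count (", n, ")")
  if (var(g) == 0) .stop_invalid("monomorphic variant: genotype is constant")
  g
}

# folded minor allele frequency of an additive 0/1/2 dosage vector
.fold_maf <- function(g) {
  f <- mean(g, na.rm = TRUE) / 2
  min(f, 1 - f)
}
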