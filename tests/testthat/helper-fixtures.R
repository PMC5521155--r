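# shared fixtures built in code

# small trait matrix with a known covariance pattern
make_traits <- function(n = 200, m = 4, seed = 42) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    y <- outer(f, rep(1, m)) * seq(0.2, 1, length.out = m) + matrix(rnorm(n * m), n, m)
    colnames(y) <- paste0("t", seq_len(m))
    y
  })
}

make_genotype <- function(n = 200, maf = 0.3, seed = 7) {
  withr::with_seed(seed, rbinom(n, 2, maf))
}

# independent two-layer resampling oracle for the GATE null: the inner
# ECDFs come from a separate draw set instead of being reused
two_layer_eta <- function(tmat, inner_tmat, k_max) {
  Bi <- nrow(inner_tmat)
  inner <- gatetest:::.maxxi_matrix(inner_tmat, k_max)
  outer_mx <- gatetest:::.maxxi_matrix(tmat, k_max)
  sapply(seq_len(nrow(tmat)), function(b) {
    min(vapply(seq_len(k_max), function(k)
      sum(inner[, k] > outer_mx[b, k]) / Bi, 0))
  })
}

# write a phenotype TSV in the package's input format
write_pheno_tsv <- function(y, path, ids = paste0("s", seq_len(nrow(y)))) {
  df <- data.frame(sample = ids, y, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_geno_tsv <- function(g, path, ids) {
  # g: variants x samples matrix
  df <- data.frame(variant = rownames(g), g, check.names = FALSE)
  colnames(df) <- c("variant", ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
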