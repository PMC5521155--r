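# File input and quality control for genome scans.
#
# Phenotypes: TSV, first column sample ID, header of trait names, NA or
# empty cells missing.  Genotypes: TSV with rows = variants (first column
# variant ID, header of sample IDs, entries 0/1/2/NA) or VCF (biallelic
# records, additive ALT dosage from GT, ./. missing).

#' Read a phenotype matrix from TSV
#'
#' @param path TSV file; first column sample IDs, header row trait names.
#' @return numeric matrix (samples x traits) with sample IDs as row
#'   names; missing entries are `NA`.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) .stop_invalid("phenotype file needs a sample-ID column plus traits")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) .stop_invalid("duplicate sample IDs: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  y <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(y)) .stop_invalid("non-numeric phenotype entries")
  rownames(y) <- ids
  y
}

#' Read genotype dosages from TSV or VCF
#'
#' @param path input file.
#' @param format `"tsv"` (rows = variants, columns = samples) or
#'   `"vcf"` (needs the \pkg{vcfR} package; biallelic records only,
#'   multi-allelic records are skipped with a warning; `./.` is missing).
#' @return numeric matrix, variants in rows (row names = variant IDs),
#'   samples in columns; dosage counts ALT alleles, `NA` missing.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, na.strings = c("NA", "", "."))
    ids <- as.character(df[[1L]])
    gm <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(gm)) .stop_invalid("non-numeric genotype entries")
    if (any(gm < 0 | gm > 2, na.rm = TRUE)) .stop_invalid("dosages must be in [0, 2]")
    rownames(gm) <- ids
    return(gm)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stop_invalid("reading VCF needs the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.numeric(strsplit(x, "[/|]")[[1L]]) > 0)
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dos) <- ids
  dos
}

#' Quality-control filtering of traits, samples and variants
#'
#' Applies, in order: (1) drop traits whose missingness exceeds
#' `trait_miss`; (2) drop samples with any remaining missing phenotype;
#' (3) drop variants whose missingness (on retained samples) exceeds
#' `var_miss` or whose folded MAF is below `maf_floor`.
#'
#' @param y phenotype matrix (samples x traits, may contain `NA`).
#' @param g genotype matrix (variants x samples, may contain `NA`).
#' @param trait_miss,var_miss,maf_floor thresholds (defaults 0.01, 0.15,
#'   0.05).
#' @return list of class `"qc_report"` with `y`, `g` (filtered, samples
#'   aligned) and `report` (counts dropped at each step).
#' @export
qc_filter <- function(y, g, trait_miss = 0.01, var_miss = 0.15, maf_floor = 0.05) {
  y <- as.matrix(y); g <- as.matrix(g)
  common <- intersect(rownames(y), colnames(g))
  if (length(common) == 0L) .stop_invalid("no overlapping sample IDs between phenotypes and genotypes")
  missing_ids <- setdiff(rownames(y), colnames(g))
  y <- y[common, , drop = FALSE]
  g <- g[, common, drop = FALSE]
  tm <- colMeans(is.na(y))
  keep_t <- tm <= trait_miss
  y <- y[, keep_t, drop = FALSE]
  keep_s <- complete.cases(y)
  y <- y[keep_s, , drop = FALSE]
  g <- g[, keep_s, drop = FALSE]
  vm <- rowMeans(is.na(g))
  maf <- apply(g, 1L, .fold_maf)
  keep_v <- vm <= var_miss & maf >= maf_floor & !is.na(maf)
  g <- g[keep_v, , drop = FALSE]
  rep <- list(traits_dropped = sum(!keep_t), samples_dropped = sum(!keep_s),
              variants_dropped = sum(!keep_v),
              traits_kept = ncol(y), samples_kept = nrow(y), variants_kept = nrow(g),
              unmatched_samples = length(missing_ids))
  if (ncol(y) < 2L || nrow(y) < 3L || nrow(g) < 1L)
    .stop_invalid("nothing left after QC filtering: ",
                  paste(names(rep), unlist(rep), sep = "=", collapse = ", "))
  structure(list(y = y, g = g, report = rep), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC filter report:\n")
  for (nm in names(x$report)) cat("  ", nm, ":", x$report[[nm]], "\n")
  invisible(x)
}

#' Genome scan: GATE and comparators over many variants
#'
#' Runs the requested tests for every variant against one phenotype
#' matrix.  PCA is computed once on the QC-filtered traits and the GATE
#' resampling null is built once, so per-variant work is a pair of
#' regressions plus the grouped combination.  Missing genotypes at
#' retained variants are mean-imputed by default, keeping the per-variant
#' sample set identical to the PCA sample set (required for the shared
#' null); `impute = "complete"` instead drops incomplete samples per
#' variant (PCA and null still come from the full filtered set).
#'
#' @param y phenotype matrix (samples x traits) or path readable by
#'   [read_phenotypes()].
#' @param g genotype matrix (variants x samples) or path.
#' @param geno_format `"tsv"` or `"vcf"` when `g` is a path.
#' @param covariates optional covariate matrix (rows matching samples).
#' @param methods tests to run per variant.
#' @param B,k_max,seed GATE null parameters.
#' @param alpha nominal level used for the Bonferroni threshold in the
#'   result attributes.
#' @param qc logical: apply [qc_filter()] (default `TRUE`).
#' @param trait_miss,var_miss,maf_floor QC thresholds.
#' @param impute `"mean"` or `"complete"` handling of missing genotypes.
#' @param null optional pre-built [gate_null()].
#' @param cache optional directory for the null cache.
#' @param paper_formula passed to [gate_from_wald()].
#' @return data frame, one row per variant: `variant`, `maf`, and
#'   `<method>_stat` / `<method>_p` columns; attributes `bonferroni`
#'   (adjusted threshold `alpha / n_variants`), `qc` (report), `B`,
#'   `seed`.
#' @export
gate_scan <- function(y, g, geno_format = c("tsv", "vcf"), covariates = NULL,
                      methods = c("TATES", "MANOVA", "MultiPhen", "mCPC", "GATE"),
                      B = 10000L, k_max = 2L, seed = 1L, alpha = 0.05,
                      qc = TRUE, trait_miss = 0.01, var_miss = 0.15,
                      maf_floor = 0.05, impute = c("mean", "complete"),
                      null = NULL, cache = NULL, paper_formula = FALSE) {
  impute <- match.arg(impute)
  methods <- match.arg(methods, .ALL_METHODS, several.ok = TRUE)
  if (is.character(y)) y <- read_phenotypes(y)
  if (is.character(g)) g <- read_genotypes(g, match.arg(geno_format))
  if (is.null(rownames(y))) rownames(y) <- paste0("s", seq_len(nrow(y)))
  if (is.null(colnames(g))) colnames(g) <- rownames(y)
  qcr <- if (qc) qc_filter(y, g, trait_miss, var_miss, maf_floor)
         else {
           common <- intersect(rownames(y), colnames(g))
           list(y = y[common, , drop = FALSE], g = g[, common, drop = FALSE],
                report = NULL)
         }
  y <- qcr$y; g <- qcr$g
  pca <- trait_pca(y)
  tcor <- cor(y)
  if ("GATE" %in% methods && is.null(null))
    null <- gate_null(ncol(y), k_max = k_max, B = B, seed = as.integer(seed),
                      cache = cache)
  rows <- vector("list", nrow(g))
  for (v in seq_len(nrow(g))) {
    gv <- g[v, ]
    if (anyNA(gv)) {
      if (impute == "mean") gv[is.na(gv)] <- mean(gv, na.rm = TRUE)
      else {
        keep <- !is.na(gv)
        gv <- gv[keep]
      }
    }
    keep <- if (length(gv) == nrow(y)) rep(TRUE, nrow(y)) else !is.na(g[v, ])
    row <- list(variant = rownames(g)[v], maf = .fold_maf(gv))
    for (meth in methods) {
      res <- tryCatch({
        yv <- y[keep, , drop = FALSE]
        switch(meth,
          GATE = {
            tt <- suppressWarnings(pc_wald(
              if (all(keep)) pca else trait_pca(yv), gv, covariates))
            r <- gate_from_wald(tt, null, paper_formula = paper_formula)
            c(r$eta0, r$p_value)
          },
          FCT = { tt <- suppressWarnings(pc_wald(if (all(keep)) pca else trait_pca(yv), gv, covariates))
                  h <- fct_test(tt); c(h$statistic, h$p.value) },
          mCPC = { pp <- if (all(keep)) pca else trait_pca(yv)
                   tt <- suppressWarnings(pc_wald(pp, gv, covariates))
                   h <- mcpc_test(tt, pp$values); c(h$statistic, h$p.value) },
          MANOVA = { h <- manova_test(yv, gv); c(h$statistic, h$p.value) },
          TATES = { h <- tates_test(univariate_trait_tests(yv, gv, covariates),
                                    if (all(keep)) tcor else cor(yv))
                    c(h$statistic, h$p.value) },
          MultiPhen = { h <- multiphen_test(yv, gv); c(h$statistic, h$p.value) })
      }, error = function(e) c(NA_real_, NA_real_))
      row[[paste0(meth, "_stat")]] <- res[1L]
      row[[paste0(meth, "_p")]] <- res[2L]
    }
    rows[[v]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- alpha / nrow(g)
  attr(out, "qc") <- qcr$report
  attr(out, "B") <- if (is.null(null)) NA_integer_ else null$B
  attr(out, "seed") <- as.integer(seed)
  out
}
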