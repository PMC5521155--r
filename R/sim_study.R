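# Simulation-study drivers: type-I-error and power experiments over
# (structure, MAF, lambda, h2) grids, with one shared GATE null per m.

.ALL_METHODS <- c("TATES", "MANOVA", "MultiPhen", "mCPC", "GATE", "FCT")

#' Run one simulation scenario
#'
#' Simulates `reps` datasets from a structure at the given MAF, effect
#' size and association fraction, applies the requested tests to each,
#' and returns per-method rejection proportions at level `alpha`.  The
#' GATE resampling null is built once (or passed in) and reused across
#' replicates; it depends only on the number of traits.  Method failures
#' (e.g. proportional-odds non-convergence) are counted and excluded
#' from the rejection denominator.
#'
#' @param structure structure name or [structure_spec()].
#' @param maf minor allele frequency.
#' @param n sample size; `NULL` uses 1500 for `maf <= 0.15`, else 1000.
#' @param h2,lambda effect size per associated trait and associated
#'   fraction; both 0 gives a type-I-error scenario.
#' @param methods subset of TATES, MANOVA, MultiPhen, mCPC, GATE, FCT.
#' @param reps number of replicates.
#' @param alpha nominal level.
#' @param B,k_max resampling-null parameters for GATE.
#' @param seed master seed; each replicate derives its own seed from
#'   `(seed, scenario label, replicate index)` so any one replicate can
#'   be re-run in isolation.
#' @param null optional pre-built [gate_null()] (must match `m`, `k_max`).
#' @param assignment passed to [simulate_dataset()].
#' @param keep_pvalues if `TRUE`, the reps-by-methods p-value matrix is
#'   attached.
#' @return object of class `"scenario_result"`: list with `rejection`
#'   (named vector), `se` (Monte-Carlo standard errors), `n_fail`,
#'   `reps`, `alpha` and the scenario descriptors.
#' @export
run_scenario <- function(structure, maf, n = NULL, h2 = 0, lambda = 0,
                         methods = c("TATES", "MANOVA", "MultiPhen", "mCPC", "GATE"),
                         reps = 1000L, alpha = 0.05, B = 10000L, k_max = 2L,
                         seed = 1L, null = NULL, assignment = "first",
                         keep_pvalues = FALSE) {
  spec <- structure_spec(structure)
  methods <- match.arg(methods, .ALL_METHODS, several.ok = TRUE)
  reps <- as.integer(reps)
  if (reps < 1L) .stop_invalid("reps must be positive")
  if (is.null(n)) n <- if (maf <= 0.15) 1500L else 1000L
  label <- paste(spec$name, maf, n, h2, lambda, assignment, sep = "|")
  if (any(c("GATE") %in% methods) && is.null(null))
    null <- gate_null(spec$m, k_max = k_max, B = B,
                      seed = .derive_seed(seed, paste0("null", spec$m)))
  if (!is.null(null) && null$m != spec$m)
    .stop_invalid("supplied null has m = ", null$m, " but structure has m = ", spec$m)
  pmat <- matrix(NA_real_, reps, length(methods), dimnames = list(NULL, methods))
  need_pca <- any(c("GATE", "mCPC", "FCT") %in% methods)
  for (r in seq_len(reps)) {
    d <- simulate_dataset(spec, n = n, maf = maf, h2 = h2, lambda = lambda,
                          assignment = assignment,
                          seed = .derive_seed(seed, label, r))
    if (need_pca) {
      pca <- suppressWarnings(trait_pca(d$y))
      tt <- suppressWarnings(pc_wald(pca, d$g))
    }
    for (meth in methods) {
      pmat[r, meth] <- tryCatch(switch(meth,
        GATE      = gate_from_wald(tt, null)$p_value,
        FCT       = fct_test(tt)$p.value,
        mCPC      = mcpc_test(tt, pca$values)$p.value,
        MANOVA    = manova_test(d$y, d$g)$p.value,
        TATES     = tates_test(univariate_trait_tests(d$y, d$g), cor(d$y))$p.value,
        MultiPhen = multiphen_test(d$y, d$g)$p.value),
        error = function(e) NA_real_)
    }
  }
  ok <- colSums(!is.na(pmat))
  rej <- colSums(pmat <= alpha, na.rm = TRUE) / ok
  out <- list(structure = spec$name, m = spec$m, maf = maf, n = n, h2 = h2,
              lambda = lambda, alpha = alpha, reps = reps, B = if (is.null(null)) NA else null$B,
              k_max = if (is.null(null)) NA else null$k_max, seed = seed,
              rejection = rej, se = sqrt(rej * (1 - rej) / ok),
              n_fail = reps - ok)
  if (keep_pvalues) out$pvalues <- pmat
  structure(out, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$structure, "(m =", x$m, ") MAF =", x$maf, ", n =", x$n,
      ", h2 =", x$h2, ", lambda =", x$lambda, "\n")
  cat(x$reps, "replicates at alpha =", x$alpha, "\n")
  tab <- rbind(rejection = round(x$rejection, 4), `MC s.e.` = round(x$se, 4),
               failures = x$n_fail)
  print(tab)
  invisible(x)
}

#' Scenario grids matching the published tables and figures
#'
#' Enumerates the factorial scenario lists of the simulation study:
#' `table1`/`table2` are null grids over the eight indirect / eight
#' direct structures by four MAFs; `fig2`..`fig5` are power grids over
#' five association fractions with the per-structure explained variances
#' used in the corresponding figure (fig2: 0.1/0.2/0.1/0.2%; fig3:
#' 0.1/0.1/0.05/0.1%; fig4: 0.2/0.1/0.2/0.2%; fig5: all 0.1%).
#'
#' @param id one of `"table1"`, `"table2"`, `"fig2"`, `"fig3"`,
#'   `"fig4"`, `"fig5"`.
#' @return data frame with columns `structure`, `maf`, `n`, `h2`,
#'   `lambda`.
#' @export
paper_grid <- function(id = c("table1", "table2", "fig2", "fig3", "fig4", "fig5")) {
  id <- match.arg(id)
  mafs <- c(0.05, 0.15, 0.30, 0.50)
  lam <- seq(0.2, 1, by = 0.2)
  cfg <- switch(id,
    table1 = list(st = paste0("S", 1:8),   h2 = rep(0, 8),   lam = 0),
    table2 = list(st = paste0("S", 9:16),  h2 = rep(0, 8),   lam = 0),
    fig2   = list(st = paste0("S", 1:4),   h2 = c(0.001, 0.002, 0.001, 0.002),  lam = lam),
    fig3   = list(st = paste0("S", 5:8),   h2 = c(0.001, 0.001, 0.0005, 0.001), lam = lam),
    fig4   = list(st = paste0("S", 9:12),  h2 = c(0.002, 0.001, 0.002, 0.002),  lam = lam),
    fig5   = list(st = paste0("S", 13:16), h2 = rep(0.001, 4),                  lam = lam))
  g <- expand.grid(structure = cfg$st, maf = mafs, lambda = cfg$lam,
                   stringsAsFactors = FALSE)
  g$h2 <- cfg$h2[match(g$structure, cfg$st)] * (g$lambda > 0)
  g$n <- ifelse(g$maf <= 0.15, 1500L, 1000L)
  g[, c("structure", "maf", "n", "h2", "lambda")]
}

#' Tabulate scenario results in the published layout
#'
#' Binds scenario results into a data frame with one row per scenario
#' and the method columns in the order TATES, MANOVA, MultiPhen, mCPC,
#' GATE (missing methods left blank), optionally writing a TSV.
#'
#' @param results list of `"scenario_result"` objects.
#' @param file optional path for a TSV copy.
#' @return the data frame, invisibly if written.
#' @export
render_tables <- function(results, file = NULL) {
  cols <- c("TATES", "MANOVA", "MultiPhen", "mCPC", "GATE")
  rows <- lapply(results, function(r) {
    vals <- setNames(rep(NA_real_, length(cols)), cols)
    keep <- intersect(names(r$rejection), cols)
    vals[keep] <- r$rejection[keep]
    cbind(data.frame(structure = r$structure, maf = r$maf, n = r$n,
                     h2 = r$h2, lambda = r$lambda, reps = r$reps),
          as.data.frame(as.list(vals)))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
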