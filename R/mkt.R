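# Per-gene McDonald-Kreitman tests with FDR correction.

#' Per-gene McDonald-Kreitman tests
#'
#' For every gene with strictly positive Dn, Ds, Pn and Ps, tests
#' independence of the 2x2 table \[\[Dn, Ds\], \[Pn, Ps\]\] (Pearson
#' chi-square without continuity correction by default; Fisher's exact test
#' available for the small counts typical of closely related species). Genes
#' with any zero cell are excluded from testing — the test is undefined there
#' — and reported with `excluded_reason = "zero cell"`. P-values are
#' Benjamini-Hochberg adjusted across all tested genes; a gene is flagged
#' significant when its adjusted p-value is at most `fdr` *and* its
#' neutrality ratio (Dn/Ds)/(Pn/Ps) exceeds 1 (an excess of amino-acid
#' fixation, the positive-selection direction).
#'
#' @param counts data frame with columns `gene_id`, `Dn`, `Ds`, `Pn`, `Ps`
#' @param method `"chisq"` (Pearson, no continuity correction) or `"fisher"`
#' @param fdr significance level on the FDR-adjusted p-value
#' @return an object of class `mkt_results`: the per-gene results data frame
#'   (columns `gene_id`, `Dn`, `Ds`, `Pn`, `Ps`, `eligible`, `chi2`,
#'   `p_raw`, `q_fdr`, `ratio`, `direction`, `significant`) with the test
#'   settings as attributes
#' @export
mkt <- function(counts, method = c("chisq", "fisher"), fdr = 0.05) {
  method <- match.arg(method)
  need <- c("gene_id", "Dn", "Ds", "Pn", "Ps")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  res <- counts[, need]
  res$eligible <- with(res, Dn > 0 & Ds > 0 & Pn > 0 & Ps > 0)
  res$chi2 <- NA_real_
  res$p_raw <- NA_real_
  res$ratio <- with(res, ifelse(Ds > 0 & Pn > 0 & Ps > 0,
                                (Dn / Ds) / (Pn / Ps), NA_real_))
  for (i in which(res$eligible)) {
    tab <- matrix(c(res$Dn[i], res$Ds[i], res$Pn[i], res$Ps[i]),
                  nrow = 2, byrow = TRUE)
    if (method == "chisq") {
      t <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res$chi2[i] <- unname(t$statistic)
      res$p_raw[i] <- t$p.value
    } else {
      res$p_raw[i] <- stats::fisher.test(tab)$p.value
    }
  }
  res$q_fdr <- NA_real_
  res$q_fdr[res$eligible] <- stats::p.adjust(res$p_raw[res$eligible],
                                             method = "BH")
  res$direction <- ifelse(is.na(res$ratio), NA_character_,
                          ifelse(res$ratio > 1, "positive", "negative"))
  res$significant <- res$eligible & !is.na(res$q_fdr) & res$q_fdr <= fdr &
    res$ratio > 1
  res$excluded_reason <- ifelse(res$eligible, NA_character_, "zero cell")
  structure(res, class = c("mkt_results", "data.frame"),
            method = method, fdr = fdr)
}

#' Recompute FDR-adjusted p-values for MKT results
#'
#' Benjamini-Hochberg step-up over all tested genes; used internally by
#' [mkt()] and exported to re-adjust after subsetting genes.
#'
#' @param results an `mkt_results` object (or data frame with `p_raw` and
#'   `eligible`)
#' @param fdr significance level
#' @return the results with `q_fdr` and `significant` recomputed
#' @export
fdr_correct <- function(results, fdr = 0.05) {
  results$q_fdr <- NA_real_
  results$q_fdr[results$eligible] <-
    stats::p.adjust(results$p_raw[results$eligible], method = "BH")
  results$significant <- results$eligible & !is.na(results$q_fdr) &
    results$q_fdr <= fdr & results$ratio > 1
  attr(results, "fdr") <- fdr
  results
}

#' @export
print.mkt_results <- function(x, ...) {
  n_tested <- sum(x$eligible)
  n_sig <- sum(x$significant)
  cat(sprintf(
    "McDonald-Kreitman tests (%s): %d genes, %d testable (non-zero cells), %d significant at FDR %.2g\n",
    attr(x, "method"), nrow(x), n_tested, n_sig, attr(x, "fdr")))
  if (n_sig > 0) {
    sig <- x[x$significant, c("gene_id", "Dn", "Ds", "Pn", "Ps", "ratio",
                              "p_raw", "q_fdr")]
    print.data.frame(sig, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.mkt_results <- function(object, ...) {
  out <- list(
    n_genes = nrow(object),
    n_tested = sum(object$eligible),
    n_excluded = sum(!object$eligible),
    n_significant = sum(object$significant),
    prop_significant = sum(object$significant) / max(1, sum(object$eligible)),
    method = attr(object, "method"),
    fdr = attr(object, "fdr")
  )
  class(out) <- "summary.mkt_results"
  out
}

#' @export
print.summary.mkt_results <- function(x, ...) {
  cat("McDonald-Kreitman test summary\n")
  cat(sprintf("  genes:        %d\n", x$n_genes))
  cat(sprintf("  testable:     %d (%d excluded for zero cells)\n",
              x$n_tested, x$n_excluded))
  cat(sprintf("  significant:  %d (%.1f%%) at FDR %.2g, %s test\n",
              x$n_significant, 100 * x$prop_significant, x$fdr, x$method))
  invisible(x)
}
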