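# Transcriptome-wide adaptive substitution fraction alpha: aggregate
# (summed-counts) estimator with a bootstrap over genes.

#' Estimate the adaptive substitution fraction alpha
#'
#' Computes the aggregate estimator
#' \deqn{\alpha = 1 - \frac{\sum D_s \sum P_n}{\sum D_n \sum P_s}}
#' over gene-summed substitution and polymorphism counts, with a confidence
#' interval from resampling genes with replacement. Polymorphism counts are
#' expected to have the requested frequency-class exclusion already applied
#' (see [pool_gene_counts()] or [truth_gene_counts()]); `exclusion_mode` is
#' recorded on the fit for reporting.
#'
#' @param counts data frame with columns `Dn`, `Ds`, `Pn`, `Ps` (one row per
#'   gene)
#' @param exclusion_mode label of the SNP frequency-class exclusion applied
#'   upstream: `"none"`, `"low"` or `"low_moderate"`
#' @param n_bootstrap number of bootstrap resamples of genes
#' @param conf_level confidence level of the percentile interval
#' @param seed optional integer seed for the bootstrap RNG
#' @return an object of class `alpha_fit` with components `alpha`, `ci_low`,
#'   `ci_high`, `n_genes`, `exclusion_mode`, `n_bootstrap`, `boot`
#'   (replicate estimates), `totals`
#' @export
estimate_alpha <- function(counts,
                           exclusion_mode = c("none", "low", "low_moderate"),
                           n_bootstrap = 1000, conf_level = 0.95,
                           seed = NULL) {
  exclusion_mode <- match.arg(exclusion_mode)
  need <- c("Dn", "Ds", "Pn", "Ps")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  m <- as.matrix(counts[, need])
  if (any(m < 0)) stop("counts must be non-negative")
  n <- nrow(m)
  if (n < 2) stop("alpha estimation needs at least 2 genes")
  tot <- colSums(m)
  if (tot["Dn"] == 0 || tot["Ps"] == 0) {
    stop("alpha undefined: total Dn and total Ps must be positive")
  }
  alpha <- .alpha_from_totals(tot)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .alpha_from_totals(colSums(m[idx, , drop = FALSE]))
    }, numeric(1))
    ok <- is.finite(boot)
    if (sum(ok) >= 2) {
      a <- (1 - conf_level) / 2
      ci <- unname(stats::quantile(boot[ok], c(a, 1 - a)))
    }
  }
  fit <- list(alpha = alpha, ci_low = ci[1], ci_high = ci[2],
              n_genes = n, exclusion_mode = exclusion_mode,
              n_bootstrap = n_bootstrap, conf_level = conf_level,
              boot = boot, totals = tot,
              n_boot_undefined = sum(!is.finite(boot)))
  class(fit) <- "alpha_fit"
  if (is.finite(ci[1]) && (alpha < ci[1] || alpha > ci[2])) {
    message("alpha point estimate lies outside its bootstrap interval")
  }
  fit
}

.alpha_from_totals <- function(tot) {
  if (tot[["Dn"]] == 0 || tot[["Ps"]] == 0) return(NA_real_)
  1 - (tot[["Ds"]] * tot[["Pn"]]) / (tot[["Dn"]] * tot[["Ps"]])
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf(
    "alpha = %.3f (%d%% CI %.3f-%.3f), %d genes, exclusion: %s, %d bootstraps\n",
    x$alpha, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$n_genes, x$exclusion_mode, x$n_bootstrap))
  invisible(x)
}

#' @export
summary.alpha_fit <- function(object, ...) {
  cat("Adaptive substitution fraction (aggregate estimator)\n")
  cat(sprintf("  alpha:      %.4f\n", object$alpha))
  cat(sprintf("  %d%% CI:     [%.4f, %.4f] (percentile bootstrap, %d resamples",
              round(100 * object$conf_level), object$ci_low, object$ci_high,
              object$n_bootstrap))
  if (object$n_boot_undefined > 0) {
    cat(sprintf(", %d undefined replicates dropped", object$n_boot_undefined))
  }
  cat(")\n")
  cat(sprintf("  genes:      %d, SNP exclusion: %s\n",
              object$n_genes, object$exclusion_mode))
  cat(sprintf("  totals:     Dn=%g Ds=%g Pn=%g Ps=%g\n",
              object$totals[["Dn"]], object$totals[["Ds"]],
              object$totals[["Pn"]], object$totals[["Ps"]]))
  invisible(object)
}

#' @export
coef.alpha_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
confint.alpha_fit <- function(object, parm = "alpha", level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level) {
    ok <- is.finite(object$boot)
    if (sum(ok) < 2) stop("no bootstrap replicates stored")
    a <- (1 - level) / 2
    ci <- unname(stats::quantile(object$boot[ok], c(a, 1 - a)))
  } else {
    level <- object$conf_level
    ci <- c(object$ci_low, object$ci_high)
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("alpha",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}

#' @export
plot.alpha_fit <- function(x, ...) {
  if (length(x$boot) == 0) stop("no bootstrap replicates to plot")
  graphics::hist(x$boot[is.finite(x$boot)], breaks = 30,
                 main = "Bootstrap distribution of alpha",
                 xlab = expression(alpha), ...)
  graphics::abline(v = x$alpha, lwd = 2)
  graphics::abline(v = c(x$ci_low, x$ci_high), lty = 2)
  invisible(x)
}

#' Molecular-clock divergence time from synonymous divergence
#'
#' Converts the mean synonymous substitution rate per synonymous site (dS)
#' between two lineages into a divergence time under a strict clock,
#' T = dS / (2 r), where r is the per-lineage synonymous substitution rate
#' per site per million years (the factor 2 accounts for the two lineages
#' accumulating substitutions independently).
#'
#' @param mean_dS mean pairwise synonymous divergence
#' @param rates vector of per-lineage synonymous rates (substitutions per
#'   site per million years)
#' @return data frame with columns `rate` and `t_mya`, plus attributes
#'   `t_min`/`t_max` giving the interval over the supplied rates
#' @export
clock_estimate <- function(mean_dS, rates) {
  stopifnot(mean_dS >= 0, all(rates > 0))
  t <- mean_dS / (2 * rates)
  out <- data.frame(rate = rates, t_mya = t)
  attr(out, "t_min") <- min(t)
  attr(out, "t_max") <- max(t)
  out
}
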