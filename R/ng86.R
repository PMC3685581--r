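# Nei-Gojobori (1986) style counting of synonymous/non-synonymous sites and
# substitutions for pairwise codon alignments.

# cache environment for per-convention site tables and pathway results
.ng86_cache <- new.env(parent = emptyenv())

#' Synonymous and non-synonymous site composition of a codon
#'
#' Each codon position contributes a fractional synonymous "site" equal to the
#' proportion of possible single-nucleotide changes at that position that
#' leave the encoded amino acid unchanged; the non-synonymous fraction is the
#' complement. The three position fractions always sum to 3 sites per codon.
#'
#' Changes that would create a stop codon are, by default, removed from the
#' set of possible changes (the mutational-opportunity convention), so a
#' position with one stop-codon mutant divides its site weight over the two
#' remaining changes. With `stop_mutants = "nonsynonymous"` stop mutants stay
#' in the denominator and count as non-synonymous.
#'
#' @param codon a single sense codon (no gaps, no N, not a stop)
#' @param stop_mutants how single-nucleotide changes to stop codons enter the
#'   per-position fractions: `"exclude"` (default) or `"nonsynonymous"`
#' @return named numeric vector `c(n = ..., s = ...)`, summing to 3
#' @export
codon_site_composition <- function(codon,
                                   stop_mutants = c("exclude", "nonsynonymous")) {
  stop_mutants <- match.arg(stop_mutants)
  tab <- .site_table(stop_mutants)
  codon <- toupper(codon)
  if (!codon %in% rownames(tab)) {
    stop("codon '", codon, "' is a stop codon or is not a valid sense codon")
  }
  c(n = tab[codon, "n"], s = tab[codon, "s"])
}

# site composition table for all 61 sense codons, built once per convention
.site_table <- function(stop_mutants) {
  key <- paste0("sites_", stop_mutants)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  tab <- t(vapply(.sense_codons, function(codon) {
    s_total <- 0
    for (pos in 1:3) {
      from <- substr(codon, pos, pos)
      muts <- vapply(setdiff(BASES, from), function(b) {
        m <- codon
        substr(m, pos, pos) <- b
        m
      }, character(1))
      syn <- sum(!is_stop_codon(muts) &
                   translate_codons(muts) == translate_codons(codon))
      denom <- if (stop_mutants == "exclude") sum(!is_stop_codon(muts)) else 3L
      s_total <- s_total + (if (denom > 0) syn / denom else 0)
    }
    c(n = 3 - s_total, s = s_total)
  }, c(n = 0, s = 0)))
  .ng86_cache[[key]] <- tab
  tab
}

#' Classify the substitutions between two aligned codons
#'
#' Codons differing at one position are classified directly by whether the
#' amino acid changes. Codons differing at two or three positions are averaged
#' with equal weights over all orderings of single-nucleotide steps whose
#' intermediate codons are not stop codons.
#'
#' @param codon_a,codon_b sense codons (gap-free, non-stop)
#' @return named numeric vector `c(Dn = ..., Ds = ...)`; the two components
#'   sum to the number of differing positions. Returns `c(NA, NA)` when every
#'   pathway passes through a stop codon.
#' @export
count_substitutions <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  if (is_stop_codon(codon_a) || is_stop_codon(codon_b)) {
    stop("stop codons cannot be compared")
  }
  key <- paste0(codon_a, codon_b)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .count_paths(codon_a, codon_b)
  .ng86_cache[[key]] <- res
  res
}

# enumerate all orderings of single steps between two codons, skipping
# pathways whose intermediates are stops, and average syn/nonsyn step counts
.count_paths <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(Dn = 0, Ds = 0))
  orders <- .permutations(diff_pos)
  tot_n <- 0
  tot_s <- 0
  n_valid <- 0L
  for (ord in orders) {
    cur <- codon_a
    path_n <- 0L
    path_s <- 0L
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop_codon(nxt) && nxt != codon_b) {
        ok <- FALSE
        break
      }
      if (translate_codons(nxt) == translate_codons(cur)) {
        path_s <- path_s + 1L
      } else {
        path_n <- path_n + 1L
      }
      cur <- nxt
    }
    if (ok) {
      tot_n <- tot_n + path_n
      tot_s <- tot_s + path_s
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(Dn = NA_real_, Ds = NA_real_))
  c(Dn = tot_n / n_valid, Ds = tot_s / n_valid)
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' @param p proportion of sites that differ (raw d)
#' @return corrected distance; `NA` where `p >= 0.75`
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Per-gene divergence summary from a trimmed codon alignment
#'
#' Site counts (N, S) are the arithmetic mean of the two sequences' codon
#' site compositions over usable codon columns. Substitutions are summed over
#' pathway-averaged per-codon classifications. Codon columns containing gaps,
#' N or stop codons in either sequence are excluded from site and substitution
#' counting; nucleotide p-distance uses all columns where both bases are
#' unambiguous nucleotides, and amino-acid distance all usable codon columns.
#'
#' @param aln a [codon_alignment] object (or list with `seq_a`, `seq_b`)
#' @param stop_mutants passed to [codon_site_composition()]
#' @return a one-row data frame with columns `gene_id`, `codons_used`, `N`,
#'   `S`, `Dn`, `Ds`, `nt_diffs`, `aa_diffs`, `p_distance`, `aa_distance`,
#'   `dN_raw`, `dS_raw`, `dN_jc`, `dS_jc`
#' @export
gene_divergence <- function(aln, stop_mutants = c("exclude", "nonsynonymous")) {
  stop_mutants <- match.arg(stop_mutants)
  a <- toupper(aln$seq_a)
  b <- toupper(aln$seq_b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  cod_a <- split_codons(a)
  cod_b <- split_codons(b)

  # nucleotide p-distance over unambiguous non-gap columns
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  nt_ok <- av %in% BASES & bv %in% BASES
  nt_diffs <- sum(av[nt_ok] != bv[nt_ok])
  p_distance <- if (sum(nt_ok) > 0) nt_diffs / sum(nt_ok) else NA_real_

  usable <- !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b) &
    !is_stop_codon(cod_a) & !is_stop_codon(cod_b)
  cod_a <- cod_a[usable]
  cod_b <- cod_b[usable]
  codons_used <- length(cod_a)
  if (codons_used == 0L) {
    stop("no usable codon columns in alignment ",
         if (!is.null(aln$gene_id)) aln$gene_id else "")
  }

  tab <- .site_table(stop_mutants)
  sites_a <- tab[cod_a, , drop = FALSE]
  sites_b <- tab[cod_b, , drop = FALSE]
  N <- (sum(sites_a[, "n"]) + sum(sites_b[, "n"])) / 2
  S <- (sum(sites_a[, "s"]) + sum(sites_b[, "s"])) / 2

  Dn <- 0
  Ds <- 0
  diff_idx <- which(cod_a != cod_b)
  for (i in diff_idx) {
    cnt <- count_substitutions(cod_a[i], cod_b[i])
    if (anyNA(cnt)) next  # all pathways blocked by stops: codon dropped
    Dn <- Dn + cnt[["Dn"]]
    Ds <- Ds + cnt[["Ds"]]
  }

  aa_a <- translate_codons(cod_a)
  aa_b <- translate_codons(cod_b)
  aa_diffs <- sum(aa_a != aa_b)
  aa_distance <- aa_diffs / codons_used

  dN_raw <- if (N > 0) Dn / N else NA_real_
  dS_raw <- if (S > 0) Ds / S else NA_real_
  data.frame(
    gene_id = if (!is.null(aln$gene_id)) aln$gene_id else NA_character_,
    codons_used = codons_used,
    N = N, S = S, Dn = Dn, Ds = Ds,
    nt_diffs = nt_diffs, aa_diffs = aa_diffs,
    p_distance = p_distance, aa_distance = aa_distance,
    dN_raw = dN_raw, dS_raw = dS_raw,
    dN_jc = jukes_cantor(dN_raw), dS_jc = jukes_cantor(dS_raw),
    stringsAsFactors = FALSE
  )
}
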