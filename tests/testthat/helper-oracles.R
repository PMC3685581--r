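# Independent oracles used to cross-check the package implementations.
# Deliberately written with different algorithms/data structures than the
# package code (direct genetic-code lookups, exhaustive scans, recursion).

GC_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})
ORACLE_STOPS <- names(GC_TABLE)[GC_TABLE == "*"]
SENSE <- setdiff(names(GC_TABLE), ORACLE_STOPS)

oracle_aa <- function(codon) unname(GC_TABLE[codon])

# enumerate the 9 single-nucleotide mutants per codon and tally synonymous
# fractions per position
oracle_site_composition <- function(codon, stop_mutants = "exclude") {
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (mut %in% ORACLE_STOPS) {
        next   # never synonymous; kept out of the "exclude" denominator
      }
      valid <- valid + 1
      if (oracle_aa(mut) == oracle_aa(codon)) syn <- syn + 1
    }
    denom <- if (stop_mutants == "exclude") valid else 3
    if (denom > 0) s <- s + syn / denom
  }
  c(n = 3 - s, s = s)
}

# recursive enumeration of all mutational pathways between two codons,
# skipping stop intermediates; returns averaged (nonsyn, syn) step counts
oracle_pathways <- function(a, b) {
  if (a == b) return(c(0, 0))
  paths <- list()
  walk <- function(cur, n_steps, s_steps) {
    if (cur == b) {
      paths[[length(paths) + 1]] <<- c(n_steps, s_steps)
      return(invisible())
    }
    for (pos in 1:3) {
      if (substr(cur, pos, pos) == substr(b, pos, pos)) next
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (nxt %in% ORACLE_STOPS && nxt != b) next
      if (oracle_aa(nxt) == oracle_aa(cur)) {
        walk(nxt, n_steps, s_steps + 1)
      } else {
        walk(nxt, n_steps + 1, s_steps)
      }
    }
  }
  walk(a, 0, 0)
  if (length(paths) == 0) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

# brute-force longest closed ORF: scan every ATG in all six frames
oracle_longest_orf <- function(contig, min_aa = 30) {
  best <- NULL
  n <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (start in seq_len(n - 2)) {
      if (substr(s, start, start + 2) != "ATG") next
      i <- start
      while (i + 2 <= n) {
        cod <- substr(s, i, i + 2)
        if (grepl("[^ACGT]", cod)) break
        if (cod %in% ORACLE_STOPS) {
          aa_len <- (i - start) / 3
          if (i > start && aa_len >= min_aa) {
            cand <- list(strand = strand, s_from = start, s_to = i + 2,
                         aa = aa_len)
            if (is.null(best) || cand$aa > best$aa) best <- cand
          }
          break
        }
        i <- i + 3
      }
    }
  }
  best
}

# translate-both-alleles oracle for silent/non-silent classification
oracle_classify <- function(codon, codon_pos, allele1, allele2) {
  c1 <- codon
  substr(c1, codon_pos, codon_pos) <- allele1
  c2 <- codon
  substr(c2, codon_pos, codon_pos) <- allele2
  if (oracle_aa(c1) == oracle_aa(c2)) "silent" else "non-silent"
}

random_sense_codon <- function() SENSE[sample.int(length(SENSE), 1)]

# random CDS string of n codons: ATG + sense codons + stop
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(SENSE[sample.int(length(SENSE), n_codons - 2, replace = TRUE)],
               collapse = ""),
         ORACLE_STOPS[sample.int(3, 1)])
}
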