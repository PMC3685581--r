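# Pairwise ortholog alignment: best-pair selection within a cluster, global
# protein alignment, back-translation to codons, end-trimming and the
# p-distance quality filter.

#' Construct a codon alignment
#'
#' @param gene_id gene/cluster identifier
#' @param seq_a,seq_b aligned in-frame nucleotide sequences of equal length
#'   divisible by 3 (gaps as `-`)
#' @param id_a,id_b source ORF identifiers
#' @return an object of class `codon_alignment`
#' @export
codon_alignment <- function(gene_id, seq_a, seq_b, id_a = NA, id_b = NA) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  stopifnot(nchar(seq_a) == nchar(seq_b), nchar(seq_a) %% 3 == 0)
  structure(
    list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
         id_a = id_a, id_b = id_b, aligned_length = nchar(seq_a)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment %s: %d nt (%d codon columns), p-distance %.4f\n",
              x$gene_id, x$aligned_length, x$aligned_length / 3,
              p_distance(x$seq_a, x$seq_b)))
  invisible(x)
}

#' Uncorrected pairwise p-distance
#'
#' Proportion of mismatching columns among columns where both sequences have
#' an unambiguous nucleotide (gap and N columns are excluded).
#'
#' @param a,b aligned sequences of equal length
#' @return proportion in \[0, 1\], `NA` if no comparable column
#' @export
p_distance <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  ok <- av %in% BASES & bv %in% BASES
  if (!any(ok)) return(NA_real_)
  sum(av[ok] != bv[ok]) / sum(ok)
}

# global protein alignment score used for best-pair selection
.protein_align <- function(prot_a, prot_b, gap_opening = 10, gap_extension = 0.5) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
}

#' Select the most similar cross-species ORF pair from an ortholog cluster
#'
#' Scores every cross-species pair by global protein alignment (BLOSUM62,
#' affine gaps) and returns the pair with the highest score. Ties are broken
#' by the longer summed ORF length, then lexicographically by the pair of
#' ORF identifiers. Percent identity may be used as the similarity metric
#' instead of the alignment score.
#'
#' @param orfs_a,orfs_b named lists of `orf_record`s, one per species
#' @param metric `"score"` (default) or `"identity"`
#' @return list with elements `orf_a`, `orf_b` (the selected records), or
#'   `NULL` when either species is absent from the cluster
#' @export
select_best_pair <- function(orfs_a, orfs_b, metric = c("score", "identity")) {
  metric <- match.arg(metric)
  if (length(orfs_a) == 0L || length(orfs_b) == 0L) return(NULL)
  best <- NULL
  ids_a <- names(orfs_a) %||% as.character(seq_along(orfs_a))
  ids_b <- names(orfs_b) %||% as.character(seq_along(orfs_b))
  for (i in seq_along(orfs_a)) {
    prot_i <- orf_protein(orfs_a[[i]])
    for (j in seq_along(orfs_b)) {
      aln <- .protein_align(prot_i, orf_protein(orfs_b[[j]]))
      val <- if (metric == "score") Biostrings::score(aln) else Biostrings::pid(aln)
      len <- nchar(orfs_a[[i]]$sequence) + nchar(orfs_b[[j]]$sequence)
      key <- paste(ids_a[i], ids_b[j])
      if (is.null(best) || val > best$val ||
          (val == best$val && (len > best$len ||
                               (len == best$len && key < best$key)))) {
        best <- list(orf_a = orfs_a[[i]], orf_b = orfs_b[[j]],
                     val = val, len = len, key = key)
      }
    }
  }
  best[c("orf_a", "orf_b")]
}

#' Align two ORFs at the protein level and back-translate to codons
#'
#' The two ORFs are translated (trailing stops dropped), globally aligned
#' with affine gap penalties, and the protein alignment is mapped back onto
#' the original codons so that every non-gap column of the result is the
#' codon that encoded the aligned residue.
#'
#' @param orf_a,orf_b `orf_record` objects
#' @param gene_id identifier for the resulting alignment
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment (half-bit units, BLOSUM62)
#' @return an untrimmed [codon_alignment()]
#' @export
align_and_backtranslate <- function(orf_a, orf_b, gene_id = orf_a$contig_id,
                                    gap_opening = 10, gap_extension = 0.5) {
  prot_a <- orf_protein(orf_a)
  prot_b <- orf_protein(orf_b)
  if (nchar(prot_a) == 0L || nchar(prot_b) == 0L) {
    stop("gene ", gene_id, ": empty translation, gene skipped")
  }
  aln <- .protein_align(prot_a, prot_b, gap_opening, gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cod_a <- .coding_codons(orf_a)
  cod_b <- .coding_codons(orf_b)
  nt_a <- .backtranslate(pat, cod_a)
  nt_b <- .backtranslate(sub, cod_b)
  codon_alignment(gene_id, nt_a, nt_b,
                  id_a = orf_a$contig_id, id_b = orf_b$contig_id)
}

# codons of an ORF without the trailing stop
.coding_codons <- function(orf) {
  cods <- split_codons(orf$sequence)
  if (length(cods) > 0 && is_stop_codon(cods[length(cods)])) {
    cods <- cods[-length(cods)]
  }
  cods
}

.backtranslate <- function(aligned_chars, codons) {
  out <- character(length(aligned_chars))
  k <- 0L
  for (i in seq_along(aligned_chars)) {
    if (aligned_chars[i] == "-") {
      out[i] <- "---"
    } else {
      k <- k + 1L
      out[i] <- codons[k]
    }
  }
  if (k != length(codons)) {
    stop("back-translation mismatch: ", k, " aligned residues for ",
         length(codons), " codons")
  }
  paste(out, collapse = "")
}

#' Trim a codon alignment and apply the divergence filter
#'
#' Removes `trim_nt` nucleotides (default 15, i.e. five codon columns) from
#' each end of the alignment, snapping inward to the next codon boundary, and
#' discards the alignment when the post-trim p-distance exceeds
#' `max_p_distance` (strictly greater) or no complete codon column survives.
#'
#' @param aln an untrimmed [codon_alignment()]
#' @param trim_nt nucleotides to remove from each end
#' @param max_p_distance maximum retained pairwise p-distance
#' @return the trimmed `codon_alignment`, or `NULL` when filtered out
#' @export
trim_alignment <- function(aln, trim_nt = 15, max_p_distance = 0.1) {
  len <- aln$aligned_length
  from_cod <- ceiling(trim_nt / 3) + 1L   # snap inward to codon boundary
  to_cod <- (len - trim_nt) %/% 3L
  if (to_cod < from_cod) return(NULL)
  from <- (from_cod - 1L) * 3L + 1L
  to <- to_cod * 3L
  seq_a <- substring(aln$seq_a, from, to)
  seq_b <- substring(aln$seq_b, from, to)
  pd <- p_distance(seq_a, seq_b)
  if (is.na(pd) || pd > max_p_distance) return(NULL)
  out <- codon_alignment(aln$gene_id, seq_a, seq_b, aln$id_a, aln$id_b)
  out$trim_offset_nt <- from - 1L   # nt dropped from the left, for coordinate maps
  out
}
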