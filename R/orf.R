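# Open-reading-frame prediction: homology-anchored frame extension or the
# longest closed ORF over all six frames.

#' Construct an ORF record
#'
#' Coordinates are 1-based inclusive on the input contig, always with
#' `start < end` (for minus-strand ORFs the sequence is the reverse
#' complement of `contig[start..end]`).
#'
#' @param contig_id contig identifier
#' @param strand `"+"` or `"-"`
#' @param start,end 1-based inclusive nucleotide coordinates on the contig
#' @param sequence in-frame nucleotide sequence (reading direction)
#' @param anchored logical; `TRUE` when produced from a homology anchor
#' @return an object of class `orf_record`
#' @export
orf_record <- function(contig_id, strand, start, end, sequence,
                       anchored = FALSE) {
  stopifnot(strand %in% c("+", "-"), start >= 1, end >= start,
            nchar(sequence) == end - start + 1,
            nchar(sequence) %% 3 == 0)
  structure(
    list(contig_id = contig_id, strand = strand, start = start, end = end,
         sequence = toupper(sequence), anchored = anchored),
    class = "orf_record"
  )
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("ORF %s [%d-%d] (%s) %d nt, %d aa%s\n",
              x$contig_id, x$start, x$end, x$strand, nchar(x$sequence),
              sum(!is_stop_codon(split_codons(x$sequence))),
              if (x$anchored) ", anchored" else ""))
  invisible(x)
}

#' Predict the coding ORF of a contig
#'
#' Without an anchor, scans all six reading frames for closed ORFs (ATG to
#' stop, no internal stop) and returns the longest one encoding at least
#' `min_aa` amino acids; ties are broken by earlier start coordinate on the
#' contig, then by preferring the plus strand. With an anchor (an externally
#' supplied homology hit giving strand and frame), the stop-free in-frame
#' stretch through the anchor position is returned and may be open at either
#' end.
#'
#' @param contig nucleotide sequence (A/C/G/T/N)
#' @param contig_id identifier used in the returned record
#' @param anchor optional list with elements `strand` (`"+"`/`"-"`), `frame`
#'   (1-3, offset into the stranded sequence) and optionally `start`
#'   (1-based position, in reading direction on the stranded sequence, that
#'   the homology hit covers; defaults to the first in-frame position)
#' @param min_aa minimum number of encoded amino acids for a de novo ORF
#' @return an [orf_record()] or `NULL` when no ORF meets the requirements
#' @export
predict_orf <- function(contig, contig_id = "contig", anchor = NULL,
                        min_aa = 30) {
  contig <- toupper(contig)
  .check_nucleotides(contig, "contig")
  n <- nchar(contig)
  if (n < 3 * min_aa) return(NULL)
  if (!grepl("[ACGT]", contig)) return(NULL)
  if (is.null(anchor)) {
    .predict_orf_denovo(contig, contig_id, min_aa)
  } else {
    .predict_orf_anchored(contig, contig_id, anchor)
  }
}

.predict_orf_denovo <- function(contig, contig_id, min_aa) {
  n <- nchar(contig)
  best <- NULL
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") contig else revcomp(contig)
    for (frame in 1:3) {
      usable <- n - frame + 1L
      ncod <- usable %/% 3L
      if (ncod < min_aa + 1L) next
      starts <- frame + 3L * (seq_len(ncod) - 1L)
      codons <- substring(seq_s, starts, starts + 2L)
      is_stop <- is_stop_codon(codons)
      is_atg <- codons == "ATG"
      # walk stop-delimited segments; ORF = first ATG .. stop of segment
      stop_idx <- which(is_stop)
      seg_start <- 1L
      for (si in stop_idx) {
        atg_in_seg <- which(is_atg[seg_start:(si - 1L)])
        if (si > seg_start && length(atg_in_seg) > 0L) {
          a <- seg_start + atg_in_seg[1L] - 1L
          aa_len <- si - a            # codons before the stop
          if (aa_len >= min_aa) {
            cand <- .frame_to_record(contig, contig_id, strand, seq_s,
                                     starts[a], starts[si] + 2L,
                                     anchored = FALSE)
            best <- .better_orf(best, cand, aa_len)
          }
        }
        seg_start <- si + 1L
      }
    }
  }
  best$record
}

# keep the candidate with more amino acids; ties: earlier contig start, then
# plus strand
.better_orf <- function(best, cand, aa_len) {
  if (is.null(best)) return(list(record = cand, aa = aa_len))
  if (aa_len > best$aa) return(list(record = cand, aa = aa_len))
  if (aa_len == best$aa) {
    if (cand$start < best$record$start ||
        (cand$start == best$record$start &&
         cand$strand == "+" && best$record$strand == "-")) {
      return(list(record = cand, aa = aa_len))
    }
  }
  best
}

# convert coordinates on the stranded sequence back to contig coordinates
.frame_to_record <- function(contig, contig_id, strand, seq_s, s_from, s_to,
                             anchored) {
  n <- nchar(contig)
  if (strand == "+") {
    start <- s_from; end <- s_to
  } else {
    start <- n - s_to + 1L; end <- n - s_from + 1L
  }
  orf_record(contig_id, strand, start, end,
             substring(seq_s, s_from, s_to), anchored = anchored)
}

.predict_orf_anchored <- function(contig, contig_id, anchor) {
  strand <- anchor$strand %||% "+"
  frame <- anchor$frame %||% 1L
  stopifnot(strand %in% c("+", "-"), frame %in% 1:3)
  n <- nchar(contig)
  seq_s <- if (strand == "+") contig else revcomp(contig)
  usable <- n - frame + 1L
  ncod <- usable %/% 3L
  if (ncod < 1L) return(NULL)
  starts <- frame + 3L * (seq_len(ncod) - 1L)
  codons <- substring(seq_s, starts, starts + 2L)
  is_stop <- is_stop_codon(codons)
  anchor_pos <- anchor$start %||% frame
  anchor_cod <- (anchor_pos - frame) %/% 3L + 1L
  if (anchor_cod < 1L || anchor_cod > ncod) {
    stop("anchor position lies outside the anchored frame")
  }
  if (is_stop[anchor_cod]) return(NULL)
  # extend from the anchor codon to the nearest stop (or sequence end) on
  # each side; the stop codon on the right is included to close the ORF
  left <- anchor_cod
  while (left > 1L && !is_stop[left - 1L]) left <- left - 1L
  right <- anchor_cod
  while (right < ncod && !is_stop[right]) right <- right + 1L
  .frame_to_record(contig, contig_id, strand, seq_s,
                   starts[left],
                   starts[right] + 2L,
                   anchored = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict ORFs for a set of contigs
#'
#' @param contigs named character vector of contig sequences
#' @param anchors optional named list of anchors (see [predict_orf()])
#' @param min_aa minimum amino acids for de novo ORFs
#' @return named list of `orf_record` objects (contigs without a qualifying
#'   ORF are omitted)
#' @export
predict_orfs <- function(contigs, anchors = NULL, min_aa = 30) {
  out <- list()
  for (id in names(contigs)) {
    rec <- predict_orf(contigs[[id]], contig_id = id,
                       anchor = anchors[[id]], min_aa = min_aa)
    if (!is.null(rec)) out[[id]] <- rec
  }
  out
}

#' Tabulate ORF records as a BED-like data frame
#'
#' @param orfs list of `orf_record` objects
#' @return data frame with 1-based inclusive coordinates and strand
#' @export
orf_table <- function(orfs) {
  data.frame(
    contig_id = vapply(orfs, `[[`, "", "contig_id"),
    start = vapply(orfs, `[[`, 0L, "start"),
    end = vapply(orfs, `[[`, 0L, "end"),
    strand = vapply(orfs, `[[`, "", "strand"),
    anchored = vapply(orfs, `[[`, FALSE, "anchored"),
    length_nt = vapply(orfs, function(o) nchar(o$sequence), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Amino-acid translation of an ORF (stop trimmed)
#'
#' @param orf an `orf_record`
#' @return single protein string; trailing stop codon, if present, is dropped
#'   and codons containing N translate to `X`
#' @export
orf_protein <- function(orf) {
  cods <- split_codons(orf$sequence)
  if (length(cods) > 0 && is_stop_codon(cods[length(cods)])) {
    cods <- cods[-length(cods)]
  }
  aa <- translate_codons(cods)
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
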