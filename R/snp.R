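# Pooled-sample SNP calling and classification. Filters follow the pooled
# 454 protocol: depth >= 10, exactly two alleles, rarer allele seen at least
# twice, column quality >= 20, and no more than three low-quality (< 15)
# bases in the surrounding window.

.pileup_cols <- c("contig", "pos", "ref_base", "depth", "countA", "countC",
                  "countG", "countT", "base_quality_min", "neighborhood_low_q")

#' Read a pileup TSV
#'
#' The dialect has one row per position with columns contig, pos (1-based),
#' ref_base, depth, countA/countC/countG/countT, base_quality_min and
#' neighborhood_low_q (count of bases with quality < 15 in the +/-3 window).
#'
#' @param path file path
#' @return data frame of pileup columns
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.pileup_cols, names(df))
  if (length(missing)) {
    stop("pileup ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a pileup TSV
#'
#' @param pileup data frame of pileup columns
#' @param path output path
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, .pileup_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call diallelic SNPs from pooled pileup columns
#'
#' A column is emitted as a SNP exactly when all filters hold: mapping depth
#' at least `min_depth`, exactly two alleles with nonzero counts, the rarer
#' allele observed at least `min_minor` times, column quality at least
#' `min_quality`, and at most `max_low_q_neighbors` surrounding bases of
#' quality below 15. Columns with more than two alleles are rejected
#' outright, not reduced to their top two alleles. When the two allele
#' counts tie, the alphabetically first base is reported as the major
#' allele.
#'
#' @param pileup data frame of pileup columns (sorted by contig, pos)
#' @param min_depth minimum mapping depth
#' @param min_minor minimum observations of the rarer allele
#' @param min_quality minimum column quality score
#' @param max_low_q_neighbors maximum low-quality surrounding bases
#' @return data frame of SNP records: `contig`, `pos`, `major_allele`,
#'   `minor_allele`, `major_count`, `minor_count`, `depth`, `minor_freq`,
#'   `quality`, `freq_class`
#' @export
call_snps <- function(pileup, min_depth = 10, min_minor = 2,
                      min_quality = 20, max_low_q_neighbors = 3) {
  cm <- as.matrix(pileup[, c("countA", "countC", "countG", "countT")])
  colnames(cm) <- BASES
  allele_depth <- rowSums(cm)
  bad <- which(pileup$depth != allele_depth)
  if (length(bad)) {
    warning(length(bad), " pileup rows with depth != allele count sum; ",
            "allele count sum used")
  }
  n_alleles <- rowSums(cm > 0)
  ord <- t(apply(cm, 1L, sort, decreasing = TRUE))
  major_count <- ord[, 1]
  minor_count <- ifelse(n_alleles >= 2, ord[, 2], 0L)
  pass <- allele_depth >= min_depth &
    n_alleles == 2L &
    minor_count >= min_minor &
    pileup$base_quality_min >= min_quality &
    pileup$neighborhood_low_q <= max_low_q_neighbors
  idx <- which(pass)
  if (length(idx) == 0L) return(.empty_snp_calls())
  major <- character(length(idx))
  minor <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    present <- BASES[cm[i, ] > 0]
    cnts <- cm[i, present]
    o <- order(-cnts, present)   # count desc, then base order for ties
    major[k] <- present[o[1]]
    minor[k] <- present[o[2]]
  }
  out <- data.frame(
    contig = pileup$contig[idx], pos = pileup$pos[idx],
    major_allele = major, minor_allele = minor,
    major_count = major_count[idx], minor_count = minor_count[idx],
    depth = allele_depth[idx],
    minor_freq = minor_count[idx] / allele_depth[idx],
    quality = pileup$base_quality_min[idx],
    stringsAsFactors = FALSE
  )
  out$freq_class <- bin_by_frequency(out$minor_freq)
  out
}

.empty_snp_calls <- function() {
  data.frame(contig = character(0), pos = integer(0),
             major_allele = character(0), minor_allele = character(0),
             major_count = integer(0), minor_count = integer(0),
             depth = integer(0), minor_freq = numeric(0),
             quality = numeric(0), freq_class = character(0),
             stringsAsFactors = FALSE)
}

#' Classify SNPs as silent or non-silent within ORFs
#'
#' Maps each SNP position onto the codon of the covering ORF (strand-aware)
#' and compares the amino acids encoded with the major versus the minor
#' allele. Positions outside every supplied ORF are classified
#' `"outside_orf"`; SNPs falling in a codon containing N are excluded
#' (effect `NA`).
#'
#' @param snps data frame from [call_snps()]
#' @param orfs named list of `orf_record`s, names matching `snps$contig`
#' @return `snps` with an added `effect` column (`"silent"`, `"non-silent"`,
#'   `"outside_orf"` or `NA`)
#' @export
classify_snps <- function(snps, orfs) {
  effect <- rep("outside_orf", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    orf <- orfs[[snps$contig[i]]]
    if (is.null(orf)) next
    effect[i] <- classify_snp(snps$pos[i], snps$major_allele[i],
                              snps$minor_allele[i], orf)
  }
  snps$effect <- effect
  snps
}

#' Silent/non-silent call for a single SNP against one ORF
#'
#' @param pos 1-based contig position of the SNP
#' @param major,minor the two alleles (contig strand)
#' @param orf the covering `orf_record`
#' @return `"silent"`, `"non-silent"`, `"outside_orf"`, or `NA` when the
#'   codon contains ambiguous bases
#' @export
classify_snp <- function(pos, major, minor, orf) {
  if (pos < orf$start || pos > orf$end) return("outside_orf")
  if (orf$strand == "+") {
    off <- pos - orf$start + 1L
    maj <- toupper(major)
    min_ <- toupper(minor)
  } else {
    off <- orf$end - pos + 1L
    maj <- chartr("ACGTN", "TGCAN", toupper(major))
    min_ <- chartr("ACGTN", "TGCAN", toupper(minor))
  }
  ci <- (off - 1L) %/% 3L + 1L
  cp <- (off - 1L) %% 3L + 1L
  codon <- substring(orf$sequence, (ci - 1L) * 3L + 1L, ci * 3L)
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  cod_maj <- codon
  substr(cod_maj, cp, cp) <- maj
  cod_min <- codon
  substr(cod_min, cp, cp) <- min_
  aa_maj <- translate_codons(cod_maj)
  aa_min <- translate_codons(cod_min)
  if (is.na(aa_maj) || is.na(aa_min)) return(NA_character_)
  if (aa_maj == aa_min) "silent" else "non-silent"
}

#' Bin SNPs by rarer-allele frequency
#'
#' Classes follow the low/moderate/common convention: low below `low`
#' (default 5%), moderate in `[low, moderate)`, common in `[moderate, 0.5]`.
#' The half-open boundaries are this package's convention; the class limits
#' are configurable.
#'
#' @param minor_freq numeric vector of rarer-allele frequencies in (0, 0.5]
#' @param low,moderate class boundaries
#' @return character vector: `"low"`, `"moderate"` or `"common"`
#' @export
bin_by_frequency <- function(minor_freq, low = 0.05, moderate = 0.15) {
  stopifnot(all(minor_freq > 0 & minor_freq <= 0.5))
  ifelse(minor_freq < low, "low",
         ifelse(minor_freq < moderate, "moderate", "common"))
}

#' Pool classified SNP counts per gene across species
#'
#' Adds up the silent and non-silent in-ORF SNPs of both species per gene,
#' optionally excluding low (or low and moderate) frequency classes first.
#'
#' @param snps_a,snps_b classified SNP data frames (with `effect` and
#'   `freq_class`) for the two species
#' @param gene_map data frame with columns `contig` and `gene_id` assigning
#'   each contig to exactly one gene
#' @param exclusion `"none"`, `"low"` or `"low_moderate"`
#' @return data frame `gene_id`, `Pn`, `Ps` covering every gene in
#'   `gene_map` (zero counts included)
#' @export
pool_gene_counts <- function(snps_a, snps_b, gene_map,
                             exclusion = c("none", "low", "low_moderate")) {
  exclusion <- match.arg(exclusion)
  all_snps <- rbind(snps_a, snps_b)
  all_snps <- all_snps[!is.na(all_snps$effect) &
                         all_snps$effect %in% c("silent", "non-silent"), ,
                       drop = FALSE]
  drop_classes <- switch(exclusion,
                         none = character(0),
                         low = "low",
                         low_moderate = c("low", "moderate"))
  all_snps <- all_snps[!all_snps$freq_class %in% drop_classes, , drop = FALSE]
  gid <- gene_map$gene_id[match(all_snps$contig, gene_map$contig)]
  if (anyNA(gid) && nrow(all_snps) > 0) {
    warning(sum(is.na(gid)), " SNPs on contigs absent from gene_map dropped")
    all_snps <- all_snps[!is.na(gid), , drop = FALSE]
    gid <- gid[!is.na(gid)]
  }
  genes <- sort(unique(gene_map$gene_id))
  f <- factor(gid, levels = genes)
  data.frame(
    gene_id = genes,
    Pn = as.numeric(tapply(all_snps$effect == "non-silent", f, sum,
                           default = 0)),
    Ps = as.numeric(tapply(all_snps$effect == "silent", f, sum, default = 0)),
    stringsAsFactors = FALSE
  )
}

#' Probability of detecting a segregating allele in a pooled sample
#'
#' The rarer allele is detected when it is sampled at least `min_minor`
#' times among `depth` reads, i.e. the upper tail of Binomial(depth, freq).
#'
#' @param depth read depth at the site
#' @param freq true frequency of the rarer allele
#' @param min_minor minimum required observations of the rarer allele
#' @return detection probability
#' @export
detection_probability <- function(depth, freq, min_minor = 2) {
  stopifnot(all(depth >= 1), all(freq >= 0), all(freq <= 0.5))
  ifelse(freq == 0, 0, 1 - stats::pbinom(min_minor - 1, depth, freq))
}
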