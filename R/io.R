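# Plain-text readers and writers: FASTA, cluster assignments, truth tables,
# and the simulated-study directory layout.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width for wrapping
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write all outputs of a simulated study to a directory
#'
#' Writes one coding-sequence FASTA and (when simulated) one pileup TSV per
#' species, the truth tables for fixed differences and polymorphisms, and a
#' cluster table mapping the two species' contigs to genes.
#'
#' @param sim an `mk_simulation` from [simulate_study()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- sim$config$species
  write_fasta(sim$seq_a, file.path(dir, paste0("cds_", sp[1], ".fasta")))
  write_fasta(sim$seq_b, file.path(dir, paste0("cds_", sp[2], ".fasta")))
  if (!is.null(sim$pileup_a)) {
    write_pileup(sim$pileup_a, file.path(dir, paste0("pileup_", sp[1], ".tsv")))
    write_pileup(sim$pileup_b, file.path(dir, paste0("pileup_", sp[2], ".tsv")))
  }
  utils::write.table(sim$subs, file.path(dir, "truth_substitutions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- rbind(
    data.frame(cluster_id = sim$genes$gene_id, species = sp[1],
               orf_id = names(sim$seq_a), stringsAsFactors = FALSE),
    data.frame(cluster_id = sim$genes$gene_id, species = sp[2],
               orf_id = names(sim$seq_b), stringsAsFactors = FALSE)
  )
  utils::write.table(clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cluster assignment table
#'
#' @param path TSV with columns `cluster_id`, `species`, `orf_id`
#' @return data frame
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "species", "orf_id")
  if (!all(need %in% names(df))) {
    stop("cluster table must have columns ", paste(need, collapse = ", "))
  }
  df
}
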