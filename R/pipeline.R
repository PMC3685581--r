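# End-to-end orchestration: ORF prediction -> ortholog codon alignments ->
# divergence counting -> SNP calling/classification -> MKT and alpha.

#' Pipeline configuration
#'
#' Filter thresholds default to the pooled-transcriptome protocol this
#' pipeline mirrors: minimum mapping depth 10 and SNP quality 20, p-distance
#' cutoff 0.1, 15 bp end-trimming, and a 30-amino-acid ORF minimum.
#'
#' @param fasta_a,fasta_b per-species contig/CDS FASTA paths
#' @param pileup_a,pileup_b per-species pileup TSV paths (optional; without
#'   them only divergence is computed)
#' @param clusters path to a cluster TSV (`cluster_id`, `species`, `orf_id`)
#'   assigning contigs of the two species to putative ortholog groups
#' @param species length-2 character vector of species labels matching the
#'   cluster table
#' @param out_dir output directory for stage TSVs and the summary
#' @param min_orf_aa minimum amino acids for de novo ORFs
#' @param trim_nt nucleotides trimmed from each alignment end
#' @param max_p_distance alignment divergence cutoff (strictly greater
#'   excluded)
#' @param min_depth,min_minor,min_quality,max_low_q_neighbors SNP filters
#' @param fdr FDR level for the MKT
#' @param mkt_method `"chisq"` or `"fisher"`
#' @param n_bootstrap bootstrap resamples for the alpha interval
#' @param seed integer seed for the bootstrap
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(fasta_a, fasta_b, pileup_a = NULL, pileup_b = NULL,
                            clusters = NULL, species = c("A", "B"),
                            out_dir = "mkalpha_out",
                            min_orf_aa = 30, trim_nt = 15,
                            max_p_distance = 0.1,
                            min_depth = 10, min_minor = 2, min_quality = 20,
                            max_low_q_neighbors = 3,
                            fdr = 0.05, mkt_method = "chisq",
                            n_bootstrap = 1000, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full ortholog divergence/polymorphism pipeline
#'
#' Stages: (1) ORF prediction per species; (2) best-pair selection within
#' each ortholog cluster, protein alignment, back-translation, end-trimming
#' and the p-distance filter; (3) per-gene synonymous/non-synonymous site
#' and substitution counting; (4) SNP calling from the pooled pileups,
#' silent/non-silent classification and per-gene pooling across species;
#' (5) per-gene McDonald-Kreitman tests and the transcriptome-wide alpha
#' under the three SNP frequency-class exclusion modes. Each stage writes a
#' TSV into `out_dir`, and a funnel summary records every filter's in/out
#' counts.
#'
#' @param config a [pipeline_config()]
#' @return list with the per-stage tables (`orfs_a`, `orfs_b`,
#'   `alignment_summary`, `divergence`, `snps_a`, `snps_b`, `gene_counts`),
#'   `mkt` (an `mkt_results`), `alpha` (list of `alpha_fit` per exclusion
#'   mode), and `summary` (funnel counts, divergence histogram, SNP class
#'   table)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_info <- function(...) message(sprintf(...))

  contigs_a <- read_fasta(config$fasta_a)
  contigs_b <- read_fasta(config$fasta_b)
  log_info("stage orf: %d + %d contigs in", length(contigs_a),
           length(contigs_b))
  orfs_a <- predict_orfs(contigs_a, min_aa = config$min_orf_aa)
  orfs_b <- predict_orfs(contigs_b, min_aa = config$min_orf_aa)
  log_info("stage orf: %d + %d ORFs out", length(orfs_a), length(orfs_b))
  .write_tsv(orf_table(orfs_a), config$out_dir, "orfs_a.tsv")
  .write_tsv(orf_table(orfs_b), config$out_dir, "orfs_b.tsv")

  if (is.null(config$clusters)) {
    stop("a cluster table is required to pair orthologs across species")
  }
  clusters <- read_clusters(config$clusters)
  cl_ids <- unique(clusters$cluster_id)
  aln_rows <- list()
  alignments <- list()
  div_rows <- list()
  gene_map_rows <- list()
  n_single_species <- 0L
  for (cid in cl_ids) {
    sub <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    ids_a <- intersect(sub$orf_id[sub$species == config$species[1]],
                       names(orfs_a))
    ids_b <- intersect(sub$orf_id[sub$species == config$species[2]],
                       names(orfs_b))
    if (length(ids_a) == 0L || length(ids_b) == 0L) {
      n_single_species <- n_single_species + 1L
      next
    }
    pair <- select_best_pair(orfs_a[ids_a], orfs_b[ids_b])
    aln <- align_and_backtranslate(pair$orf_a, pair$orf_b, gene_id = cid)
    trimmed <- trim_alignment(aln, trim_nt = config$trim_nt,
                              max_p_distance = config$max_p_distance)
    retained <- !is.null(trimmed)
    aln_rows[[cid]] <- data.frame(
      gene_id = cid, id_a = pair$orf_a$contig_id, id_b = pair$orf_b$contig_id,
      length = if (retained) trimmed$aligned_length else aln$aligned_length,
      p_distance = if (retained) p_distance(trimmed$seq_a, trimmed$seq_b)
                   else p_distance(aln$seq_a, aln$seq_b),
      retained = retained, stringsAsFactors = FALSE)
    if (retained) {
      alignments[[cid]] <- trimmed
      div_rows[[cid]] <- gene_divergence(trimmed)
      gene_map_rows[[cid]] <- data.frame(
        contig = c(pair$orf_a$contig_id, pair$orf_b$contig_id),
        gene_id = cid, stringsAsFactors = FALSE)
    }
  }
  alignment_summary <- if (length(aln_rows)) do.call(rbind, aln_rows) else
    data.frame(gene_id = character(0), id_a = character(0),
               id_b = character(0), length = integer(0),
               p_distance = numeric(0), retained = logical(0))
  divergence <- if (length(div_rows)) do.call(rbind, div_rows) else NULL
  gene_map <- if (length(gene_map_rows)) do.call(rbind, gene_map_rows) else
    data.frame(contig = character(0), gene_id = character(0))
  log_info("stage align: %d clusters in, %d single-species skipped, %d aligned, %d retained",
           length(cl_ids), n_single_species, nrow(alignment_summary),
           sum(alignment_summary$retained))
  .write_tsv(alignment_summary, config$out_dir, "alignment_summary.tsv")
  .write_tsv(divergence, config$out_dir, "gene_divergence.tsv")

  snps_a <- snps_b <- NULL
  gene_counts <- list()
  mkt_res <- NULL
  alpha_fits <- list()
  if (!is.null(config$pileup_a) && !is.null(config$pileup_b) &&
      !is.null(divergence)) {
    snps_a <- .pipeline_snps(config$pileup_a, orfs_a, config)
    snps_b <- .pipeline_snps(config$pileup_b, orfs_b, config)
    log_info("stage snps: %d + %d SNPs pass filters", nrow(snps_a),
             nrow(snps_b))
    .write_tsv(snps_a, config$out_dir, "snps_a.tsv")
    .write_tsv(snps_b, config$out_dir, "snps_b.tsv")

    for (mode in c("none", "low", "low_moderate")) {
      poly <- pool_gene_counts(snps_a, snps_b, gene_map, exclusion = mode)
      cnt <- merge(divergence[, c("gene_id", "N", "S", "Dn", "Ds")],
                   poly, by = "gene_id")
      gene_counts[[mode]] <- cnt
      alpha_fits[[mode]] <- tryCatch(
        estimate_alpha(cnt, exclusion_mode = mode,
                       n_bootstrap = config$n_bootstrap,
                       seed = config$seed),
        error = function(e) {
          log_info("alpha (%s) undefined: %s", mode, conditionMessage(e))
          NULL
        })
    }
    .write_tsv(gene_counts[["none"]], config$out_dir, "gene_counts.tsv")
    mkt_res <- mkt(gene_counts[["none"]], method = config$mkt_method,
                   fdr = config$fdr)
    log_info("stage mkt: %d genes, %d testable, %d significant",
             nrow(mkt_res), sum(mkt_res$eligible), sum(mkt_res$significant))
    .write_tsv(as.data.frame(mkt_res), config$out_dir, "mkt_results.tsv")
    alpha_report <- do.call(rbind, lapply(names(alpha_fits), function(m) {
      f <- alpha_fits[[m]]
      if (is.null(f)) return(NULL)
      data.frame(exclusion = m, alpha = f$alpha, ci_low = f$ci_low,
                 ci_high = f$ci_high, n_genes = f$n_genes,
                 n_bootstrap = f$n_bootstrap, stringsAsFactors = FALSE)
    }))
    .write_tsv(alpha_report, config$out_dir, "alpha_report.tsv")
  }

  summary <- .pipeline_summary(contigs_a, contigs_b, orfs_a, orfs_b,
                               cl_ids, n_single_species, alignment_summary,
                               divergence, snps_a, snps_b, mkt_res,
                               alpha_fits, config)
  res <- list(orfs_a = orf_table(orfs_a), orfs_b = orf_table(orfs_b),
              alignment_summary = alignment_summary, divergence = divergence,
              alignments = alignments, gene_map = gene_map,
              snps_a = snps_a, snps_b = snps_b,
              gene_counts = gene_counts, mkt = mkt_res, alpha = alpha_fits,
              summary = summary, config = config)
  class(res) <- "mk_pipeline"
  res
}

.pipeline_snps <- function(pileup_path, orfs, config) {
  pl <- read_pileup(pileup_path)
  calls <- call_snps(pl, min_depth = config$min_depth,
                     min_minor = config$min_minor,
                     min_quality = config$min_quality,
                     max_low_q_neighbors = config$max_low_q_neighbors)
  classify_snps(calls, orfs)
}

.pipeline_summary <- function(contigs_a, contigs_b, orfs_a, orfs_b,
                              cl_ids, n_single_species, alignment_summary,
                              divergence, snps_a, snps_b, mkt_res,
                              alpha_fits, config) {
  funnel <- data.frame(
    stage = c("contigs_a", "contigs_b", "orfs_a", "orfs_b", "clusters",
              "clusters_two_species", "alignments", "alignments_retained",
              "mkt_testable", "mkt_significant"),
    count = c(length(contigs_a), length(contigs_b), length(orfs_a),
              length(orfs_b), length(cl_ids),
              length(cl_ids) - n_single_species,
              nrow(alignment_summary), sum(alignment_summary$retained),
              if (is.null(mkt_res)) NA else sum(mkt_res$eligible),
              if (is.null(mkt_res)) NA else sum(mkt_res$significant)),
    stringsAsFactors = FALSE)
  breaks <- seq(0, config$max_p_distance, by = 0.005)
  counts <- if (is.null(divergence)) rep(0L, length(breaks) - 1L) else
    graphics::hist(pmin(divergence$p_distance, config$max_p_distance),
                   breaks = breaks, plot = FALSE)$counts
  div_hist <- data.frame(bin_low = utils::head(breaks, -1),
                         bin_high = breaks[-1], count = counts)
  snp_class <- NULL
  if (!is.null(snps_a)) {
    all_snps <- rbind(snps_a, snps_b)
    all_snps <- all_snps[!is.na(all_snps$effect) &
                           all_snps$effect != "outside_orf", , drop = FALSE]
    cls <- factor(all_snps$freq_class, levels = c("low", "moderate", "common"))
    Pn <- tapply(all_snps$effect == "non-silent", cls, sum, default = 0)
    Ps <- tapply(all_snps$effect == "silent", cls, sum, default = 0)
    snp_class <- data.frame(class = levels(cls), Pn = as.numeric(Pn),
                            Ps = as.numeric(Ps),
                            Pn_Ps = as.numeric(Pn) / pmax(1e-12, as.numeric(Ps)),
                            stringsAsFactors = FALSE)
  }
  out <- list(funnel = funnel, divergence_histogram = div_hist,
              snp_class_table = snp_class,
              mean_p_distance = if (is.null(divergence)) NA_real_ else
                mean(divergence$p_distance),
              mean_aa_distance = if (is.null(divergence)) NA_real_ else
                mean(divergence$aa_distance),
              mean_dS_jc = if (is.null(divergence)) NA_real_ else
                mean(divergence$dS_jc, na.rm = TRUE),
              zero_divergence = if (is.null(divergence)) 0L else
                sum(divergence$nt_diffs == 0))
  .write_tsv(funnel, config$out_dir, "summary_funnel.tsv")
  .write_tsv(div_hist, config$out_dir, "divergence_histogram.tsv")
  if (!is.null(snp_class)) {
    .write_tsv(snp_class, config$out_dir, "snp_class_table.tsv")
  }
  out
}

.write_tsv <- function(df, dir, name) {
  if (is.null(df)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file.path(dir, name))
}

#' @export
print.mk_pipeline <- function(x, ...) {
  cat("Ortholog divergence/polymorphism pipeline run\n")
  print(x$summary$funnel, row.names = FALSE)
  cat(sprintf("mean p-distance %.4f, %d zero-divergence alignments\n",
              x$summary$mean_p_distance, x$summary$zero_divergence))
  for (f in x$alpha) if (!is.null(f)) print(f)
  invisible(x)
}
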