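# Synthetic-data generator: ortholog pairs diverged at a target nucleotide
# p-distance with a known fraction of adaptive amino-acid substitutions,
# within-species polymorphism at known frequencies, and pooled-read pileups
# with sequencing error. Every emitted quantity is recorded in truth tables
# so downstream stages can be validated against ground truth.

#' Simulation configuration
#'
#' Defaults emulate the pooled 454 transcriptome comparison of two chironomid
#' sister species: ~1.53% nucleotide divergence, a quarter of amino-acid
#' substitutions adaptive, pools of 60 diploid individuals (120 chromosomes),
#' ~1% per-base sequencing error, and a mean mapping depth of 10.
#'
#' @param n_genes number of ortholog pairs to simulate
#' @param mean_len_codons mean gene length in codons (including the start and
#'   stop codon); individual lengths are Poisson-distributed with minimum 32
#' @param divergence_target expected nucleotide p-distance between the pair
#' @param adaptive_fraction true alpha: expected fraction of non-synonymous
#'   fixed differences that are adaptive (extra non-synonymous substitutions
#'   on top of the neutral process)
#' @param theta per-site probability that a site is polymorphic within a
#'   species (neutral polymorphisms)
#' @param deleterious_theta per-site probability of an additional
#'   slightly-deleterious non-synonymous polymorphism segregating at low
#'   frequency (0 disables the class)
#' @param pool_chromosomes number of chromosomes in the sequenced pool;
#'   allele frequencies take values k/pool_chromosomes
#' @param allele_freq_spectrum data frame with columns `freq` and `prob`
#'   giving the folded spectrum of the rarer allele; default is the
#'   discretized neutral 1/x spectrum folded to (0, 0.5]
#' @param coverage_mean mean reads per site for pileup simulation
#' @param error_rate per-base substitution error probability
#' @param species length-2 character vector of species labels
#' @param seed integer seed; a fixed seed makes all outputs byte-identical
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_genes = 500,
                       mean_len_codons = 134,
                       divergence_target = 0.0153,
                       adaptive_fraction = 0.25,
                       theta = 0.006,
                       deleterious_theta = 0,
                       pool_chromosomes = 120,
                       allele_freq_spectrum = NULL,
                       coverage_mean = 10,
                       error_rate = 0.0107,
                       species = c("A", "B"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              mean_len_codons = mean_len_codons,
              divergence_target = divergence_target,
              adaptive_fraction = adaptive_fraction,
              theta = theta,
              deleterious_theta = deleterious_theta,
              pool_chromosomes = as.integer(pool_chromosomes),
              allele_freq_spectrum = allele_freq_spectrum,
              coverage_mean = coverage_mean,
              error_rate = error_rate,
              species = species,
              seed = as.integer(seed))
  if (is.null(cfg$allele_freq_spectrum)) {
    cfg$allele_freq_spectrum <- neutral_folded_spectrum(cfg$pool_chromosomes)
  }
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  props <- c("divergence_target", "adaptive_fraction", "theta",
             "deleterious_theta", "error_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$coverage_mean < 0) stop("coverage_mean must be >= 0")
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (cfg$mean_len_codons < 32) stop("mean_len_codons must be >= 32")
  if (cfg$divergence_target == 0 && cfg$adaptive_fraction > 0) {
    stop("impossible configuration: adaptive_fraction > 0 requires ",
         "divergence_target > 0")
  }
  spec <- cfg$allele_freq_spectrum
  if (!is.data.frame(spec) || !all(c("freq", "prob") %in% names(spec)) ||
      any(spec$freq <= 0) || any(spec$freq > 0.5)) {
    stop("allele_freq_spectrum must be a data frame with freq in (0, 0.5]")
  }
  invisible(cfg)
}

#' Discretized folded neutral allele-frequency spectrum
#'
#' Under the standard neutral model the unfolded spectrum is proportional to
#' 1/x; folding to the rarer allele over a pool of `n_chrom` chromosomes gives
#' minor-allele count j with weight 1/j + 1/(n_chrom - j) for j < n_chrom/2
#' and 1/j for j = n_chrom/2.
#'
#' @param n_chrom number of chromosomes in the pool (even)
#' @return data frame with columns `freq` and `prob`
#' @export
neutral_folded_spectrum <- function(n_chrom = 120) {
  j <- seq_len(n_chrom %/% 2L)
  w <- 1 / j + ifelse(j < n_chrom - j, 1 / (n_chrom - j), 0)
  data.frame(freq = j / n_chrom, prob = w / sum(w))
}

# low-frequency-skewed spectrum for the slightly-deleterious class: weight
# 1/j^2 over minor counts with frequency <= 0.15 (mass concentrated < 5%)
.deleterious_spectrum <- function(n_chrom = 120) {
  jmax <- max(1L, floor(0.15 * n_chrom))
  j <- seq_len(jmax)
  w <- 1 / j^2
  data.frame(freq = j / n_chrom, prob = w / sum(w))
}

.sample_freq <- function(spectrum, n) {
  if (n == 0L) return(numeric(0))
  spectrum$freq[sample.int(nrow(spectrum), n, replace = TRUE,
                           prob = spectrum$prob)]
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

# precomputed single-nucleotide mutation table: for every sense codon and
# position, the non-stop alternative bases, resulting codons and whether the
# change is synonymous
.mut_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- new.env(parent = emptyenv())
    for (cod in .sense_codons) {
      per_pos <- vector("list", 3L)
      for (off in 1:3) {
        from <- substr(cod, off, off)
        cands <- setdiff(BASES, from)
        muts <- vapply(cands, function(b) {
          m <- cod; substr(m, off, off) <- b; m
        }, character(1), USE.NAMES = FALSE)
        keep <- !is_stop_codon(muts)
        per_pos[[off]] <- list(
          alts = cands[keep], muts = muts[keep],
          syn = translate_codons(muts[keep]) == translate_codons(cod))
      }
      assign(cod, per_pos, envir = t)
    }
    tab <<- t
    tab
  }
})

# mutate one nucleotide of a codon vector; returns the updated codons plus
# whether the change was synonymous; alt bases creating a stop codon are
# rejected; `require_nonsyn` restricts to amino-acid-changing alternatives
.mutate_site <- function(codons, nt_pos, require_nonsyn = FALSE) {
  ci <- (nt_pos - 1L) %/% 3L + 1L
  off <- (nt_pos - 1L) %% 3L + 1L
  cod <- codons[ci]
  opt <- .mut_table()[[cod]][[off]]
  idx <- if (require_nonsyn) which(!opt$syn) else seq_along(opt$alts)
  if (length(idx) == 0L) return(NULL)
  pick <- idx[sample.int(length(idx), 1L)]
  codons[ci] <- opt$muts[pick]
  list(codons = codons, from = substr(cod, off, off), to = opt$alts[pick],
       syn = opt$syn[pick])
}

#' Simulate one ortholog pair with known substitution truth
#'
#' An ancestral in-frame gene (ATG ... stop) is generated and substitutions
#' are placed on the two descendant lineages codon-aware: neutral
#' substitutions hit random mutable sites with a per-site probability
#' calibrated so the realized pair divergence matches `divergence_target`
#' after the additional adaptive non-synonymous substitutions are added.
#' Changes creating stop codons are rejected, so both sequences remain valid
#' open reading frames. Within-species polymorphisms are placed as
#' independent sites with frequencies drawn from the configured spectrum.
#'
#' Uses the current RNG state; seed via [simulate_study()] or `set.seed()`.
#'
#' @param config a [sim_config()]
#' @param gene_index index of the gene (used for the identifier)
#' @return list with `gene_id`, `seq_a`, `seq_b` (full CDS strings),
#'   `len_codons`, `subs` (one row per fixed difference: position, lineage,
#'   from, to, `syn`, `adaptive`), and `snps` (one row per true polymorphism:
#'   species, position, major/minor allele, minor frequency, `silent`,
#'   `deleterious`)
#' @export
simulate_ortholog_pair <- function(config, gene_index = 1L) {
  raw <- .simulate_pair_raw(config, gene_index)
  raw$subs <- data.frame(raw$subs, stringsAsFactors = FALSE)
  if (nrow(raw$subs) == 0L) raw$subs <- .empty_subs()
  raw$snps <- data.frame(raw$snps, stringsAsFactors = FALSE)
  if (nrow(raw$snps) == 0L) raw$snps <- .empty_snps()
  raw
}

# vector-accumulating inner generator (data frames are assembled by the
# callers once, not per event)
.simulate_pair_raw <- function(config, gene_index) {
  len <- max(32L, stats::rpois(1L, config$mean_len_codons))
  gene_id <- sprintf("g%05d", gene_index)
  body <- .sense_codons[sample.int(length(.sense_codons), len - 2L,
                                   replace = TRUE)]
  anc <- c("ATG", body, .sample1(STOP_CODONS))
  mut_nt <- 4:(3L * (len - 1L))          # all sites except start & stop codon
  n_mut <- length(mut_nt)

  a <- config$adaptive_fraction
  d <- config$divergence_target
  # expected non-synonymous fraction of accepted neutral changes, from the
  # mutational-opportunity site composition of the ancestral gene
  tab <- .site_table("exclude")
  anc_internal <- anc[2:(len - 1L)]
  f_nonsyn <- sum(tab[anc_internal, "n"]) / (3 * (len - 2L))
  d_neutral <- if (a > 0) d / (1 + f_nonsyn * a / (1 - a)) else d

  cods <- list(anc, anc)   # lineage a = 1, lineage b = 2
  ev_lin <- character(0); ev_pos <- integer(0)
  ev_from <- character(0); ev_to <- character(0)
  ev_syn <- logical(0); ev_adapt <- logical(0)
  hit <- mut_nt[stats::runif(n_mut) < d_neutral]
  for (pos in hit) {
    lin <- .sample1(1:2)
    m <- .mutate_site(cods[[lin]], pos)
    if (is.null(m)) next
    cods[[lin]] <- m$codons
    ev_lin <- c(ev_lin, c("a", "b")[lin]); ev_pos <- c(ev_pos, pos)
    ev_from <- c(ev_from, m$from); ev_to <- c(ev_to, m$to)
    ev_syn <- c(ev_syn, m$syn); ev_adapt <- c(ev_adapt, FALSE)
  }
  dn0 <- sum(!ev_syn)
  if (a > 0 && dn0 > 0) {
    n_adapt <- stats::rpois(1L, dn0 * a / (1 - a))
    placed <- 0L
    tries <- 0L
    while (placed < n_adapt && tries < 50L * (n_adapt + 1L)) {
      tries <- tries + 1L
      pos <- .sample1(mut_nt)
      lin <- .sample1(1:2)
      m <- .mutate_site(cods[[lin]], pos, require_nonsyn = TRUE)
      if (is.null(m)) next
      cods[[lin]] <- m$codons
      ev_lin <- c(ev_lin, c("a", "b")[lin]); ev_pos <- c(ev_pos, pos)
      ev_from <- c(ev_from, m$from); ev_to <- c(ev_to, m$to)
      ev_syn <- c(ev_syn, FALSE); ev_adapt <- c(ev_adapt, TRUE)
      placed <- placed + 1L
    }
  }
  subs <- list(gene_id = rep(gene_id, length(ev_pos)), lineage = ev_lin,
               pos = ev_pos, from = ev_from, to = ev_to, syn = ev_syn,
               adaptive = ev_adapt)

  snps <- .merge_rows(lapply(1:2, function(sp) {
    .simulate_snps(cods[[sp]], mut_nt, config,
                   species = config$species[sp], gene_id = gene_id)
  }))

  list(gene_id = gene_id,
       seq_a = paste(cods[[1]], collapse = ""),
       seq_b = paste(cods[[2]], collapse = ""),
       len_codons = len, subs = subs, snps = snps)
}

# concatenate same-shaped lists of column vectors
.merge_rows <- function(parts) {
  parts <- parts[vapply(parts, function(p) length(p[[1]]) > 0, TRUE)]
  if (length(parts) == 0L) return(NULL)
  cols <- names(parts[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(parts, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  out
}

.empty_subs <- function() {
  data.frame(gene_id = character(0), lineage = character(0),
             pos = integer(0), from = character(0), to = character(0),
             syn = logical(0), adaptive = logical(0), stringsAsFactors = FALSE)
}

.empty_snps <- function() {
  data.frame(gene_id = character(0), species = character(0),
             pos = integer(0), major = character(0), minor = character(0),
             minor_freq = numeric(0), silent = logical(0),
             deleterious = logical(0), stringsAsFactors = FALSE)
}

# independent-site polymorphisms for one species; the slightly-deleterious
# class adds forced non-synonymous variants at low-frequency-skewed sites.
# Returns a list of column vectors (see .merge_rows).
.simulate_snps <- function(codons, mut_nt, config, species, gene_id) {
  pos_v <- integer(0); major_v <- character(0); minor_v <- character(0)
  freq_v <- numeric(0); silent_v <- logical(0); del_v <- logical(0)
  neutral_pos <- mut_nt[stats::runif(length(mut_nt)) < config$theta]
  for (pos in neutral_pos) {
    m <- .mutate_site(codons, pos)
    if (is.null(m)) next
    pos_v <- c(pos_v, pos); major_v <- c(major_v, m$from)
    minor_v <- c(minor_v, m$to)
    freq_v <- c(freq_v, .sample_freq(config$allele_freq_spectrum, 1L))
    silent_v <- c(silent_v, m$syn); del_v <- c(del_v, FALSE)
  }
  if (config$deleterious_theta > 0) {
    del_spec <- .deleterious_spectrum(config$pool_chromosomes)
    del_pos <- mut_nt[stats::runif(length(mut_nt)) < config$deleterious_theta]
    del_pos <- setdiff(del_pos, neutral_pos)
    for (pos in del_pos) {
      m <- .mutate_site(codons, pos, require_nonsyn = TRUE)
      if (is.null(m)) next
      pos_v <- c(pos_v, pos); major_v <- c(major_v, m$from)
      minor_v <- c(minor_v, m$to)
      freq_v <- c(freq_v, .sample_freq(del_spec, 1L))
      silent_v <- c(silent_v, FALSE); del_v <- c(del_v, TRUE)
    }
  }
  list(gene_id = rep(gene_id, length(pos_v)),
       species = rep(species, length(pos_v)),
       pos = pos_v, major = major_v, minor = minor_v,
       minor_freq = freq_v, silent = silent_v, deleterious = del_v)
}

#' Simulate a full two-species ortholog study
#'
#' @param config a [sim_config()]; `config$seed` seeds all randomness
#' @param pileups logical; also simulate pooled-read pileups for both species
#' @return a list of class `mk_simulation` with elements `config`, `seq_a`,
#'   `seq_b` (named character vectors of CDS, names are contig ids
#'   `<species>_<gene>`), `genes` (gene table), `subs`, `snps` (truth
#'   tables) and, when requested, `pileup_a`, `pileup_b`
#' @export
simulate_study <- function(config, pileups = TRUE) {
  set.seed(config$seed)
  seqs_a <- character(config$n_genes)
  seqs_b <- character(config$n_genes)
  lens <- integer(config$n_genes)
  ids <- character(config$n_genes)
  subs <- vector("list", config$n_genes)
  snps <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    g <- .simulate_pair_raw(config, i)
    ids[i] <- g$gene_id
    seqs_a[i] <- g$seq_a
    seqs_b[i] <- g$seq_b
    lens[i] <- g$len_codons
    subs[[i]] <- g$subs
    snps[[i]] <- g$snps
  }
  names(seqs_a) <- paste0(config$species[1], "_", ids)
  names(seqs_b) <- paste0(config$species[2], "_", ids)
  subs <- .merge_rows(subs)
  snps <- .merge_rows(snps[!vapply(snps, is.null, TRUE)])
  sim <- list(config = config,
              seq_a = seqs_a, seq_b = seqs_b,
              genes = data.frame(gene_id = ids, len_codons = lens,
                                 stringsAsFactors = FALSE),
              subs = if (is.null(subs)) .empty_subs()
                     else data.frame(subs, stringsAsFactors = FALSE),
              snps = if (is.null(snps)) .empty_snps()
                     else data.frame(snps, stringsAsFactors = FALSE))
  if (pileups) {
    sim$pileup_a <- .species_pileup(sim, 1L)
    sim$pileup_b <- .species_pileup(sim, 2L)
  }
  class(sim) <- "mk_simulation"
  sim
}

#' @export
print.mk_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic ortholog study: %d genes, %d fixed differences (%d non-syn, %d adaptive), %d true SNPs\n",
    nrow(x$genes), nrow(x$subs), sum(!x$subs$syn), sum(x$subs$adaptive),
    nrow(x$snps)))
  invisible(x)
}

.species_pileup <- function(sim, sp) {
  seqs <- if (sp == 1L) sim$seq_a else sim$seq_b
  species <- sim$config$species[sp]
  snps <- sim$snps[sim$snps$species == species, , drop = FALSE]
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    gid <- sim$genes$gene_id[i]
    gs <- snps[snps$gene_id == gid, , drop = FALSE]
    parts[[i]] <- simulate_pileup(seqs[[i]], gs,
                                  coverage_mean = sim$config$coverage_mean,
                                  error_rate = sim$config$error_rate,
                                  contig_id = names(seqs)[i])
  }
  do.call(rbind, parts)
}

#' Simulate a pooled-sequencing pileup for one contig
#'
#' Per-position read depth is Poisson with the given mean; each read carries
#' the reference (or, at SNP positions, the minor allele with its true
#' frequency) and is then misread to a uniformly chosen other base with
#' probability `error_rate`. A per-column quality score and a count of
#' low-quality neighbouring bases are emitted so quality filters can be
#' exercised.
#'
#' Uses the current RNG state unless `seed` is given.
#'
#' @param sequence contig sequence
#' @param snps data frame of true SNPs on this contig (columns `pos`,
#'   `minor`, `minor_freq`); may be empty
#' @param coverage_mean mean reads per position (0 gives an empty pileup
#'   with a warning)
#' @param error_rate per-base substitution error probability
#' @param contig_id contig identifier for the output
#' @param seed optional integer seed
#' @return data frame with columns `contig`, `pos`, `ref_base`, `depth`,
#'   `countA`, `countC`, `countG`, `countT`, `base_quality_min`,
#'   `neighborhood_low_q`
#' @export
simulate_pileup <- function(sequence, snps = NULL, coverage_mean = 10,
                            error_rate = 0.01, contig_id = "contig",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(sequence)
  if (coverage_mean == 0) {
    warning("coverage_mean is 0: empty pileup for ", contig_id)
    return(.empty_pileup())
  }
  ref <- strsplit(toupper(sequence), "")[[1]]
  if (!is.null(snps) && nrow(snps) > 0 && any(snps$pos > n)) {
    stop("SNP position beyond contig length for ", contig_id)
  }
  e <- error_rate
  # per-position observation probabilities for each base
  p <- matrix(e / 3, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  idx <- cbind(seq_len(n), match(ref, BASES))
  p[idx] <- 1 - e
  if (!is.null(snps) && nrow(snps) > 0) {
    for (k in seq_len(nrow(snps))) {
      pos <- snps$pos[k]
      f <- snps$minor_freq[k]
      # mixture of the two alleles' error kernels
      pv <- (1 - f) * .error_kernel(ref[pos], e) + f * .error_kernel(snps$minor[k], e)
      p[pos, ] <- pv
    }
  }
  depth <- stats::rpois(n, coverage_mean)
  counts <- .multinomial_rows(depth, p)
  qual <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(n, 35, 6)))))
  nlow <- stats::rbinom(n, 6, 0.02)
  data.frame(contig = contig_id, pos = seq_len(n), ref_base = ref,
             depth = depth,
             countA = counts[, "A"], countC = counts[, "C"],
             countG = counts[, "G"], countT = counts[, "T"],
             base_quality_min = qual, neighborhood_low_q = nlow,
             stringsAsFactors = FALSE)
}

.error_kernel <- function(base, e) {
  pv <- rep(e / 3, 4)
  names(pv) <- BASES
  pv[base] <- 1 - e
  pv
}

.empty_pileup <- function() {
  data.frame(contig = character(0), pos = integer(0), ref_base = character(0),
             depth = integer(0), countA = integer(0), countC = integer(0),
             countG = integer(0), countT = integer(0),
             base_quality_min = integer(0), neighborhood_low_q = integer(0),
             stringsAsFactors = FALSE)
}

# vectorized row-wise multinomial draw by sequential binomial decomposition
.multinomial_rows <- function(size, p) {
  n <- length(size)
  out <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  remaining <- size
  prem <- rep(1, n)
  for (j in 1:3) {
    pj <- p[, j] / prem
    pj[!is.finite(pj)] <- 0
    pj <- pmin(pmax(pj, 0), 1)
    out[, j] <- stats::rbinom(n, remaining, pj)
    remaining <- remaining - out[, j]
    prem <- prem - p[, j]
  }
  out[, 4] <- remaining
  out
}

#' Aggregate truth tables to per-gene MKT counts
#'
#' Sums the generator's true fixed differences to Dn/Ds and true SNPs of both
#' species to Pn/Ps per gene, applying the requested frequency-class
#' exclusion, and computes N/S site counts from the sequences.
#'
#' @param sim an `mk_simulation`
#' @param exclusion frequency classes dropped from the polymorphism counts:
#'   `"none"`, `"low"` (minor frequency < 0.05) or `"low_moderate"`
#'   (< 0.15)
#' @return data frame with `gene_id`, `Dn`, `Ds`, `Pn`, `Ps`, `N`, `S`
#' @export
truth_gene_counts <- function(sim, exclusion = c("none", "low", "low_moderate")) {
  exclusion <- match.arg(exclusion)
  ids <- sim$genes$gene_id
  subs <- sim$subs
  Dn <- tapply(!subs$syn, factor(subs$gene_id, levels = ids), sum, default = 0)
  Ds <- tapply(subs$syn, factor(subs$gene_id, levels = ids), sum, default = 0)
  snps <- sim$snps
  keep <- switch(exclusion,
                 none = rep(TRUE, nrow(snps)),
                 low = snps$minor_freq >= 0.05,
                 low_moderate = snps$minor_freq >= 0.15)
  snps <- snps[keep, , drop = FALSE]
  f <- factor(snps$gene_id, levels = ids)
  Pn <- tapply(!snps$silent, f, sum, default = 0)
  Ps <- tapply(snps$silent, f, sum, default = 0)
  tab <- .site_table("exclude")
  NS <- t(vapply(seq_along(ids), function(i) {
    ca <- split_codons(sim$seq_a[[i]])
    cb <- split_codons(sim$seq_b[[i]])
    ca <- ca[2:(length(ca) - 1L)]
    cb <- cb[2:(length(cb) - 1L)]
    c(N = (sum(tab[ca, "n"]) + sum(tab[cb, "n"])) / 2,
      S = (sum(tab[ca, "s"]) + sum(tab[cb, "s"])) / 2)
  }, c(N = 0, S = 0)))
  data.frame(gene_id = ids,
             Dn = as.numeric(Dn), Ds = as.numeric(Ds),
             Pn = as.numeric(Pn), Ps = as.numeric(Ps),
             N = NS[, "N"], S = NS[, "S"],
             stringsAsFactors = FALSE)
}

#' True adaptive substitution fraction realized in a simulation
#'
#' @param sim an `mk_simulation`
#' @return adaptive non-synonymous fixations over all non-synonymous
#'   fixations
#' @export
true_alpha <- function(sim) {
  nonsyn <- !sim$subs$syn
  if (!any(nonsyn)) return(NA_real_)
  sum(sim$subs$adaptive[nonsyn]) / sum(nonsyn)
}
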