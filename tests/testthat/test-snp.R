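pileup_row <- function(pos = 1, counts = c(9, 0, 3, 0), qual = 30, nlow = 0,
                       contig = "c1", ref = "A") {
  data.frame(contig = contig, pos = pos, ref_base = ref,
             depth = sum(counts), countA = counts[1], countC = counts[2],
             countG = counts[3], countT = counts[4],
             base_quality_min = qual, neighborhood_low_q = nlow,
             stringsAsFactors = FALSE)
}

test_that("SNP calling applies all five filters conjunctively", {
  # passing column: depth 12, A=9/G=3, quality 30, clean neighborhood
  out <- call_snps(pileup_row())
  expect_equal(nrow(out), 1)
  expect_equal(out$major_allele, "A")
  expect_equal(out$minor_allele, "G")
  expect_equal(out$minor_freq, 0.25)
  # each filter individually rejects
  expect_equal(nrow(call_snps(pileup_row(counts = c(6, 0, 3, 0)))), 0)  # depth 9
  expect_equal(nrow(call_snps(pileup_row(counts = c(49, 0, 1, 0)))), 0) # minor 1
  expect_equal(nrow(call_snps(pileup_row(counts = c(6, 3, 3, 0)))), 0)  # triallelic
  expect_equal(nrow(call_snps(pileup_row(qual = 19))), 0)               # quality
  expect_equal(nrow(call_snps(pileup_row(nlow = 4))), 0)                # neighbors
  expect_equal(nrow(call_snps(pileup_row(counts = c(12, 0, 0, 0)))), 0) # monoallelic
  # tied counts: alphabetically first base is the major allele
  tie <- call_snps(pileup_row(counts = c(0, 6, 0, 6)))
  expect_equal(tie$major_allele, "C")
  expect_equal(tie$minor_allele, "T")
  expect_equal(tie$minor_freq, 0.5)
})

test_that("calling equals the literal conjunction of filters on random pileups", {
  set.seed(71)
  sim <- simulate_study(sim_config(n_genes = 30, coverage_mean = 25,
                                   seed = 73))
  pl <- sim$pileup_a
  got <- call_snps(pl)
  cm <- as.matrix(pl[, c("countA", "countC", "countG", "countT")])
  manual <- logical(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    cnt <- sort(cm[i, cm[i, ] > 0], decreasing = TRUE)
    manual[i] <- sum(cm[i, ]) >= 10 &&
      length(cnt) == 2 &&
      cnt[2] >= 2 &&
      pl$base_quality_min[i] >= 20 &&
      pl$neighborhood_low_q[i] <= 3
  }
  expect_equal(paste(got$contig, got$pos),
               paste(pl$contig[manual], pl$pos[manual]))
})

test_that("SNP classification agrees with translating both alleles", {
  orf <- orf_record("c1", "+", 1, 9, "ATGCCTTAA")
  # third position of CCT: CCT vs CCA, both Pro -> silent
  expect_equal(classify_snp(6, "T", "A", orf), "silent")
  # first position of CCT: CCT (Pro) vs GCT (Ala) -> non-silent
  expect_equal(classify_snp(4, "C", "G", orf), "non-silent")
  expect_equal(classify_snp(12, "A", "G", orf), "outside_orf")
  # minus-strand ORF: contig position maps through the reverse complement
  contig_rc <- revcomp("ATGCCTTAA")
  orf_m <- orf_record("c2", "-", 1, 9, "ATGCCTTAA")
  # contig position 4 on minus strand = reading position 6 (CCT third base)
  expect_equal(classify_snp(4, "A", "T", orf_m), "silent")
  # ambiguous codon: excluded
  orf_n <- orf_record("c3", "+", 1, 9, "ATGCNTTAA")
  expect_true(is.na(classify_snp(6, "T", "A", orf_n)))
})

test_that("random SNPs classify identically to the brute-force oracle", {
  set.seed(79)
  for (i in 1:200) {
    cds <- random_cds(40)
    orf <- orf_record("c", "+", 1, nchar(cds), cds)
    pos <- sample(4:(nchar(cds) - 3), 1)
    ci <- (pos - 1) %/% 3 + 1
    cp <- (pos - 1) %% 3 + 1
    codon <- substring(cds, (ci - 1) * 3 + 1, ci * 3)
    ref <- substr(codon, cp, cp)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_snp(pos, ref, alt, orf)
    want <- oracle_classify(codon, cp, ref, alt)
    # alleles encoding a stop are still compared residue-to-residue by the
    # oracle; skip the rare stop-allele cases where "silence" is undefined
    alt_codon <- codon
    substr(alt_codon, cp, cp) <- alt
    if (oracle_aa(alt_codon) == "*") next
    expect_equal(got, want, info = paste(cds, pos, ref, alt))
  }
})

test_that("frequency classes follow the low/moderate/common boundaries", {
  expect_equal(bin_by_frequency(2 / 100), "low")
  expect_equal(bin_by_frequency(2 / 40), "moderate")   # exactly 0.05
  expect_equal(bin_by_frequency(20 / 60), "common")
  expect_equal(bin_by_frequency(c(0.049, 0.05, 0.149, 0.15, 0.5)),
               c("low", "moderate", "moderate", "common", "common"))
  expect_error(bin_by_frequency(0.6))
  expect_error(bin_by_frequency(0))
})

test_that("per-gene pooling adds species counts and honours exclusions", {
  snps_a <- data.frame(
    contig = "A_g1", pos = 1:5,
    effect = c("non-silent", "non-silent", "non-silent", "silent", "silent"),
    freq_class = c("common", "common", "low", "common", "moderate"),
    stringsAsFactors = FALSE)
  snps_b <- data.frame(
    contig = "B_g1", pos = 1:5,
    effect = c("non-silent", "silent", "silent", "silent", "silent"),
    freq_class = c("common", "low", "common", "common", "common"),
    stringsAsFactors = FALSE)
  gene_map <- data.frame(contig = c("A_g1", "B_g1"), gene_id = "g1",
                         stringsAsFactors = FALSE)
  none <- pool_gene_counts(snps_a, snps_b, gene_map, exclusion = "none")
  expect_equal(none$Pn, 4)
  expect_equal(none$Ps, 6)
  low <- pool_gene_counts(snps_a, snps_b, gene_map, exclusion = "low")
  expect_equal(low$Pn, 3)   # one low-frequency non-silent SNP dropped
  expect_equal(low$Ps, 5)
  lm <- pool_gene_counts(snps_a, snps_b, gene_map, exclusion = "low_moderate")
  expect_equal(lm$Ps, 4)
  # genes without SNPs appear with zero counts
  gm2 <- rbind(gene_map, data.frame(contig = c("A_g2", "B_g2"),
                                    gene_id = "g2"))
  none2 <- pool_gene_counts(snps_a, snps_b, gm2, exclusion = "none")
  expect_equal(none2$Pn[none2$gene_id == "g2"], 0)
  expect_equal(none2$Ps[none2$gene_id == "g2"], 0)
})

test_that("detection probability is the binomial upper tail", {
  # depth 10, frequency 0.25, at least 2 copies
  hand <- 1 - 0.75^10 - 10 * 0.25 * 0.75^9
  expect_equal(detection_probability(10, 0.25), hand, tolerance = 1e-12)
  expect_equal(round(detection_probability(10, 0.25), 3), 0.756)
  expect_equal(detection_probability(10, 0), 0)
  expect_gt(detection_probability(200, 0.25), 0.999)
  # manual binomial-sum oracle across parameters
  for (depth in c(10, 25, 60)) {
    for (f in c(0.05, 0.25, 0.5)) {
      want <- sum(sapply(2:depth, function(k) {
        choose(depth, k) * f^k * (1 - f)^(depth - k)
      }))
      expect_equal(detection_probability(depth, f), want, tolerance = 1e-9)
    }
  }
})

test_that("high-coverage error-free pileups recover the true SNP set", {
  cfg <- sim_config(n_genes = 25, coverage_mean = 100, error_rate = 0,
                    seed = 83)
  sim <- simulate_study(cfg)
  calls <- call_snps(sim$pileup_a)
  truth <- sim$snps[sim$snps$species == "A", ]
  truth_key <- paste0("A_", truth$gene_id, ":", truth$pos)
  call_key <- paste(calls$contig, calls$pos, sep = ":")
  # no false positives without sequencing error
  expect_true(all(call_key %in% truth_key))
  # every common variant is found at this depth
  common <- truth_key[truth$minor_freq >= 0.25]
  expect_true(all(common %in% call_key))
})
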