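test_that("zero divergence yields identical sequences and empty truth", {
  set.seed(41)
  g <- simulate_ortholog_pair(sim_config(divergence_target = 0,
                                         adaptive_fraction = 0, theta = 0), 1)
  expect_identical(g$seq_a, g$seq_b)
  expect_equal(nrow(g$subs), 0)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(divergence_target = 0, adaptive_fraction = 0.2),
               "impossible")
  expect_error(sim_config(theta = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("a fixed seed reproduces the study byte for byte", {
  cfg <- sim_config(n_genes = 5, seed = 1, coverage_mean = 20)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$seq_a, s2$seq_a)
  expect_identical(s1$snps, s2$snps)
  expect_identical(s1$pileup_a, s2$pileup_a)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_sim_data(s1, d1)
  write_sim_data(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("realized divergence tracks the configured target", {
  sim <- simulate_study(sim_config(n_genes = 200, mean_len_codons = 300,
                                   divergence_target = 0.015, theta = 0,
                                   seed = 43), pileups = FALSE)
  pd <- mapply(p_distance, sim$seq_a, sim$seq_b)
  expect_lt(abs(mean(pd) - 0.015), 0.003)
})

test_that("truth tables reconcile with the emitted sequences", {
  sim <- simulate_study(sim_config(n_genes = 100, seed = 47), pileups = FALSE)
  # substitution events match the reconstructible nucleotide differences
  # (multiple hits at one site are rare at ~1.5% divergence)
  nt_diffs <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$seq_a, sim$seq_b))
  expect_lt(abs(nt_diffs - nrow(sim$subs)) / nrow(sim$subs), 0.02)
  # NG86 pathway counting over the pairs recovers the true Dn/Ds totals
  div <- do.call(rbind, lapply(seq_len(nrow(sim$genes)), function(i) {
    gene_divergence(codon_alignment(sim$genes$gene_id[i],
                                    sim$seq_a[[i]], sim$seq_b[[i]]))
  }))
  truth <- truth_gene_counts(sim)
  expect_lt(abs(sum(div$Dn) - sum(truth$Dn)) / sum(truth$Dn), 0.02)
  expect_lt(abs(sum(div$Ds) - sum(truth$Ds)) / max(1, sum(truth$Ds)), 0.05)
  # emitted files round-trip through the package readers
  d <- file.path(tempdir(), "roundtrip")
  write_sim_data(sim, d)
  fa <- read_fasta(file.path(d, "cds_A.fasta"))
  expect_identical(unname(fa), unname(sim$seq_a))
  expect_identical(names(fa), names(sim$seq_a))
  unlink(d, recursive = TRUE)
})

test_that("the realized adaptive fraction converges to the configured value", {
  sim <- simulate_study(sim_config(n_genes = 1000, adaptive_fraction = 0.3,
                                   theta = 0, seed = 53), pileups = FALSE)
  expect_lt(abs(true_alpha(sim) - 0.3), 0.03)
})

test_that("SNP minor-allele frequencies follow the configured spectrum", {
  cfg <- sim_config(n_genes = 300, seed = 59)
  sim <- simulate_study(cfg, pileups = FALSE)
  expect_true(all(sim$snps$minor_freq > 0 & sim$snps$minor_freq <= 0.5))
  # frequencies live on the pool grid k/120
  expect_true(all(abs(sim$snps$minor_freq * 120 -
                        round(sim$snps$minor_freq * 120)) < 1e-9))
  # silent/non-silent truth agrees with translating both alleles in place
  for (i in sample.int(nrow(sim$snps), 50)) {
    s <- sim$snps[i, ]
    seqs <- if (s$species == "A") sim$seq_a else sim$seq_b
    seq <- seqs[[paste0(s$species, "_", s$gene_id)]]
    ci <- (s$pos - 1) %/% 3 + 1
    codon <- substring(seq, (ci - 1) * 3 + 1, ci * 3)
    cp <- (s$pos - 1) %% 3 + 1
    expect_equal(substr(codon, cp, cp), s$major)
    want <- oracle_classify(codon, cp, s$major, s$minor)
    expect_equal(ifelse(s$silent, "silent", "non-silent"), want)
  }
})

test_that("pileup simulation reproduces binomial allele sampling", {
  # one SNP at frequency 0.5, coverage 200, no error: the minor-allele count
  # behaves like Binomial(depth, 0.5)
  seqs <- paste(rep("GGT", 40), collapse = "")
  counts <- sapply(1:30, function(s) {
    pl <- simulate_pileup(seqs, data.frame(pos = 60, minor = "A",
                                           minor_freq = 0.5),
                          coverage_mean = 200, error_rate = 0,
                          seed = 700 + s)
    row <- pl[pl$pos == 60, ]
    c(minor = row$countA, depth = row$depth)
  })
  frac <- sum(counts["minor", ]) / sum(counts["depth", ])
  expect_lt(abs(frac - 0.5), 0.02)
  # without SNPs and error, every column is monoallelic
  pl0 <- simulate_pileup(seqs, NULL, coverage_mean = 50, error_rate = 0,
                         seed = 61)
  cm <- as.matrix(pl0[, c("countA", "countC", "countG", "countT")])
  expect_true(all(rowSums(cm > 0) <= 1))
  expect_equal(rowSums(cm), pl0$depth, ignore_attr = TRUE)
  # zero coverage warns and returns an empty pileup
  expect_warning(pl_empty <- simulate_pileup(seqs, NULL, coverage_mean = 0),
                 "empty")
  expect_equal(nrow(pl_empty), 0)
  # seeded pileups are reproducible
  p1 <- simulate_pileup(seqs, NULL, coverage_mean = 30, seed = 67)
  p2 <- simulate_pileup(seqs, NULL, coverage_mean = 30, seed = 67)
  expect_identical(p1, p2)
})
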