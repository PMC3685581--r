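test_that("the MKT chi-square matches the hand-computed Pearson statistic", {
  counts <- data.frame(gene_id = "g1", Dn = 20, Ds = 5, Pn = 10, Ps = 40)
  res <- mkt(counts)
  # expected cells: 10/15/20/30 -> chi2 = 100/10 + 100/15 + 100/20 + 100/30
  expect_equal(res$chi2, 25, tolerance = 1e-9)
  expect_equal(res$p_raw, pchisq(25, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$ratio, (20 / 5) / (10 / 40))
  expect_equal(res$direction, "positive")
  expect_true(res$eligible)
  expect_true(res$significant)
})

test_that("a perfectly independent table gives chi-square zero", {
  res <- mkt(data.frame(gene_id = "g", Dn = 10, Ds = 20, Pn = 5, Ps = 10))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p_raw, 1, tolerance = 1e-12)
  expect_equal(res$ratio, 1)
  expect_false(res$significant)
})

test_that("zero-cell genes are excluded rather than tested", {
  counts <- data.frame(gene_id = c("g1", "g2", "g3"),
                       Dn = c(5, 0, 5), Ds = c(0, 3, 3),
                       Pn = c(2, 2, 2), Ps = c(4, 4, 4))
  res <- mkt(counts)
  expect_equal(res$eligible, c(FALSE, FALSE, TRUE))
  expect_equal(res$excluded_reason[1:2], rep("zero cell", 2))
  expect_true(all(is.na(res$p_raw[1:2])))
  expect_false(any(res$significant[1:2]))
})

test_that("the chi-square statistic is invariant to swapping the table rows", {
  set.seed(91)
  for (i in 1:20) {
    v <- sample(1:30, 4, replace = TRUE)
    r1 <- mkt(data.frame(gene_id = "g", Dn = v[1], Ds = v[2],
                         Pn = v[3], Ps = v[4]))
    r2 <- mkt(data.frame(gene_id = "g", Dn = v[3], Ds = v[4],
                         Pn = v[1], Ps = v[2]))
    expect_equal(r1$chi2, r2$chi2, tolerance = 1e-9)
    expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-9)
    # the neutrality ratio inverts
    expect_equal(r1$ratio, 1 / r2$ratio, tolerance = 1e-9)
  }
})

test_that("Fisher's exact test option reproduces stats::fisher.test", {
  counts <- data.frame(gene_id = c("a", "b"),
                       Dn = c(6, 3), Ds = c(2, 7), Pn = c(1, 4), Ps = c(8, 2))
  res <- mkt(counts, method = "fisher")
  for (i in 1:2) {
    want <- fisher.test(matrix(c(counts$Dn[i], counts$Ds[i],
                                 counts$Pn[i], counts$Ps[i]),
                               nrow = 2, byrow = TRUE))$p.value
    expect_equal(res$p_raw[i], want, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule", {
  # fdr_correct operates on the stored raw p-values directly
  fake <- data.frame(gene_id = paste0("g", 1:4),
                     Dn = 5, Ds = 5, Pn = 5, Ps = 5,
                     eligible = TRUE,
                     p_raw = c(0.01, 0.02, 0.03, 0.04),
                     ratio = c(2, 2, 2, 0.5))
  adj <- fdr_correct(fake, fdr = 0.05)
  # BH on (.01,.02,.03,.04): q_i = min over j>=i of p_j * 4 / j = 0.04 for all
  expect_equal(adj$q_fdr, rep(0.04, 4), tolerance = 1e-12)
  # significance additionally requires ratio > 1
  expect_equal(adj$significant, c(TRUE, TRUE, TRUE, FALSE))
  # a single tested gene: q equals p
  one <- fdr_correct(data.frame(gene_id = "g", Dn = 1, Ds = 1, Pn = 1, Ps = 1,
                                eligible = TRUE, p_raw = 0.031, ratio = 3))
  expect_equal(one$q_fdr, 0.031)
  # q is never below p
  set.seed(97)
  many <- fdr_correct(data.frame(gene_id = paste0("g", 1:50),
                                 Dn = 1, Ds = 1, Pn = 1, Ps = 1,
                                 eligible = TRUE, p_raw = runif(50),
                                 ratio = 2))
  expect_true(all(many$q_fdr >= many$p_raw - 1e-12))
  # uninformative p-values yield no significance
  flat <- fdr_correct(data.frame(gene_id = paste0("g", 1:10),
                                 Dn = 1, Ds = 1, Pn = 1, Ps = 1,
                                 eligible = TRUE, p_raw = 1, ratio = 2))
  expect_false(any(flat$significant))
})

test_that("the aggregate alpha estimator follows its closed form", {
  counts <- data.frame(Dn = c(25, 15), Ds = c(12, 8),
                       Pn = c(6, 4), Ps = c(3, 7))
  fit <- estimate_alpha(counts, n_bootstrap = 0)
  expect_equal(fit$alpha, 1 - (20 * 10) / (40 * 10))   # = 0.5
  expect_equal(unname(fit$totals), c(40, 20, 10, 10))
  expect_equal(coef(fit), c(alpha = 0.5))
  # genes with all-zero counts do not change the point estimate
  counts0 <- rbind(counts, data.frame(Dn = 0, Ds = 0, Pn = 0, Ps = 0))
  expect_equal(estimate_alpha(counts0, n_bootstrap = 0)$alpha, fit$alpha)
})

test_that("degenerate alpha inputs are rejected", {
  expect_error(estimate_alpha(data.frame(Dn = c(0, 0), Ds = 1:2,
                                         Pn = 1:2, Ps = 1:2),
                              n_bootstrap = 0), "Dn")
  expect_error(estimate_alpha(data.frame(Dn = 1:2, Ds = 1:2,
                                         Pn = 1:2, Ps = c(0, 0)),
                              n_bootstrap = 0), "Ps")
  expect_error(estimate_alpha(data.frame(Dn = 1, Ds = 1, Pn = 1, Ps = 1),
                              n_bootstrap = 0), "2 genes")
  expect_error(estimate_alpha(data.frame(Dn = c(-1, 2), Ds = 1:2,
                                         Pn = 1:2, Ps = 1:2),
                              n_bootstrap = 0), "non-negative")
})

test_that("the gene bootstrap is seeded, ordered and covers the estimate", {
  set.seed(103)
  counts <- data.frame(Dn = rpois(80, 6), Ds = rpois(80, 4),
                       Pn = rpois(80, 3), Ps = rpois(80, 5))
  f1 <- estimate_alpha(counts, n_bootstrap = 400, seed = 7)
  f2 <- estimate_alpha(counts, n_bootstrap = 400, seed = 7)
  expect_identical(f1$boot, f2$boot)
  expect_identical(f1$ci_low, f2$ci_low)
  expect_lt(f1$ci_low, f1$ci_high)
  expect_equal(length(f1$boot), 400)
  # percentile interval matches quantiles of the stored replicates
  ok <- is.finite(f1$boot)
  expect_equal(c(f1$ci_low, f1$ci_high),
               unname(quantile(f1$boot[ok], c(0.025, 0.975))))
  # confint at the fitted level returns the stored interval
  ci <- confint(f1)
  expect_equal(unname(ci[1, ]), c(f1$ci_low, f1$ci_high))
})

test_that("molecular-clock times follow T = dS / (2r)", {
  ce <- clock_estimate(0.06, 0.015)
  expect_equal(ce$t_mya, 2.0)
  multi <- clock_estimate(0.06, c(0.016, 0.015, 0.011))
  expect_equal(multi$t_mya, 0.06 / (2 * c(0.016, 0.015, 0.011)))
  expect_equal(attr(multi, "t_min"), 0.06 / 0.032)
  expect_equal(attr(multi, "t_max"), 0.06 / 0.022)
  expect_equal(clock_estimate(0, 0.015)$t_mya, 0)
  expect_error(clock_estimate(0.06, 0))
})
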