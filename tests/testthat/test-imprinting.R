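# Imprinting caller: informative filter, chi-square dosage test, FDR,
# reciprocal classification rules, contamination estimator.

counts_row <- function(gene, dir, m, p, rep_i = 1) {
  data.frame(gene_id = gene, direction = dir, replicate = rep_i,
             maternal = m, paternal = p)
}

test_that("informative filter applies the per-direction read threshold", {
  cnt <- rbind(counts_row("g1", "AxB", 12, 7),    # 19 reads: below threshold
               counts_row("g1", "BxA", 100, 50),
               counts_row("g2", "AxB", 20, 0),    # boundary: retained
               counts_row("g2", "BxA", 40, 20))
  res <- informative_filter(cnt, 20)
  expect_equal(res$testable[res$gene_id == "g1"], c(FALSE, FALSE))
  expect_equal(res$testable[res$gene_id == "g2"], c(TRUE, TRUE))
  res0 <- informative_filter(cnt, 0)
  expect_true(all(res0$testable))
})

test_that("chi-square dosage test matches hand arithmetic and chisq.test", {
  # exact 2:1 split: statistic 0, p 1
  r <- chisq_allelic_test(20, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # inverted split: (10-20)^2/20 + (20-10)^2/10 = 15
  r <- chisq_allelic_test(10, 20)
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 1.08e-4, tolerance = 1e-2)
  # all paternal: (0-20)^2/20 + (30-10)^2/10 = 20 + 40 = 60
  expect_equal(chisq_allelic_test(0, 30)$statistic, 60)
  # independent route: stats::chisq.test without correction
  for (mp in list(c(30, 10), c(55, 45), c(3, 17))) {
    ours <- chisq_allelic_test(mp[1], mp[2])
    ref <- suppressWarnings(chisq.test(mp, p = c(2 / 3, 1 / 3), correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  expect_error(chisq_allelic_test(0, 0), "zero informative")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)  # single p: q = p
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  set.seed(5)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification applies reciprocal fraction and significance rules", {
  cnt <- rbind(
    counts_row("peg", "AxB", 5, 45),  counts_row("peg", "BxA", 6, 44),
    counts_row("bal", "AxB", 40, 20), counts_row("bal", "BxA", 40, 20),
    counts_row("conf", "AxB", 95, 5), counts_row("conf", "BxA", 9, 41),
    counts_row("meg", "AxB", 97, 3),  counts_row("meg", "BxA", 95, 5),
    counts_row("low", "AxB", 6, 4),   counts_row("low", "BxA", 100, 2)
  )
  calls <- call_imprinting(cnt)
  got <- setNames(calls$call, calls$gene_id)
  expect_equal(got[["peg"]], "PEG")            # paternal 0.90 / 0.88, significant
  expect_equal(got[["bal"]], "biallelic")      # exact 2:1
  expect_equal(got[["conf"]], "biallelic")     # direction conflict
  expect_equal(got[["meg"]], "MEG")
  expect_equal(got[["low"]], "not_testable")   # 10 reads in AxB
  expect_true(all(calls$q_AxB[calls$call %in% c("MEG", "PEG")] < 0.01))
})

test_that("replicates are summed within direction before testing", {
  cnt <- rbind(counts_row("g", "AxB", 6, 6, 1), counts_row("g", "AxB", 6, 6, 2),
               counts_row("g", "BxA", 12, 12, 1))
  calls <- call_imprinting(cnt)
  expect_equal(calls$informative_AxB, 24)  # 12 + 12, above threshold
  expect_equal(calls$call, "biallelic")
})

test_that("classification is label-symmetric", {
  set.seed(31)
  cfg <- sim_config(n_genes = 300, chrom_length = 3e6, seed = 37)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  cnt <- simulate_counts(ann, truth, cfg)
  calls <- call_imprinting(cnt)
  swapped <- cnt
  swapped$maternal <- cnt$paternal
  swapped$paternal <- cnt$maternal
  calls_sw <- call_imprinting(swapped, meg_maternal = 0.50,
                              peg_paternal = 0.85, expected_maternal = 1 / 3)
  expect_equal(calls_sw$gene_id, calls$gene_id)
  expect_equal(calls_sw$call == "MEG", calls$call == "PEG")
  expect_equal(calls_sw$call == "PEG", calls$call == "MEG")
  expect_equal(calls_sw$chi2_AxB, calls$chi2_AxB)
})

test_that("FDR is controlled on purely biallelic data", {
  cfg <- sim_config(n_genes = 3000, chrom_length = 3e7, seed = 41,
                    class_fractions = c(PEG = 0, MEG = 0, biallelic = 1),
                    replicates_per_direction = 1)
  ann <- generate_annotation(cfg)
  cnt <- simulate_counts(ann, simulate_truth(ann, cfg), cfg)
  calls <- call_imprinting(cnt)
  frac_sig <- mean(calls$q_AxB < 0.01, na.rm = TRUE)
  se <- sqrt(0.01 * 0.99 / sum(is.finite(calls$q_AxB)))
  expect_lte(frac_sig, 0.01 + 3 * se)
  expect_true(all(calls$call %in% c("biallelic", "not_testable")) ||
                mean(calls$call %in% c("MEG", "PEG")) < 0.005)
})

test_that("contamination estimator inverts the mixture model", {
  est <- estimate_contamination(data.frame(gene_id = "g", maternal = 200,
                                           paternal = 100))
  expect_equal(est$c, 0)          # f_obs = 2/3: clean endosperm
  est <- estimate_contamination(data.frame(gene_id = "g", maternal = 75,
                                           paternal = 25))
  expect_equal(est$c, 0.25)       # f_obs = 0.75
  est <- estimate_contamination(data.frame(gene_id = "g", maternal = 60,
                                           paternal = 40))
  expect_equal(est$c, 0)          # f_obs = 0.60: clamped at 0
  expect_error(estimate_contamination(data.frame(gene_id = "g", maternal = 0,
                                                 paternal = 0)), "positive")
  # restriction to a provided gene set
  cnt <- rbind(counts_row("a", "AxB", 90, 10), counts_row("b", "AxB", 66, 34))
  est_b <- estimate_contamination(cnt, genes = "b")
  expect_equal(est_b$n_genes, 1)
  expect_equal(est_b$f_obs, 0.66)
})

test_that("contamination is recovered from biallelic simulations", {
  for (c_true in c(0, 0.25)) {
    cfg <- sim_config(n_genes = 2000, chrom_length = 2e7, seed = 43,
                      contamination = c_true, sequencing_depth = 100,
                      replicates_per_direction = 1,
                      class_fractions = c(PEG = 0, MEG = 0, biallelic = 1))
    ann <- generate_annotation(cfg)
    cnt <- simulate_counts(ann, simulate_truth(ann, cfg), cfg)
    est <- estimate_contamination(cnt[cnt$direction == "AxB", ])
    expect_lt(abs(est$c - c_true), 0.02)
  }
})
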