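# Synthetic-data generator: configuration validation, deterministic
# annotation placement, mark structure, and the count model.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_fractions = c(PEG = 0.5, MEG = 0.4, biallelic = 0.2)),
               "sum to 1")
  expect_error(sim_config(contamination = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(maternal_fraction_by_class =
                            c(PEG = 0.1, MEG = 0.95, biallelic = 0.5)),
               "2/3")
  expect_error(sim_config(mark_effect = list(PEG = c(CHG_central_cell = 0.4))),
               "each class")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(unname(cfg$maternal_fraction_by_class["biallelic"]), 2 / 3)
})

test_that("annotation placement is valid and deterministic", {
  cfg <- sim_config(n_genes = 1, chrom_length = 10000, seed = 5)
  ann1 <- generate_annotation(cfg)
  expect_equal(nrow(ann1), 1)
  expect_true(ann1$start >= 0 && ann1$end <= 10000)

  cfg <- sim_config(n_genes = 200, chrom_length = 2e6,
                    gene_length_range = c(1000, 3000), seed = 9)
  ann <- generate_annotation(cfg)
  lens <- ann$end - ann$start
  expect_true(all(lens >= 1000 & lens <= 3000))
  ord <- order(ann$start)
  expect_true(all(ann$start[ord][-1] >= ann$end[ord][-200]))  # no overlaps
  expect_identical(ann, generate_annotation(cfg))  # same seed, same output

  expect_error(generate_annotation(sim_config(n_genes = 100, chrom_length = 5e4)),
               "configuration error")
})

test_that("fixed seed gives identical datasets across runs", {
  cfg <- small_config(n_genes = 15, seed = 3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$marks, d2$marks)
  expect_identical(d1$counts, d2$counts)
})

test_that("truth table covers each gene once with configured class mix", {
  cfg <- small_config(n_genes = 100, chrom_length = 1e6)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  expect_setequal(truth$gene_id, ann$gene_id)
  expect_equal(anyDuplicated(truth$gene_id), 0)
  expect_equal(unname(table(truth$class)[c("PEG", "MEG", "biallelic")]),
               c(10, 10, 80), ignore_attr = TRUE)
  expect_equal(truth$maternal_fraction[truth$class == "biallelic"][1], 2 / 3)
})

test_that("marks carry the configured maternal-allele structure", {
  cfg <- small_config(n_genes = 30, chrom_length = 3e5, noise_sd = 0,
                      prc2_target_fraction = 0, effect_scale_range = c(1, 1))
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  mk <- simulate_marks(ann, truth, cfg)

  # noiseless: body log2 ratio over H3 equals the class effect exactly
  tr <- mk$tracks$H3K27me3$maternal
  h3 <- mk$tracks$H3$maternal
  ratio <- log2(tr$value / h3$value)
  peg <- truth$gene_id[truth$class == "PEG"][1]
  i <- match(peg, ann$gene_id)
  body <- which(tr$start >= ann$start[i] & tr$end <= ann$end[i])
  expect_equal(ratio[body], rep(2.0, length(body)))
  bi <- match(truth$gene_id[truth$class == "biallelic"][1], ann$gene_id)
  body_bi <- which(tr$start >= ann$start[bi] & tr$end <= ann$end[bi])
  expect_equal(ratio[body_bi], rep(0, length(body_bi)))

  # H3 control positive wherever ChIP signal exists
  expect_true(all(h3$value > 0))

  # methylation counts are valid
  cc <- mk$methylation$central_cell
  expect_true(all(cc$count_methylated >= 0 & cc$count_unmethylated >= 0))

  # null effects: PEG and biallelic mark distributions indistinguishable
  cfg0 <- small_config(n_genes = 60, chrom_length = 6e5, seed = 8,
                       mark_effect = list(
                         PEG = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0),
                         MEG = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0),
                         biallelic = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0)),
                       prc2_target_fraction = 0)
  ann0 <- generate_annotation(cfg0)
  truth0 <- simulate_truth(ann0, cfg0)
  mk0 <- simulate_marks(ann0, truth0, cfg0)
  lr <- bin_log_ratio(mk0$tracks$H3K27me3$maternal, mk0$tracks$H3$maternal)
  gz <- gene_zscore(zscore_track(lr), ann0)
  z_peg <- gz$z[truth0$class == "PEG"]
  z_bi <- gz$z[truth0$class == "biallelic"]
  expect_gt(wilcoxon_rank_sum(z_peg, z_bi, exact_limit = 0)$p_value, 0.01)
})

test_that("simulated maternal gene z-scores separate PEGs from biallelic genes", {
  cfg <- sim_config(n_genes = 500, chrom_length = 4e6, seed = 21)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  mk <- simulate_marks(ann, truth, cfg)
  for (mark in c("H3K27me3", "H3K9me2")) {
    lr <- bin_log_ratio(mk$tracks[[mark]]$maternal, mk$tracks$H3$maternal)
    gz <- gene_zscore(zscore_track(lr), ann)
    expect_gt(mean(gz$z[truth$class == "PEG"]),
              mean(gz$z[truth$class == "biallelic"]))
  }
})

test_that("count model follows the contamination mixture", {
  # degenerate contamination: every read maternal
  cfg1 <- small_config(n_genes = 25, contamination = 1)
  ann <- generate_annotation(cfg1)
  cnt <- simulate_counts(ann, simulate_truth(ann, cfg1), cfg1)
  expect_true(all(cnt$paternal == 0))

  # biallelic pooled fraction converges to (1 - c) * 2/3 + c
  cfg <- sim_config(n_genes = 2000, chrom_length = 2e7, seed = 13,
                    contamination = 0.15, sequencing_depth = 100,
                    replicates_per_direction = 1,
                    class_fractions = c(PEG = 0, MEG = 0, biallelic = 1))
  ann <- generate_annotation(cfg)
  cnt <- simulate_counts(ann, simulate_truth(ann, cfg), cfg)
  one_dir <- cnt[cnt$direction == "AxB", ]
  f_pool <- sum(one_dir$maternal) / sum(one_dir$maternal + one_dir$paternal)
  f_expect <- (1 - 0.15) * 2 / 3 + 0.15
  n_reads <- sum(one_dir$maternal + one_dir$paternal)
  se <- sqrt(f_expect * (1 - f_expect) / n_reads)
  expect_lt(abs(f_pool - f_expect), max(3 * se, 1e-3))
  expect_lt(abs(f_pool - 0.7167), 0.01)

  # reciprocal directions preserve parental roles (same expected fraction)
  other <- cnt[cnt$direction == "BxA", ]
  f_other <- sum(other$maternal) / sum(other$maternal + other$paternal)
  expect_lt(abs(f_other - f_expect), 0.01)
})

test_that("class separation of mark signal is monotone in mark_effect", {
  sep <- vapply(c(0, 1, 2), function(e) {
    cfg <- small_config(n_genes = 60, chrom_length = 6e5, seed = 17,
                        effect_scale_range = c(1, 1),
                        prc2_target_fraction = 0,
                        mark_effect = list(
                          PEG = c(CHG_central_cell = 0, H3K27me3_mat = e, H3K9me2_mat = 0),
                          MEG = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0),
                          biallelic = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0)))
    ann <- generate_annotation(cfg)
    truth <- simulate_truth(ann, cfg)
    mk <- simulate_marks(ann, truth, cfg)
    lr <- bin_log_ratio(mk$tracks$H3K27me3$maternal, mk$tracks$H3$maternal)
    gz <- gene_zscore(zscore_track(lr), ann)
    mean(gz$z[truth$class == "PEG"]) - mean(gz$z[truth$class == "biallelic"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("simulation files round-trip through standard formats", {
  cfg <- small_config(n_genes = 8, chrom_length = 1e5)
  dat <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  files <- write_simulation(dat, dir)
  expect_true(all(file.exists(files)))

  ann2 <- read_gene_annotation(file.path(dir, "annotation.gff3"))
  expect_equal(ann2$start, dat$annotation$start)
  expect_equal(ann2$end, dat$annotation$end)
  expect_equal(ann2$strand, dat$annotation$strand)

  tr2 <- read_bedgraph(file.path(dir, "H3K27me3_maternal.bedgraph"))
  expect_equal(sum(tr2$end - tr2$start), cfg$chrom_length)

  cx2 <- read_cx_report(file.path(dir, "methylation_central_cell.tsv"))
  expect_equal(nrow(cx2), nrow(dat$marks$methylation$central_cell))

  cnt2 <- read_allele_counts(file.path(dir, "counts.tsv"))
  expect_equal(cnt2$maternal, dat$counts$maternal)
})
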