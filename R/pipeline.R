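# End-to-end orchestration: simulate (or load) data, process ChIP tracks,
# compute methylation levels, score genes, call imprinting, and test the
# enrichment of the epigenetic prediction among expression-based PEG calls.

.default_params <- function() {
  list(
    bin_width = 150L,       # log2-ratio bin width (bp)
    pseudocount = 1,        # log2-ratio pseudocount (read-equivalents)
    flank_bp = 2000L,       # metagene flank extent
    flank_bin_bp = 100L,    # metagene flank bin width
    body_bins = 40L,        # metagene body bins
    presence_z = 1,         # z-score presence threshold for histone marks
    presence_meth = 0.2,    # presence threshold for CHG methylation level
    n_levels = 4L,          # per-mark levels 0..4, score 0..12
    min_reads = 20L,        # informative-read threshold
    fdr = 0.01,             # FDR-adjusted p threshold
    meg_maternal = 0.85,    # MEG maternal-fraction rule
    peg_paternal = 0.50,    # PEG paternal-fraction rule
    expected_maternal = 2 / 3  # endosperm dosage expectation
  )
}

#' Run the full epigenetic-signature imprinting pipeline
#'
#' Simulates a dataset (or accepts one), normalizes the allele-resolved
#' histone tracks against the H3 control, z-scores them, computes per-gene
#' body z-scores and central-cell CHG methylation levels, derives the 0-12
#' epigenetic score and its maximum-category PEG prediction set, calls
#' MEGs/PEGs from the reciprocal-cross counts, estimates seed-coat
#' contamination per direction, and tests the enrichment of predicted PEGs
#' among expression-called PEGs (hypergeometric, upper tail). The run is
#' deterministic for a fixed configuration seed.
#'
#' @param config Either a [sim_config()] object, a list of arguments for
#'   [sim_config()], or a path to a YAML file with blocks `sim` (generator
#'   arguments) and optionally `params` (pipeline parameters, see
#'   Details).
#' @param dataset Optionally, a pre-built dataset from [simulate_dataset()]
#'   (overrides `config`'s generator block).
#' @param params Named list overriding individual pipeline parameters:
#'   `bin_width` (150), `pseudocount` (1), `presence_z` (1), `presence_meth`
#'   (0.2), `n_levels` (4), `min_reads` (20), `fdr` (0.01), `meg_maternal`
#'   (0.85), `peg_paternal` (0.50), `expected_maternal` (2/3).
#' @param out_dir Optional output directory; when given, stage outputs (gene
#'   z-score TSV, methylation TSV, score TSV, imprinting-call TSV, predicted
#'   PEG list) and the JSON run report are written there.
#' @return A list of class `endosign_run` with elements `report` (run
#'   summary; every threshold echoed), `gene_scores` (per-gene mark values,
#'   levels, score), `imprinting` (caller output), `enrichment`,
#'   `contamination`, `truth` (when simulated) and `config`.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         params = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    yml <- yaml::read_yaml(config)
    params <- utils::modifyList(yml$params %||% list(), params)
    config <- do.call(sim_config, yml$sim %||% list())
  } else if (is.list(config) && !inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  prm <- utils::modifyList(.default_params(), params)

  if (is.null(dataset)) dataset <- simulate_dataset(config)
  ann <- dataset$annotation

  # stage 1: ChIP normalization and per-gene z-scores
  gz <- list()
  for (mark in c("H3K27me3", "H3K9me2")) {
    for (allele in c("maternal", "paternal")) {
      lr <- bin_log_ratio(dataset$marks$tracks[[mark]][[allele]],
                          dataset$marks$tracks$H3[[allele]],
                          bin_width = prm$bin_width,
                          pseudocount = prm$pseudocount)
      z <- zscore_track(lr)
      gz[[paste(mark, allele, sep = "_")]] <- gene_zscore(z, ann)
    }
  }

  # stage 2: central-cell CHG methylation level per gene
  meth_cc <- gene_methylation_level(dataset$marks$methylation$central_cell,
                                    ann, contexts = "CHG")

  # stage 3: epigenetic score and PEG prediction
  scores <- epigenetic_scores(
    gene_id = ann$gene_id,
    chg_cc = meth_cc$level[match(ann$gene_id, meth_cc$gene_id)],
    k27_mat = gz$H3K27me3_maternal$z[match(ann$gene_id, gz$H3K27me3_maternal$gene_id)],
    k9_mat = gz$H3K9me2_maternal$z[match(ann$gene_id, gz$H3K9me2_maternal$gene_id)],
    presence_z = prm$presence_z,
    presence_meth = prm$presence_meth,
    n_levels = prm$n_levels
  )
  predicted <- predict_pegs(scores)

  # stage 4: imprinting calls and contamination
  calls <- call_imprinting(dataset$counts,
                           min_reads = prm$min_reads, fdr = prm$fdr,
                           meg_maternal = prm$meg_maternal,
                           peg_paternal = prm$peg_paternal,
                           expected_maternal = prm$expected_maternal)
  merged <- .merge_replicates(dataset$counts)
  merged <- informative_filter(merged, prm$min_reads)
  contamination <- lapply(split(merged[merged$testable, ],
                                merged$direction[merged$testable]),
                          estimate_contamination)

  # stage 5: enrichment of the epigenetic prediction among expression calls
  tested <- calls$gene_id[calls$call != "not_testable"]
  called_peg <- calls$gene_id[calls$call == "PEG"]
  pred_tested <- intersect(predicted, tested)
  enr_expr <- hypergeom_enrichment(
    N = length(tested), K = length(called_peg),
    n = length(pred_tested), k = length(intersect(pred_tested, called_peg))
  )
  enrichment <- list(predicted_in_called_pegs = enr_expr)
  if (!is.null(dataset$truth)) {
    true_peg <- dataset$truth$gene_id[dataset$truth$class == "PEG"]
    enrichment$true_pegs_in_max_category <- hypergeom_enrichment(
      N = nrow(ann), K = length(true_peg),
      n = length(predicted), k = length(intersect(predicted, true_peg))
    )
  }

  # per-category composition table against the maximum-score category
  comp <- NULL
  max_cat <- 3L * prm$n_levels
  cat_tab <- merge(scores[c("gene_id", "category")],
                   calls[c("gene_id", "call")], by = "gene_id")
  cat_tab <- cat_tab[cat_tab$call != "not_testable", ]
  if (nrow(cat_tab)) {
    per_cat <- stats::aggregate(cbind(peg = call == "PEG", total = TRUE) ~ category,
                                data = cat_tab, FUN = sum)
    ref <- per_cat[per_cat$category == max_cat, ]
    if (nrow(ref) == 1) {
      comp <- cbind(category = per_cat$category,
                    suppressMessages(category_composition_test(
                      per_cat$peg, per_cat$total, ref$peg, ref$total)))
    }
  }

  report <- list(
    parameters = prm,
    n_genes = nrow(ann),
    n_tested = length(tested),
    n_meg = sum(calls$call == "MEG"),
    n_peg = sum(calls$call == "PEG"),
    n_not_testable = sum(calls$call == "not_testable"),
    n_predicted_pegs = length(predicted),
    predicted_pegs = predicted,
    contamination = lapply(contamination, function(x)
      list(c = x$c, f_obs = x$f_obs, n_genes = x$n_genes)),
    enrichment_predicted_in_called = as.list(enr_expr),
    seed = config$seed
  )
  if (!is.null(enrichment$true_pegs_in_max_category))
    report$enrichment_true_pegs_in_max_category <-
      as.list(enrichment$true_pegs_in_max_category)

  result <- list(report = report, gene_scores = scores, gene_zscores = gz,
                 methylation_cc = meth_cc, imprinting = calls,
                 enrichment = enrichment, category_composition = comp,
                 contamination = contamination, truth = dataset$truth,
                 config = config)
  class(result) <- "endosign_run"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    zs <- do.call(rbind, lapply(names(gz), function(nm) {
      d <- gz[[nm]]
      d$mark_allele <- nm
      d
    }))
    wt(zs, "gene_zscores.tsv")
    wt(meth_cc, "methylation_central_cell_chg.tsv")
    wt(scores, "epigenetic_scores.tsv")
    wt(calls, "imprinting_calls.tsv")
    if (!is.null(comp)) wt(comp, "category_composition.tsv")
    writeLines(predicted, file.path(out_dir, "predicted_pegs.txt"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.endosign_run <- function(x, ...) {
  r <- x$report
  cat("endosign pipeline run (seed ", r$seed, ")\n", sep = "")
  cat("  genes: ", r$n_genes, "; testable: ", r$n_tested,
      "; MEG: ", r$n_meg, "; PEG: ", r$n_peg, "\n", sep = "")
  cat("  predicted PEGs (max score category): ", r$n_predicted_pegs, "\n", sep = "")
  for (dir in names(r$contamination))
    cat(sprintf("  contamination %s: c = %.3f (f_obs = %.3f, %d genes)\n",
                dir, r$contamination[[dir]]$c, r$contamination[[dir]]$f_obs,
                r$contamination[[dir]]$n_genes))
  e <- r$enrichment_predicted_in_called
  cat(sprintf("  predicted-in-called-PEG enrichment: k = %d of n = %d (K = %d, N = %d), log10 p = %.2f\n",
              e$k, e$n, e$K, e$N, e$log10_p))
  invisible(x)
}
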