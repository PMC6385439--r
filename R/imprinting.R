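# Allele-specific expression imprinting caller for reciprocal-cross counts:
# informative-read filter, chi-square dosage test against the 2:1 endosperm
# expectation, BH-FDR, reciprocal MEG/PEG classification rules, and the
# seed-coat contamination estimator.

.merge_replicates <- function(counts) {
  agg <- stats::aggregate(cbind(maternal, paternal) ~ gene_id + direction,
                          data = counts, FUN = sum)
  agg[order(agg$gene_id, agg$direction), ]
}

#' Filter genes by informative read count
#'
#' A gene is testable when it has at least `min_reads` informative reads
#' (maternal + paternal) in every cross direction present in the table.
#'
#' @param counts Count `data.frame` (`gene_id`, `direction`, `maternal`,
#'   `paternal`); replicates, if present, must already be merged.
#' @param min_reads Minimum informative reads per direction (default 20).
#' @return The input with an added logical column `testable`.
#' @export
informative_filter <- function(counts, min_reads = 20L) {
  if (min_reads < 0) stop("`min_reads` must be >= 0", call. = FALSE)
  informative <- counts$maternal + counts$paternal
  ok_by_gene <- tapply(informative >= min_reads, counts$gene_id, all)
  counts$testable <- as.logical(ok_by_gene[counts$gene_id])
  counts
}

#' Chi-square goodness-of-fit test against the endosperm dosage ratio
#'
#' One-degree-of-freedom goodness-of-fit test of observed maternal/paternal
#' read counts against the expected split (2/3 maternal for the triploid
#' endosperm). No continuity correction is applied by default; a Yates
#' correction is available by flag.
#'
#' @param maternal,paternal Non-negative integer count vectors.
#' @param expected_maternal Expected maternal fraction (default 2/3).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A `data.frame` with `statistic` and `p_value`.
#' @examples
#' chisq_allelic_test(10, 20)  # statistic 15, p ~ 1.1e-4
#' @export
chisq_allelic_test <- function(maternal, paternal, expected_maternal = 2 / 3,
                               correct = FALSE) {
  n <- maternal + paternal
  if (any(n == 0))
    stop("zero informative reads: filter genes before testing", call. = FALSE)
  exp_m <- n * expected_maternal
  exp_p <- n * (1 - expected_maternal)
  dev_m <- abs(maternal - exp_m)
  dev_p <- abs(paternal - exp_p)
  if (correct) {
    dev_m <- pmax(0, dev_m - 0.5)
    dev_p <- pmax(0, dev_p - 0.5)
  }
  stat <- dev_m^2 / exp_m + dev_p^2 / exp_p
  data.frame(statistic = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement (as implemented by
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call imprinted genes from reciprocal-cross allele-specific counts
#'
#' Replicates are summed within each cross direction; genes with fewer than
#' `min_reads` informative reads in either direction are `not_testable`. For
#' testable genes a chi-square dosage test against the expected 2:1
#' maternal:paternal ratio is computed per direction and BH-adjusted per
#' direction over all testable genes. A gene is called `MEG` when its maternal
#' fraction is at least `meg_maternal` (default 0.85) in both directions,
#' `PEG` when its paternal fraction is at least `peg_paternal` (default 0.50)
#' in both directions, in each case with adjusted p below `fdr` (default
#' 0.01) in both directions; all other testable genes are `biallelic`.
#'
#' @param counts Count `data.frame` (`gene_id`, `direction`, `replicate`,
#'   `maternal`, `paternal`).
#' @param min_reads Informative-read threshold per direction (default 20).
#' @param fdr FDR-adjusted p-value threshold (default 0.01).
#' @param meg_maternal Minimum maternal fraction for a MEG (default 0.85).
#' @param peg_paternal Minimum paternal fraction for a PEG (default 0.50).
#' @param expected_maternal Expected maternal fraction under biallelic
#'   expression (default 2/3).
#' @param correct Yates correction for the chi-square test (default `FALSE`).
#' @return A `data.frame` with one row per gene: `gene_id`, `call`
#'   (`MEG`/`PEG`/`biallelic`/`not_testable`), and per-direction columns
#'   `informative_<dir>`, `maternal_fraction_<dir>`, `chi2_<dir>`, `p_<dir>`,
#'   `q_<dir>`.
#' @export
call_imprinting <- function(counts, min_reads = 20L, fdr = 0.01,
                            meg_maternal = 0.85, peg_paternal = 0.50,
                            expected_maternal = 2 / 3, correct = FALSE) {
  merged <- .merge_replicates(counts)
  merged <- informative_filter(merged, min_reads)
  directions <- sort(unique(merged$direction))
  genes <- sort(unique(merged$gene_id))

  res <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  stat_cols <- list()
  for (dir in directions) {
    d <- merged[merged$direction == dir, ]
    d <- d[match(genes, d$gene_id), ]
    informative <- d$maternal + d$paternal
    f <- ifelse(informative > 0, d$maternal / informative, NA_real_)
    chi2 <- p <- q <- rep(NA_real_, length(genes))
    test_idx <- which(d$testable)
    if (length(test_idx)) {
      ct <- chisq_allelic_test(d$maternal[test_idx], d$paternal[test_idx],
                               expected_maternal = expected_maternal,
                               correct = correct)
      chi2[test_idx] <- ct$statistic
      p[test_idx] <- ct$p_value
      q[test_idx] <- bh_fdr(ct$p_value)
    }
    stat_cols[[dir]] <- list(informative = informative, f = f,
                             chi2 = chi2, p = p, q = q,
                             testable = d$testable)
    res[[paste0("informative_", dir)]] <- informative
    res[[paste0("maternal_fraction_", dir)]] <- f
    res[[paste0("chi2_", dir)]] <- chi2
    res[[paste0("p_", dir)]] <- p
    res[[paste0("q_", dir)]] <- q
  }

  f_mat <- do.call(cbind, lapply(stat_cols, `[[`, "f"))
  q_mat <- do.call(cbind, lapply(stat_cols, `[[`, "q"))
  testable <- Reduce(`&`, lapply(stat_cols, `[[`, "testable"))
  testable[is.na(testable)] <- FALSE
  sig_all <- rowSums(q_mat < fdr) == length(directions)
  meg <- rowSums(f_mat >= meg_maternal) == length(directions) & sig_all
  peg <- rowSums((1 - f_mat) >= peg_paternal) == length(directions) & sig_all
  call <- rep("biallelic", length(genes))
  call[which(meg)] <- "MEG"
  call[which(peg)] <- "PEG"
  call[!testable] <- "not_testable"
  res$call <- call
  res[c("gene_id", "call", setdiff(names(res), c("gene_id", "call")))]
}

#' Estimate maternal seed-coat contamination from pooled counts
#'
#' Under the mixture model `f_obs = (1 - c) * 2/3 + c`, where `c` is the
#' proportion of reads from a purely maternal (seed-coat) source, the pooled
#' maternal read fraction of biallelically expressed genes inverts to
#' `c = 3 * f_obs - 2`, clamped to \[0, 1\]. The input should be restricted to
#' genes assumed biallelic; at genome scale the bias from a small imprinted
#' fraction is modest but real, so pass a biallelic set when one is known.
#'
#' @param counts Count `data.frame` (`gene_id`, `maternal`, `paternal`),
#'   typically one cross direction.
#' @param genes Optional character vector restricting the estimate to an
#'   assumed-biallelic gene set.
#' @return A list with `c` (estimated contamination), `f_obs` (pooled
#'   maternal fraction) and `n_genes`.
#' @examples
#' estimate_contamination(data.frame(gene_id = "g", maternal = 75, paternal = 25))
#' @export
estimate_contamination <- function(counts, genes = NULL) {
  if (!is.null(genes)) counts <- counts[counts$gene_id %in% genes, , drop = FALSE]
  m <- sum(as.numeric(counts$maternal))
  p <- sum(as.numeric(counts$paternal))
  if (m + p <= 0) stop("pooled informative reads must be positive", call. = FALSE)
  f_obs <- m / (m + p)
  list(c = min(max(3 * f_obs - 2, 0), 1),
       f_obs = f_obs,
       n_genes = length(unique(counts$gene_id)))
}
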