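# Weighted methylation levels per gene, sequence context, allele and cell
# type, computed from per-cytosine counts.

#' Per-gene weighted methylation levels
#'
#' For each gene and requested context, the weighted methylation level is the
#' total methylated read count divided by the total read count over all
#' cytosines of that context inside the gene body `[start, end)` — the
#' field-standard estimator, robust to coverage variation between sites. Genes
#' with no covered cytosine of a context get a missing level (never 0). Set
#' `weighted = FALSE` for the unweighted per-site mean of site-level
#' fractions instead.
#'
#' @param cytosines Methylation calls: `data.frame` with `chrom`, `pos`,
#'   `count_methylated`, `count_unmethylated`, `context` (see
#'   [read_cx_report()]).
#' @param genes Annotation `data.frame` (`gene_id`, `chrom`, `start`, `end`).
#' @param contexts Contexts to summarize (default `CG`, `CHG`, `CHH`).
#' @param weighted Use read-count weighting (default) or per-site means.
#' @param flank_bp Extend each gene interval by this many bp on both sides
#'   before overlap (default 0: annotated body only).
#' @return A `data.frame` with `gene_id`, `context`, `level`,
#'   `covered_cytosines`, `total_reads`; `level` is `NA` when `total_reads`
#'   is 0.
#' @examples
#' cx <- data.frame(chrom = "c", pos = c(10, 20),
#'                  count_methylated = c(2, 1), count_unmethylated = c(3, 4),
#'                  context = "CHG")
#' g <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 100)
#' gene_methylation_level(cx, g, contexts = "CHG")$level  # 3/10
#' @export
gene_methylation_level <- function(cytosines, genes,
                                   contexts = c("CG", "CHG", "CHH"),
                                   weighted = TRUE, flank_bp = 0) {
  if (any(cytosines$count_methylated < 0) || any(cytosines$count_unmethylated < 0) ||
      any(cytosines$count_methylated != round(cytosines$count_methylated)))
    stop("methylation counts must be non-negative integers", call. = FALSE)
  g <- genes
  g$start <- pmax(0, g$start - flank_bp)
  g$end <- g$end + flank_bp
  gene_gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1, end = g$end)
  )
  out <- lapply(contexts, function(ctx) {
    cx <- cytosines[cytosines$context == ctx, , drop = FALSE]
    lev <- rep(NA_real_, nrow(genes))
    nsite <- integer(nrow(genes))
    nread <- numeric(nrow(genes))
    if (nrow(cx)) {
      site_gr <- GenomicRanges::GRanges(
        seqnames = cx$chrom,
        ranges = IRanges::IRanges(start = cx$pos + 1, width = 1)
      )
      hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      tot_site <- cx$count_methylated[qi] + cx$count_unmethylated[qi]
      covered <- tot_site > 0
      nsite_t <- tapply(covered, si, sum)
      nread_t <- tapply(tot_site, si, sum)
      idx <- as.integer(names(nread_t))
      nsite[idx] <- as.integer(nsite_t)
      nread[idx] <- as.numeric(nread_t)
      if (weighted) {
        meth_t <- tapply(cx$count_methylated[qi], si, sum)
        lev[idx] <- ifelse(nread_t > 0, as.numeric(meth_t) / as.numeric(nread_t),
                           NA_real_)
      } else {
        frac <- ifelse(covered, cx$count_methylated[qi] / tot_site, NA_real_)
        mfrac <- tapply(frac, si, mean, na.rm = TRUE)
        lev[idx] <- ifelse(nsite_t > 0, as.numeric(mfrac), NA_real_)
      }
    }
    data.frame(gene_id = genes$gene_id, context = ctx, level = lev,
               covered_cytosines = nsite, total_reads = nread,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Methylation-level table across sources
#'
#' Applies [gene_methylation_level()] to a named list of per-source (cell
#' type / allele / genotype) methylation call tables and stacks the results.
#'
#' @param cytosines_by_source Named list of methylation call `data.frame`s.
#' @param genes Annotation `data.frame`.
#' @inheritParams gene_methylation_level
#' @return A `data.frame` with `gene_id`, `context`, `source`, `level`,
#'   `covered_cytosines`, `total_reads`.
#' @export
methylation_table <- function(cytosines_by_source, genes,
                              contexts = c("CG", "CHG", "CHH"),
                              weighted = TRUE, flank_bp = 0) {
  stopifnot(!is.null(names(cytosines_by_source)))
  out <- lapply(names(cytosines_by_source), function(src) {
    d <- gene_methylation_level(cytosines_by_source[[src]], genes,
                                contexts = contexts, weighted = weighted,
                                flank_bp = flank_bp)
    d$source <- src
    d
  })
  res <- do.call(rbind, out)
  res[c("gene_id", "context", "source", "level", "covered_cytosines",
        "total_reads")]
}

#' Maternal-paternal methylation level difference
#'
#' @param level_mat,level_pat Numeric vectors of methylation levels in
#'   \[0, 1\]; recycled to common length.
#' @return `level_mat - level_pat` in \[-1, 1\]; `NA` where either level is
#'   missing.
#' @export
allelic_level_difference <- function(level_mat, level_pat) {
  if (any(level_mat < 0 | level_mat > 1, na.rm = TRUE) ||
      any(level_pat < 0 | level_pat > 1, na.rm = TRUE))
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  level_mat - level_pat
}
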