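# Readers and writers for the standard formats at the package boundary.
# Internally every coordinate is 0-based half-open; GFF3 (1-based closed) and
# GRanges are converted at the boundary.

.genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = if ("strand" %in% names(genes)) genes$strand else "*",
    gene_id = genes$gene_id
  )
}

#' Read a gene annotation from GFF3 or BED
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or BED file.
#' @param feature_type For GFF3, the feature type to keep (default `"gene"`;
#'   `NULL` keeps all records).
#' @return A `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   in 0-based half-open coordinates.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
        else if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
        else if ("name" %in% names(mc)) as.character(mc$name)
        else sprintf("gene%05d", seq_along(gr))
  data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write a gene annotation as GFF3
#'
#' @param genes Annotation `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- .genes_to_granges(genes)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "endosign"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file.
#' @return A `data.frame` with `chrom`, `start`, `end`, `value` (0-based
#'   half-open intervals, value constant over each interval).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$score,
    stringsAsFactors = FALSE
  )
}

#' Write a coverage or score track as bedGraph
#'
#' Missing values (`NA`) are dropped on output, matching bedGraph semantics
#' where uncovered intervals are simply absent.
#'
#' @param track A `data.frame` with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  track <- track[is.finite(track$value), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read per-cytosine methylation calls (CX-report-style TSV)
#'
#' Expects a tab-separated file with columns `chrom`, `pos`, `strand`,
#' `count_methylated`, `count_unmethylated`, `context` (header optional; a
#' headerless file is assumed to be in that column order).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with those six columns.
#' @export
read_cx_report <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header)
    names(df) <- c("chrom", "pos", "strand", "count_methylated",
                   "count_unmethylated", "context")
  required <- c("chrom", "pos", "strand", "count_methylated",
                "count_unmethylated", "context")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("methylation table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df[required]
}

#' Read an allele-specific count table
#'
#' @param path Tab-separated file with columns `gene_id`, `direction`,
#'   `replicate`, `maternal`, `paternal`.
#' @return A `data.frame` with those columns.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "direction", "maternal", "paternal")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("count table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(df$maternal < 0) || any(df$paternal < 0) ||
      any(df$maternal != round(df$maternal)) || any(df$paternal != round(df$paternal)))
    stop("read counts must be non-negative integers", call. = FALSE)
  df
}
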