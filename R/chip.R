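# Allele-resolved ChIP signal processing: H3-normalized log2 ratios in
# fixed-width bins, z-score standardization, per-gene body z-scores, and
# metagene profiles.

.track_chrom_values <- function(track) {
  # split a bin_track into per-chromosome value vectors ordered by bin start
  sp <- split(track[c("start", "value")], track$chrom)
  lapply(sp, function(d) d$value[order(d$start)])
}

.coverage_rle <- function(cov, chrom, len) {
  d <- cov[cov$chrom == chrom, , drop = FALSE]
  ir <- IRanges::IRanges(start = d$start + 1, end = d$end)
  IRanges::coverage(ir, weight = d$value, width = len)
}

#' H3-normalized log2-ratio track in fixed-width bins
#'
#' Averages raw ChIP and H3-control coverage in fixed-width bins and computes
#' `log2((chip + pseudocount) / (control + pseudocount))` per bin. Bins in
#' which both signals are zero carry no information and are marked missing
#' (`NA`), never zero.
#'
#' @param chip,control Coverage `data.frame`s (`chrom`, `start`, `end`,
#'   `value`; 0-based half-open bedGraph semantics). Chromosome sets must
#'   match.
#' @param bin_width Bin width in bp (default 150).
#' @param pseudocount Pseudocount added to both coverages (default 1
#'   read-equivalent; avoids infinite ratios and is symmetric between
#'   numerator and denominator).
#' @return A `bin_track`: `data.frame` with `chrom`, `start`, `end`, `value`
#'   plus attributes `bin_width` and `zscored = FALSE`.
#' @examples
#' chip <- data.frame(chrom = "c", start = 0, end = 150, value = 5)
#' ctrl <- data.frame(chrom = "c", start = 0, end = 150, value = 3)
#' bin_log_ratio(chip, ctrl)$value  # log2(6/4)
#' @export
bin_log_ratio <- function(chip, control, bin_width = 150L, pseudocount = 1) {
  if (bin_width < 1) stop("`bin_width` must be >= 1", call. = FALSE)
  chroms_chip <- unique(chip$chrom)
  chroms_ctrl <- unique(control$chrom)
  if (!setequal(chroms_chip, chroms_ctrl))
    stop("chromosome sets differ between ChIP and control; only in ChIP: {",
         paste(setdiff(chroms_chip, chroms_ctrl), collapse = ", "),
         "}; only in control: {",
         paste(setdiff(chroms_ctrl, chroms_chip), collapse = ", "), "}",
         call. = FALSE)
  out <- lapply(sort(chroms_chip), function(chrom) {
    len <- max(chip$end[chip$chrom == chrom], control$end[control$chrom == chrom])
    n_bins <- as.integer(ceiling(len / bin_width))
    bins <- IRanges::IRanges(
      start = (seq_len(n_bins) - 1L) * bin_width + 1L,
      end = pmin(seq_len(n_bins) * bin_width, len)
    )
    m_chip <- IRanges::viewMeans(IRanges::Views(.coverage_rle(chip, chrom, len), bins))
    m_ctrl <- IRanges::viewMeans(IRanges::Views(.coverage_rle(control, chrom, len), bins))
    val <- log2((m_chip + pseudocount) / (m_ctrl + pseudocount))
    val[m_chip == 0 & m_ctrl == 0] <- NA_real_
    data.frame(chrom = chrom, start = IRanges::start(bins) - 1,
               end = IRanges::end(bins), value = as.numeric(val),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, bin_width = as.integer(bin_width), zscored = FALSE,
            class = c("bin_track", "data.frame"))
}

#' Z-score standardization of a binned track
#'
#' Standardizes the finite bin values to mean 0, standard deviation 1, using
#' the population-sd convention (`sqrt(mean((x - mean(x))^2))`). Missing bins
#' stay missing. By default the transformation is genome-wide; set
#' `per_chromosome = TRUE` to standardize each chromosome separately.
#'
#' @param track A `bin_track` (or any `data.frame` with `chrom`, `value`).
#' @param per_chromosome Standardize within each chromosome instead of
#'   genome-wide.
#' @return The track with `value` replaced by z-scores; attribute
#'   `zscored = TRUE` and `sd_convention = "population"`.
#' @export
zscore_track <- function(track, per_chromosome = FALSE) {
  zs <- function(x) {
    fin <- is.finite(x)
    if (sum(fin) < 2L)
      stop("z-score transformation needs at least 2 finite bins", call. = FALSE)
    mu <- mean(x[fin])
    sd_pop <- sqrt(mean((x[fin] - mu)^2))
    if (sd_pop == 0) {
      warning("constant track: standard deviation is 0, all z-scores set to 0",
              call. = FALSE)
      x[fin] <- 0
    } else {
      x[fin] <- (x[fin] - mu) / sd_pop
    }
    x
  }
  if (per_chromosome) {
    for (chrom in unique(track$chrom)) {
      sel <- track$chrom == chrom
      track$value[sel] <- zs(track$value[sel])
    }
  } else {
    track$value <- zs(track$value)
  }
  attr(track, "zscored") <- TRUE
  attr(track, "sd_convention") <- "population"
  track
}

#' Per-gene mean z-score over the gene body
#'
#' The gene z-score is the unweighted mean of the bin values of all bins
#' overlapping `[start, end)`; bins straddling a gene boundary count fully.
#' Genes with no finite overlapping bin get `NA` and are flagged
#' `not_scorable`.
#'
#' @param track A z-scored `bin_track`.
#' @param genes Annotation `data.frame` (`gene_id`, `chrom`, `start`, `end`).
#' @return A `data.frame` with `gene_id`, `z`, `n_bins` (finite bins used) and
#'   `not_scorable`.
#' @export
gene_zscore <- function(track, genes) {
  w <- attr(track, "bin_width")
  if (is.null(w)) {
    widths <- unique(track$end - track$start)
    w <- max(widths)
  }
  by_chrom <- .track_chrom_values(track)
  z <- rep(NA_real_, nrow(genes))
  n_bins <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    vals <- by_chrom[[genes$chrom[i]]]
    if (is.null(vals)) next
    i0 <- max(1L, floor(genes$start[i] / w) + 1L)
    i1 <- min(length(vals), as.integer(ceiling(genes$end[i] / w)))
    if (i1 < i0) next
    v <- vals[i0:i1]
    v <- v[is.finite(v)]
    n_bins[i] <- length(v)
    if (length(v)) z[i] <- mean(v)
  }
  data.frame(gene_id = genes$gene_id, z = z, n_bins = n_bins,
             not_scorable = !is.finite(z), stringsAsFactors = FALSE)
}

.interval_mean <- function(vals, w, a, b) {
  # overlap-weighted mean of bin values over the bp interval [a, b),
  # ignoring missing bins; NA when nothing finite overlaps
  lim <- length(vals) * w
  if (b <= 0 || a >= lim) return(NA_real_)
  a <- max(a, 0); b <- min(b, lim)
  if (b <= a) return(NA_real_)
  i0 <- floor(a / w) + 1
  i1 <- ceiling(b / w)
  idx <- i0:i1
  ov <- pmin(idx * w, b) - pmax((idx - 1) * w, a)
  v <- vals[idx]
  keep <- is.finite(v) & ov > 0
  if (!any(keep)) return(NA_real_)
  sum(v[keep] * ov[keep]) / sum(ov[keep])
}

#' Metagene profile over gene bodies and flanks
#'
#' Averages a binned track over genes aligned at their transcriptional start
#' and stop: `flank_bp / flank_bin_bp` fixed-width bins upstream of the start,
#' `body_bins` equal-length bins across the body, and the same number of
#' fixed-width bins downstream (80 positions for the 2-kb / 100-bp / 40-bin
#' defaults). Minus-strand genes are orientation-flipped before averaging.
#' Profile means ignore missing bins; the number of genes contributing a
#' finite value is recorded per position. Genes shorter than `body_bins` bp
#' are skipped (with a message).
#'
#' @param track A `bin_track` (typically z-scored).
#' @param genes Annotation `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param flank_bp Flank extent in bp (default 2000).
#' @param flank_bin_bp Flank bin width in bp (default 100); must divide
#'   `flank_bp`.
#' @param body_bins Number of equal-length body bins (default 40).
#' @return A `data.frame` with `position` (1-based index), `zone`
#'   (`upstream`/`body`/`downstream`), `mean_value` and `n_genes`.
#' @export
metagene_profile <- function(track, genes, flank_bp = 2000L,
                             flank_bin_bp = 100L, body_bins = 40L) {
  if (nrow(genes) == 0) stop("`genes` must be non-empty", call. = FALSE)
  if (flank_bp %% flank_bin_bp != 0)
    stop("`flank_bp` must be divisible by `flank_bin_bp`", call. = FALSE)
  w <- attr(track, "bin_width")
  if (is.null(w)) w <- max(track$end - track$start)
  by_chrom <- .track_chrom_values(track)
  n_flank <- as.integer(flank_bp / flank_bin_bp)
  n_pos <- 2L * n_flank + body_bins

  too_short <- (genes$end - genes$start) < body_bins
  if (any(too_short)) {
    message(sum(too_short), " gene(s) shorter than ", body_bins,
            " bp skipped in metagene profile")
    genes <- genes[!too_short, , drop = FALSE]
  }
  sums <- numeric(n_pos)
  counts <- integer(n_pos)
  for (i in seq_len(nrow(genes))) {
    vals <- by_chrom[[genes$chrom[i]]]
    if (is.null(vals)) next
    s <- genes$start[i]; e <- genes$end[i]
    up <- cbind(s - flank_bp + (seq_len(n_flank) - 1L) * flank_bin_bp,
                s - flank_bp + seq_len(n_flank) * flank_bin_bp)
    bb <- s + (e - s) * (0:body_bins) / body_bins
    body <- cbind(bb[-length(bb)], bb[-1])
    down <- cbind(e + (seq_len(n_flank) - 1L) * flank_bin_bp,
                  e + seq_len(n_flank) * flank_bin_bp)
    ivs <- rbind(up, body, down)
    if (identical(genes$strand[i], "-")) ivs <- ivs[rev(seq_len(n_pos)), , drop = FALSE]
    for (k in seq_len(n_pos)) {
      m <- .interval_mean(vals, w, ivs[k, 1], ivs[k, 2])
      if (is.finite(m)) {
        sums[k] <- sums[k] + m
        counts[k] <- counts[k] + 1L
      }
    }
  }
  mean_value <- ifelse(counts > 0, sums / counts, NA_real_)
  data.frame(
    position = seq_len(n_pos),
    zone = rep(c("upstream", "body", "downstream"),
               c(n_flank, body_bins, n_flank)),
    mean_value = mean_value,
    n_genes = counts,
    stringsAsFactors = FALSE
  )
}
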