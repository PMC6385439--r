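# Discrete epigenetic scoring: per-mark levels 0..L from breakpoints, the
# combined 0..3L score (0-12 with the default L = 4), and the maximum-score
# PEG prediction set.

#' Discretize mark values into levels
#'
#' A value's level is the number of breakpoints at or below it (closed-left: a
#' value equal to a breakpoint counts as at/above it). Missing values map to
#' level 0.
#'
#' @param value Numeric vector of mark values (gene z-scores or methylation
#'   levels).
#' @param breakpoints Strictly ascending numeric vector of length `L`.
#' @return Integer levels in `0..L`.
#' @examples
#' level_bin(c(0.1, 30, 76, NA), stats::quantile(1:100, c(.25, .5, .75)))
#' @export
level_bin <- function(value, breakpoints) {
  if (length(breakpoints) < 1 || any(diff(breakpoints) <= 0))
    stop("configuration error: `breakpoints` must be strictly ascending",
         call. = FALSE)
  lev <- findInterval(value, breakpoints)  # counts breakpoints <= value
  lev[!is.finite(value)] <- 0L
  as.integer(lev)
}

#' Presence-plus-quartile breakpoints for mark scoring
#'
#' Builds the default 4-breakpoint scheme: the first breakpoint is the
#' presence threshold (values below it score 0 = mark absent); the remaining
#' three are the quartiles of the values at or above the presence threshold,
#' so present genes are split into levels 1-4. Degenerate inputs (fewer than
#' 4 distinct present values) fall back to evenly spaced breakpoints above the
#' presence threshold.
#'
#' @param values Numeric mark values over genes (non-finite ignored).
#' @param presence Presence threshold (e.g. `1` for z-scores, `0.2` for
#'   methylation levels).
#' @return Strictly ascending numeric vector of length 4 for [level_bin()].
#' @export
score_breakpoints <- function(values, presence) {
  present <- values[is.finite(values) & values >= presence]
  q <- if (length(present) >= 4)
    unname(stats::quantile(present, c(0.25, 0.5, 0.75))) else numeric(0)
  bp <- c(presence, q)
  if (any(diff(bp) <= 0) || length(bp) < 4) {
    span <- if (length(present)) max(present) - presence else 1
    if (span <= 0) span <- 1
    bp <- presence + span * (0:3) / 4
  }
  bp
}

#' Combine per-mark levels into the epigenetic score
#'
#' The combined score is the sum of the three per-mark levels (central-cell
#' CHG methylation, maternal H3K27me3, maternal H3K9me2), each in `0..L`.
#' With the default `L = 4` the score ranges 0-12 and the maximum category is
#' score 12.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param level_chg_cc,level_k27_mat,level_k9_mat Integer levels in `0..L`.
#' @param n_levels Maximum per-mark level `L` (default 4).
#' @return A `data.frame` with `gene_id`, the three levels, `score`,
#'   `category` (equal to the score) and `is_max_category`.
#' @examples
#' combined_score("g1", 4, 4, 4)$is_max_category
#' @export
combined_score <- function(gene_id, level_chg_cc, level_k27_mat, level_k9_mat,
                           n_levels = 4L) {
  levs <- cbind(level_chg_cc, level_k27_mat, level_k9_mat)
  if (any(levs < 0 | levs > n_levels | levs != round(levs)))
    stop("levels must be integers in 0..", n_levels, call. = FALSE)
  score <- as.integer(level_chg_cc + level_k27_mat + level_k9_mat)
  data.frame(
    gene_id = gene_id,
    level_chg_cc = as.integer(level_chg_cc),
    level_k27_mat = as.integer(level_k27_mat),
    level_k9_mat = as.integer(level_k9_mat),
    score = score,
    category = score,
    is_max_category = score == 3L * n_levels,
    stringsAsFactors = FALSE
  )
}

#' Flag genes carrying a mark exclusively on the maternal allele
#'
#' A gene is maternal-specific for a mark when its maternal-allele z-score
#' reaches the presence threshold while the paternal-allele z-score does not.
#' Missing paternal z-scores are treated as below threshold (the number of
#' such genes is reported with a message).
#'
#' @param z_mat,z_pat Numeric vectors of per-gene maternal and paternal
#'   z-scores.
#' @param threshold Presence threshold (default 1).
#' @return Logical vector: `TRUE` where the mark is maternal-specific.
#' @export
maternal_specific_filter <- function(z_mat, z_pat, threshold = 1) {
  n_missing <- sum(!is.finite(z_pat))
  if (n_missing > 0)
    message(n_missing, " gene(s) with missing paternal z-score treated as unmarked")
  pat <- ifelse(is.finite(z_pat), z_pat, -Inf)
  mat <- ifelse(is.finite(z_mat), z_mat, -Inf)
  mat >= threshold & pat < threshold
}

#' Predict PEGs from the epigenetic score
#'
#' The prediction set is the maximum-score category (score 12 under the
#' default scheme): genes whose maternal alleles carry the highest level of
#' all three repressive marks.
#'
#' @param scores Output of [combined_score()] / [epigenetic_scores()].
#' @return Sorted character vector of predicted PEG gene ids.
#' @export
predict_pegs <- function(scores) {
  sort(scores$gene_id[scores$is_max_category])
}

#' Score genes from mark values
#'
#' Convenience wrapper: derives breakpoints for each mark with
#' [score_breakpoints()] (unless supplied), discretizes with [level_bin()]
#' and combines with [combined_score()].
#'
#' @param gene_id Character vector of gene ids.
#' @param chg_cc Central-cell CHG methylation level per gene (\[0, 1\]).
#' @param k27_mat,k9_mat Maternal-allele gene z-scores for H3K27me3 and
#'   H3K9me2.
#' @param presence_z Presence threshold for the histone z-scores (default 1).
#' @param presence_meth Presence threshold for the methylation level
#'   (default 0.2).
#' @param breakpoints Optional named list (`chg_cc`, `k27_mat`, `k9_mat`) of
#'   breakpoint vectors overriding the derived ones (e.g. to reproduce an
#'   externally defined scoring table).
#' @param n_levels Maximum per-mark level (default 4).
#' @return A `data.frame` as from [combined_score()], with the breakpoints
#'   used attached as attribute `breakpoints`.
#' @export
epigenetic_scores <- function(gene_id, chg_cc, k27_mat, k9_mat,
                              presence_z = 1, presence_meth = 0.2,
                              breakpoints = NULL, n_levels = 4L) {
  bp <- list(
    chg_cc = if (!is.null(breakpoints$chg_cc)) breakpoints$chg_cc
             else score_breakpoints(chg_cc, presence_meth),
    k27_mat = if (!is.null(breakpoints$k27_mat)) breakpoints$k27_mat
              else score_breakpoints(k27_mat, presence_z),
    k9_mat = if (!is.null(breakpoints$k9_mat)) breakpoints$k9_mat
             else score_breakpoints(k9_mat, presence_z)
  )
  res <- combined_score(
    gene_id,
    level_bin(chg_cc, bp$chg_cc),
    level_bin(k27_mat, bp$k27_mat),
    level_bin(k9_mat, bp$k9_mat),
    n_levels = n_levels
  )
  attr(res, "breakpoints") <- bp
  res
}
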