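# Over-representation and distribution-comparison statistics: upper-tail
# hypergeometric enrichment (log-space), per-category 2x2 composition tests,
# an exact/approximate Wilcoxon rank-sum test, and expression-bias profiles.

#' Hypergeometric gene-set enrichment (upper tail)
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` category members among `n` draws without
#' replacement from a population of `N` genes of which `K` are in the
#' category. Computed in log space for numerical stability; the returned
#' `p_value` is never printed as exactly zero because `log10_p` carries the
#' full precision.
#'
#' @param N Population size.
#' @param K Category size within the population.
#' @param n Number of draws (size of the test set).
#' @param k Observed overlap.
#' @return A `data.frame` with `N`, `K`, `n`, `k`, `p_value`, `log10_p`.
#' @examples
#' hypergeom_enrichment(10, 5, 5, 5)$p_value  # 1 / choose(10, 5)
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  bad <- k > pmin(K, n) | K > N | n > N | k < 0 | K < 0 | n < 0
  if (any(bad))
    stop("inconsistent counts: require 0 <= k <= min(K, n) <= N", call. = FALSE)
  log_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  data.frame(N = N, K = K, n = n, k = k,
             p_value = exp(log_p),
             log10_p = log_p / log(10))
}

#' Per-category composition test against a reference category
#'
#' For each category, tests whether its class composition (e.g. fraction of
#' PEGs) differs from a reference category via a 1-df chi-square test on the
#' 2x2 table `[(k, n - k), (k_ref, n_ref - k_ref)]` without continuity
#' correction. When any expected cell is below 1 the exact hypergeometric
#' (Fisher) p-value is substituted and flagged in the `method` column.
#'
#' @param k,n Class count and total per category (vectors).
#' @param k_ref,n_ref Class count and total of the reference category.
#' @return A `data.frame` with `k`, `n`, `statistic`, `p_value`, `method`.
#' @export
category_composition_test <- function(k, n, k_ref, n_ref) {
  if (any(k > n) || k_ref > n_ref || any(c(k, n, k_ref, n_ref) < 0))
    stop("require 0 <= k <= n for every category", call. = FALSE)
  out <- lapply(seq_along(k), function(i) {
    if (n[i] == 0)
      return(data.frame(k = k[i], n = 0L, statistic = NA_real_,
                        p_value = NA_real_, method = "empty"))
    tab <- matrix(c(k[i], n[i] - k[i], k_ref, n_ref - k_ref),
                  nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      message("category ", i, ": expected cell below 1, using exact test")
      p <- stats::fisher.test(tab)$p.value
      return(data.frame(k = k[i], n = n[i], statistic = NA_real_,
                        p_value = p, method = "fisher_exact"))
    }
    stat <- sum((tab - expected)^2 / expected)
    data.frame(k = k[i], n = n[i], statistic = stat,
               p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               method = "chisq")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.wilcox_exact_p <- function(x, y, alternative) {
  # permutation enumeration of the rank-sum statistic (midranks handle ties)
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(N, nx)
  w_all <- colSums(matrix(r[combs], nrow = nx))
  tol <- 1e-8
  p_le <- mean(w_all <= w_obs + tol)
  p_ge <- mean(w_all >= w_obs - tol)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

.wilcox_normal_p <- function(x, y, alternative) {
  # normal approximation with tie correction, no continuity correction
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  switch(alternative,
         less = stats::pnorm(z),
         greater = stats::pnorm(z, lower.tail = FALSE),
         two.sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test comparing the distributions of `x` and `y`. For
#' small samples (`length(x) + length(y) <= exact_limit`, default 12) the
#' p-value is computed by exact enumeration of all rank assignments (midranks
#' handle ties); larger samples use the normal approximation with tie
#' correction and no continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to the location of `x` relative to `y`).
#' @param exact_limit Maximum combined sample size for exact enumeration.
#' @return A list with `p_value`, `method` and the rank-sum `statistic` of
#'   `x`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p_value  # exact two-sided: 0.1
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  exact <- length(x) + length(y) <= exact_limit
  p <- if (exact) .wilcox_exact_p(x, y, alternative)
       else .wilcox_normal_p(x, y, alternative)
  list(p_value = p,
       method = if (exact) "exact_enumeration" else "normal_tie_corrected",
       statistic = sum(rank(c(x, y))[seq_along(x)]))
}

#' Mean mark levels by expression-bias bin
#'
#' Groups genes into bins of maternal read fraction and reports, per bin and
#' allele, the unweighted mean mark value and the gene count; empty bins are
#' reported with missing means. The bin edges must cover \[0, 1\]; the last
#' bin is closed on the right.
#'
#' @param mark_values `data.frame` with `gene_id`, `allele`, `value`.
#' @param maternal_fraction Named numeric vector (names = gene ids) of
#'   maternal read fractions in \[0, 1\].
#' @param edges Ascending bin edges covering \[0, 1\] (default deciles).
#' @return A `data.frame` with `bin`, `bin_low`, `bin_high`, `allele`,
#'   `mean_value`, `n_genes`.
#' @export
bias_profile <- function(mark_values, maternal_fraction,
                         edges = seq(0, 1, by = 0.1)) {
  if (edges[1] != 0 || edges[length(edges)] != 1 || any(diff(edges) <= 0))
    stop("configuration error: bin edges must ascend from 0 to 1", call. = FALSE)
  f <- maternal_fraction[mark_values$gene_id]
  keep <- is.finite(f) & is.finite(mark_values$value)
  mv <- mark_values[keep, , drop = FALSE]
  f <- f[keep]
  bin <- findInterval(f, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1L
  alleles <- sort(unique(mark_values$allele))
  grid <- expand.grid(bin = seq_len(n_bins), allele = alleles,
                      stringsAsFactors = FALSE)
  grid$bin_low <- edges[grid$bin]
  grid$bin_high <- edges[grid$bin + 1L]
  grid$mean_value <- NA_real_
  grid$n_genes <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- bin == grid$bin[i] & mv$allele == grid$allele[i]
    grid$n_genes[i] <- sum(sel)
    if (any(sel)) grid$mean_value[i] <- mean(mv$value[sel])
  }
  grid[c("bin", "bin_low", "bin_high", "allele", "mean_value", "n_genes")]
}
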