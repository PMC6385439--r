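# Shared fixtures: small simulation configs and independent oracle
# implementations used to cross-check the package's statistics.

small_config <- function(..., n_genes = 40, chrom_length = 4e5, seed = 42) {
  sim_config(n_genes = n_genes, chrom_length = chrom_length, seed = seed, ...)
}

# Upper-tail hypergeometric by direct combinatorial summation (oracle)
hyper_upper_oracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# BH step-up by the definition q_(i) = min_{j >= i} p_(j) * m / j (oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact rank-sum tail probabilities by full permutation enumeration (oracle)
wilcox_perm_oracle <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  sums <- combn(N, nx, FUN = function(idx) sum(r[idx]))
  p_le <- mean(sums <= w_obs + 1e-8)
  p_ge <- mean(sums >= w_obs - 1e-8)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# bp-resolution brute-force mean of a bin track over [a, b) (oracle)
per_bp_mean_oracle <- function(track, a, b) {
  w <- track$end - track$start
  v <- rep(track$value, w)
  seg <- v[(a + 1):b]
  if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
}

make_track <- function(values, bin_width = 150, chrom = "chr1") {
  n <- length(values)
  structure(
    data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin_width,
               end = seq_len(n) * bin_width, value = values,
               stringsAsFactors = FALSE),
    bin_width = as.integer(bin_width), class = c("bin_track", "data.frame")
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
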