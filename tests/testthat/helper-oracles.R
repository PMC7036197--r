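# Brute-force oracles and small fixtures shared across the suite.

# O(n * w) double-loop boundary score: mean of the w bins right of edge e
# minus mean of the w bins left of it, unmasked bins only; NA when either
# side has fewer than w / 2 unmasked bins.
brute_boundary_scores <- function(b, mask, w) {
  n <- length(b)
  out <- rep(NA_real_, max(n - 1, 0))
  if (n < 2 * w) return(out)
  for (e in seq_len(n - 1)) {
    left <- max(1, e - w + 1):e
    right <- (e + 1):min(n, e + w)
    lv <- b[left][mask[left]]
    rv <- b[right][mask[right]]
    if (length(lv) >= w / 2 && length(rv) >= w / 2)
      out[e] <- mean(rv) - mean(lv)
  }
  out
}

# Exact one-sided P(U <= u_obs) by enumerating every assignment of the
# pooled values to the x group (no ties assumed).
brute_mw_p_less <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(n))
  combs <- utils::combn(length(pooled), n)
  mean(apply(combs, 2, u_of) <= u_obs)
}

# Rank-average quantile normalization oracle written as an explicit loop
# over rank positions (independent of the package's vectorized path).
qn_oracle <- function(cols) {
  sorted <- sapply(cols, sort)
  m <- rowMeans(sorted)
  lapply(cols, function(x) {
    xs <- sort(x)
    vapply(x, function(xi) mean(m[which(xs == xi)]), 0)
  })
}

# A small genome for fast end-to-end runs.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(chrom_lengths = c(20e6, 20e6), seed = seed, ...)
}

# One-chromosome binarized track from a +/-1 vector.
pm_track <- function(b, mask = NULL, bin_size = 10000) {
  binned_track(list(chr1 = as.numeric(b)), bin_size,
               mask = if (is.null(mask)) NULL else list(chr1 = mask))
}

# Dense single-chromosome contact matrix with alternating 20-bin
# domains and continuous values (tie-free mean curves).
dense_toy_matrix <- function(n = 120, seed = 42, flat = FALSE) {
  set.seed(seed)
  bs <- 1e4
  bins <- data.frame(chrom = "chr1", start = (0:(n - 1)) * bs,
                     end = (1:n) * bs, bin_id = 0:(n - 1))
  k <- n / 40
  dom <- domain_set(data.frame(
    chrom = "chr1", start = seq(0, n - 20, 20) * bs,
    end = seq(20, n, 20) * bs,
    state = rep(c("condensed", "decondensed"), n / 40),
    proportion = 1))
  pairs <- t(utils::combn(n, 2))
  value <- if (flat) 5 / (pairs[, 2] - pairs[, 1]) else
    stats::runif(nrow(pairs), 1, 10) / (pairs[, 2] - pairs[, 1])
  cm <- contact_matrix(bins, data.frame(i = pairs[, 1], j = pairs[, 2],
                                        value = value), bs)
  list(matrix = cm, domains = dom)
}

entry_key <- function(m) paste(m$entries$i, m$entries$j)

sorted_entry_values <- function(m) m$entries$value[order(entry_key(m))]
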