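#' Classify matrix bins and entries by domain state
#'
#' A bin overlapping condensed domains by more than half its length is
#' `C`, more than half decondensed is `D`, otherwise `other`. An entry
#' is `CC` when both bins are `C`, `DD` when both are `D`, otherwise
#' `OTHER` (mixed, ambiguous and trans pairs are never touched by
#' DiSCO).
#'
#' @param matrix A [contact_matrix()].
#' @param domains A [domain_set()] on the same genome.
#' @return List with `bin_class` (character per bin) and `entry_class`
#'   (character per entry).
#' @export
classify_pairs <- function(matrix, domains) {
  stopifnot(inherits(matrix, "contact_matrix"),
            inherits(domains, "domain_set"))
  chroms <- unique(matrix$bins$chrom)
  if (!all(unique(domains$chrom) %in% chroms))
    stop("domain set names chromosomes absent from the matrix bin table")
  chrom_lengths <- vapply(chroms, function(ch)
    max(matrix$bins$end[matrix$bins$chrom == ch]), 0)
  for (ch in unique(domains$chrom))
    if (max(domains$end[domains$chrom == ch]) > chrom_lengths[[ch]] ||
        any(domains$start[domains$chrom == ch] %% 1 != 0))
      stop("domain set does not fit the matrix bin grid")
  st <- domain_bin_states(domains, matrix$resolution, chrom_lengths)
  bin_class <- unlist(st[chroms], use.names = FALSE)
  ci <- bin_class[matrix$entries$i]
  cj <- bin_class[matrix$entries$j]
  same_chrom <- matrix$bins$chrom[matrix$entries$i] ==
    matrix$bins$chrom[matrix$entries$j]
  entry_class <- rep("OTHER", nrow(matrix$entries))
  entry_class[same_chrom & ci == "C" & cj == "C"] <- "CC"
  entry_class[same_chrom & ci == "D" & cj == "D"] <- "DD"
  list(bin_class = bin_class, entry_class = entry_class)
}

# Number of within-class bin pairs at each separation k = 1..kmax,
# summed over chromosomes, via FFT cross-correlation of the class
# indicator (exact after rounding).
class_pair_counts <- function(bins, bin_class, key, kmax) {
  counts <- numeric(kmax)
  for (ch in unique(bins$chrom)) {
    sel <- bins$chrom == ch
    c01 <- as.numeric(bin_class[sel] == key)
    n <- length(c01)
    if (n < 2 || sum(c01) < 2) next
    cc <- stats::convolve(c01, c01, type = "open")
    kk <- seq_len(min(n - 1, kmax))
    counts[kk] <- counts[kk] + round(cc[n + kk])
  }
  counts
}

# Per-separation count and stored-entry sum for one class. Absent
# (unstored, zero) pairs between classified bins count as zeros, so
# mean = sum / count.
class_profile <- function(matrix, classes, key, kmax) {
  counts <- class_pair_counts(matrix$bins, classes$bin_class,
                              substr(key, 1, 1), kmax)
  sums <- numeric(kmax)
  sel <- classes$entry_class == key
  if (any(sel)) {
    k <- matrix$entries$j[sel] - matrix$entries$i[sel]
    ok <- k >= 1 & k <= kmax
    acc <- rowsum(matrix$entries$value[sel][ok], k[ok])
    sums[as.integer(rownames(acc))] <- acc[, 1]
  }
  list(count = counts, sum = sums)
}

max_separation <- function(matrix, max_dist) {
  nb <- table(matrix$bins$chrom)
  min(floor(max_dist / matrix$resolution), max(nb) - 1)
}

#' Mean interaction frequency versus genomic distance for one class
#'
#' For each separation `s = k * resolution` up to `max_dist`, the mean
#' interaction frequency of all same-class cis bin pairs at that
#' separation. Pairs with no stored entry count as zeros, so the mean
#' does not depend on sparse-storage details.
#'
#' @param matrix A [contact_matrix()].
#' @param classes Output of [classify_pairs()] (or a [domain_set()],
#'   classified on the fly).
#' @param class `"CC"` or `"DD"`.
#' @param max_dist Largest separation considered, in bp.
#' @return A data.frame of class `distance_profile` with columns `s`
#'   (bp), `mean` (`NA` where no pair exists) and `count` (number of
#'   class pairs). Attribute `empty` is `TRUE` when the class has no
#'   pairs at all.
#' @export
distance_profile <- function(matrix, classes, class = c("DD", "CC"),
                             max_dist = 100e6) {
  class <- match.arg(class)
  if (inherits(classes, "domain_set"))
    classes <- classify_pairs(matrix, classes)
  kmax <- max_separation(matrix, max_dist)
  pr <- class_profile(matrix, classes, class, kmax)
  out <- data.frame(s = seq_len(kmax) * matrix$resolution,
                    mean = ifelse(pr$count > 0, pr$sum / pr$count, NA_real_),
                    count = pr$count)
  attr(out, "class_label") <- class
  attr(out, "empty") <- all(pr$count == 0)
  if (attr(out, "empty"))
    warning("class ", class, " has no classified pairs; empty profile")
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Two-vector quantile normalization
#'
#' The standard rank-average scheme: both vectors are sorted, averaged
#' rank by rank, and each vector is mapped back through its own ranks;
#' tied values receive the mean of the rank-averages their ranks
#' occupy.
#'
#' @param a,b Numeric vectors of equal length without missing values.
#' @return List with components `a` and `b`, the normalized vectors.
#' @export
quantile_normalize_vectors <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  m <- (sort(a) + sort(b)) / 2
  assign_ranks <- function(x) {
    ord <- order(x)
    xs <- x[ord]
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    gm <- tapply(m, grp, mean)
    out <- numeric(length(x))
    out[ord] <- gm[grp]
    out
  }
  list(a = assign_ranks(a), b = assign_ranks(b))
}

#' Distance Sorted Contact Optimization (DiSCO)
#'
#' Rebalances condensed-condensed (CC) against decondensed-decondensed
#' (DD) interaction frequencies: (i) entries are split into CC and DD
#' lists, (ii) the mean interaction frequency is computed per distance
#' bin for each list, (iii) each interaction's residual `x - mu` from
#' its class mean curve is kept, (iv) the two mean-versus-distance
#' curves are quantile normalized over jointly populated distances, and
#' (v) residuals are added back to the normalized means. `OTHER`
#' entries (mixed, ambiguous, trans) and entries at distances populated
#' in only one class are returned unchanged. Zero (unstored) pairs
#' between classified bins participate like any other interaction, so
#' the output materializes them where their transformed value is
#' non-zero.
#'
#' @param matrix A [contact_matrix()].
#' @param domains A [domain_set()] defining the classes.
#' @param clip Clip negative transformed values at 0 (default). The
#'   number of clipped entries is recorded in attribute `clip_count`
#'   and messaged.
#' @param max_dist Largest separation optimized, in bp.
#' @return The transformed [contact_matrix()].
#' @export
disco_correct <- function(matrix, domains, clip = TRUE, max_dist = 100e6) {
  classes <- classify_pairs(matrix, domains)
  kmax <- max_separation(matrix, max_dist)
  pc <- class_profile(matrix, classes, "CC", kmax)
  pd <- class_profile(matrix, classes, "DD", kmax)
  if (all(pc$count == 0) || all(pd$count == 0)) {
    warning("empty CC or DD class; matrix returned unchanged")
    return(matrix)
  }
  joint <- which(pc$count > 0 & pd$count > 0)
  mu_cc <- pc$sum[joint] / pc$count[joint]
  mu_dd <- pd$sum[joint] / pd$count[joint]
  qn <- quantile_normalize_vectors(mu_cc, mu_dd)
  delta <- list(CC = numeric(kmax), DD = numeric(kmax))
  delta$CC[joint] <- qn$a - mu_cc
  delta$DD[joint] <- qn$b - mu_dd
  ent <- matrix$entries
  k_ent <- ent$j - ent$i
  new_value <- ent$value
  for (key in c("CC", "DD")) {
    sel <- classes$entry_class == key & k_ent >= 1 & k_ent <= kmax
    new_value[sel] <- ent$value[sel] + delta[[key]][k_ent[sel]]
  }
  extra <- materialize_absent_pairs(matrix, classes, delta, kmax)
  out <- data.frame(i = c(ent$i, extra$i), j = c(ent$j, extra$j),
                    value = c(new_value, extra$value))
  clip_count <- 0L
  if (clip) {
    neg <- out$value < 0
    clip_count <- sum(neg)
    if (clip_count > 0) {
      message(clip_count, " negative transformed value(s) clipped at 0")
      out$value[neg] <- 0
    }
  }
  res <- contact_matrix(matrix$bins, out, matrix$resolution,
                        allow_negative = !clip)
  attr(res, "clip_count") <- clip_count
  attr(res, "dropped") <- attr(matrix, "dropped")
  res
}

# Unstored same-class pairs at separations where the class mean curve
# moved: their transformed value is 0 + delta, which must appear in the
# output for the transformation to act on all pairs.
materialize_absent_pairs <- function(matrix, classes, delta, kmax) {
  res <- list(i = integer(0), j = integer(0), value = numeric(0))
  nb <- nrow(matrix$bins)
  for (key in c("CC", "DD")) {
    ks <- which(delta[[key]] != 0)
    if (length(ks) == 0) next
    kmax_eff <- max(ks)
    sel_ent <- classes$entry_class == key
    stored_key <- matrix$entries$i[sel_ent] * (nb + 1) +
      matrix$entries$j[sel_ent]
    for (ch in unique(matrix$bins$chrom)) {
      idx <- which(matrix$bins$chrom == ch &
                     classes$bin_class == substr(key, 1, 1))
      m <- length(idx)
      if (m < 2) next
      a <- rep(seq_len(m - 1), (m - 1):1)
      bndx <- a + sequence((m - 1):1)
      gi <- idx[a]; gj <- idx[bndx]
      k <- gj - gi
      keep <- k <= kmax_eff & delta[[key]][pmin(k, kmax)] != 0 & k <= kmax
      gi <- gi[keep]; gj <- gj[keep]; k <- k[keep]
      if (length(gi) == 0) next
      absent <- !(gi * (nb + 1) + gj) %in% stored_key
      res$i <- c(res$i, gi[absent])
      res$j <- c(res$j, gj[absent])
      res$value <- c(res$value, delta[[key]][k[absent]])
    }
  }
  res
}

#' Decondensed-to-condensed interaction ratio versus distance
#'
#' `ratio(s) = mean_DD(s) / mean_CC(s)` over distance bins populated in
#' both classes; bins with a zero CC mean are omitted (and counted in a
#' message).
#'
#' @param matrix A [contact_matrix()].
#' @param domains A [domain_set()].
#' @param max_dist Largest separation, in bp.
#' @return data.frame with columns `s` (bp) and `ratio`.
#' @export
ratio_curve <- function(matrix, domains, max_dist = 100e6) {
  classes <- classify_pairs(matrix, domains)
  kmax <- max_separation(matrix, max_dist)
  pc <- class_profile(matrix, classes, "CC", kmax)
  pd <- class_profile(matrix, classes, "DD", kmax)
  joint <- pc$count > 0 & pd$count > 0
  zero_cc <- joint & pc$sum == 0
  if (any(zero_cc))
    message(sum(zero_cc), " distance bin(s) with zero CC mean omitted")
  keep <- which(joint & pc$sum > 0)
  data.frame(s = keep * matrix$resolution,
             ratio = (pd$sum[keep] / pd$count[keep]) /
               (pc$sum[keep] / pc$count[keep]))
}

#' Iterative (ICE-style) matrix balancing
#'
#' Drops the lowest-coverage `low_cov_drop` fraction of bins (and all
#' zero-coverage bins), then alternately rescales the symmetric matrix
#' until the maximum relative deviation of the kept bins' marginals
#' from their mean falls below `tol`.
#'
#' @param matrix A [contact_matrix()].
#' @param max_iter Iteration cap; non-convergence returns the last
#'   iterate with a warning and attribute `converged = FALSE`.
#' @param tol Relative marginal tolerance.
#' @param low_cov_drop Fraction of bins dropped for low coverage.
#' @return The balanced [contact_matrix()], with attributes `dropped`
#'   (1-based bin indices), `converged` and `iterations`.
#' @export
ice_balance <- function(matrix, max_iter = 200, tol = 1e-5,
                        low_cov_drop = 0.02) {
  stopifnot(inherits(matrix, "contact_matrix"))
  nb <- nrow(matrix$bins)
  ent <- matrix$entries
  cov <- entry_marginals(ent$i, ent$j, ent$value, nb)
  n_drop <- floor(low_cov_drop * nb)
  dropped <- union(which(cov == 0), order(cov)[seq_len(n_drop)])
  kept <- setdiff(seq_len(nb), dropped)
  keep_ent <- !(ent$i %in% dropped | ent$j %in% dropped)
  ent <- ent[keep_ent, , drop = FALSE]
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    marg <- entry_marginals(ent$i, ent$j, ent$value, nb)[kept]
    s <- marg / mean(marg)
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    # symmetric update: both the row and the column of an entry are
    # rescaled in one pass, so the correction enters as sqrt(s_i s_j)
    sfull <- rep(1, nb)
    sfull[kept] <- sqrt(s)
    ent$value <- ent$value / (sfull[ent$i] * sfull[ent$j])
    it <- it + 1
  }
  if (!converged)
    warning("ice_balance did not converge in ", max_iter, " iterations")
  out <- contact_matrix(matrix$bins, ent, matrix$resolution)
  attr(out, "dropped") <- sort(dropped)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}
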