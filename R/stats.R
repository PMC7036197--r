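#' Mann-Whitney U test
#'
#' U counts the pairs where an `x` exceeds a `y` (ties count one half,
#' via midranks). The p-value is exact — full enumeration of the null
#' distribution by dynamic programming — when `n * m <= 400` and there
#' are no ties; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @return List with `U`, `p`, `n`, `m` and `method` (`"exact"` or
#'   `"normal"`).
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(gsub("-", ".", alternative[1]),
                           c("two.sided", "less", "greater"))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n * m <= 400) {
    counts <- mw_null_counts(n, m)
    total <- sum(counts)
    p_le <- sum(counts[seq_len(U + 1)]) / total
    p_ge <- sum(counts[(U + 1):length(counts)]) / total
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    N <- n + m
    mu <- n * m / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                              (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
                less = stats::pnorm((U - mu + 0.5) / sigma),
                greater = stats::pnorm(-(U - mu - 0.5) / sigma),
                two.sided = min(1, 2 * stats::pnorm(
                  -(abs(U - mu) - 0.5) / sigma)))
    method <- "normal"
  }
  list(U = U, p = p, n = n, m = m, method = method)
}

# Null distribution of U for sample sizes n, m without ties: counts of
# arrangements with U = 0..n*m, from the classic recurrence
# f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u).
mw_null_counts <- function(n, m) {
  polys <- vector("list", (n + 1) * (m + 1))
  at <- function(a, b) a * (m + 1) + b + 1
  for (a in 0:n) polys[[at(a, 0)]] <- 1
  for (b in 0:m) polys[[at(0, b)]] <- 1
  for (a in seq_len(n)) for (b in seq_len(m)) {
    p1 <- c(rep(0, b), polys[[at(a - 1, b)]])
    p2 <- polys[[at(a, b - 1)]]
    L <- max(length(p1), length(p2))
    polys[[at(a, b)]] <- c(p1, rep(0, L - length(p1))) +
      c(p2, rep(0, L - length(p2)))
  }
  polys[[at(n, m)]]
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks over pairwise complete observations.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The correlation, or `NA` with a warning when either vector
#'   is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

# k-column rank-average quantile normalization; ties receive the mean
# of the rank-averages their ranks occupy.
qn_columns <- function(mat) {
  m <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (cidx in seq_len(ncol(mat))) {
    x <- mat[, cidx]
    ord <- order(x)
    xs <- x[ord]
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    gm <- tapply(m, grp, mean)
    out[ord, cidx] <- gm[grp]
  }
  out
}

#' Quantile normalize a set of tracks
#'
#' Column-wise quantile normalization across tracks over jointly
#' unmasked bins (the same rank-average semantics as
#' [quantile_normalize_vectors()], generalized to k tracks). Output
#' masks are the joint mask. A single track is returned unchanged.
#'
#' @param tracks List of [binned_track()]s on a shared grid.
#' @return List of normalized [binned_track()]s.
#' @export
quantile_normalize_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (length(tracks) == 1) return(tracks)
  do.call(stop_unless_same_grid, tracks)
  joint <- Reduce(`&`, lapply(tracks, track_mask))
  mat <- vapply(tracks, function(t)
    track_values(t, masked_as_na = FALSE)[joint],
    numeric(sum(joint)))
  qn <- qn_columns(mat)
  lapply(seq_along(tracks), function(ti) {
    v <- track_values(tracks[[ti]], masked_as_na = FALSE)
    v[joint] <- qn[, ti]
    track_like(tracks[[ti]], v, joint)
  })
}

#' Length fraction of state domains covered by an annotation
#'
#' The fraction of the total bp of `state` domains that intersects the
#' annotation intervals.
#'
#' @param domains A [domain_set()].
#' @param annotation data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp).
#' @param state Domain state whose coverage is measured.
#' @return Fraction in `[0, 1]`, or `NA` with a warning when no domain
#'   has that state.
#' @export
overlap_fraction <- function(domains, annotation, state = "condensed") {
  d <- domains[domains$state == state, , drop = FALSE]
  total <- sum(d$end - d$start)
  if (total == 0) {
    warning("no domains with state ", state, "; fraction undefined")
    return(NA_real_)
  }
  inter <- 0
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    aa <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (nrow(aa) == 0) next
    ir <- IRanges::intersect(
      IRanges::IRanges(dd$start + 1, dd$end),
      IRanges::reduce(IRanges::IRanges(aa$start + 1, aa$end)))
    inter <- inter + sum(IRanges::width(ir))
  }
  inter / total
}

#' Per-bin state-switch table between two segmentations
#'
#' Cross-tabulates the per-bin states (condensed / decondensed /
#' ambiguous, assigned by majority overlap) of two domain sets over the
#' bins covered by both, and derives the switching percentages:
#' `pct_condensed_to_decondensed` is the percentage of `a`-condensed
#' bins that are decondensed in `b`, and conversely.
#'
#' @param a,b [domain_set()]s on the same bin grid.
#' @param bin_size Bin width in bp.
#' @return An object of class `switch_table`: list with the 3x3
#'   `table`, the two switch percentages and `n_bins`.
#' @export
switch_table <- function(a, b, bin_size = 10000) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) stop("the two domain sets share no chromosomes")
  lab <- c(C = "condensed", D = "decondensed", other = "ambiguous")
  sa_all <- character(0); sb_all <- character(0)
  for (ch in chroms) {
    la <- max(a$end[a$chrom == ch]); lb <- max(b$end[b$chrom == ch])
    n <- floor(min(la, lb) / bin_size)
    if (n == 0) next
    len <- stats::setNames(n * bin_size, ch)
    sa <- domain_bin_states(a[a$chrom == ch, ], bin_size, len)[[ch]][1:n]
    sb <- domain_bin_states(b[b$chrom == ch, ], bin_size, len)[[ch]][1:n]
    sa_all <- c(sa_all, lab[sa]); sb_all <- c(sb_all, lab[sb])
  }
  if (length(sa_all) == 0) stop("no jointly covered bins")
  states <- c("condensed", "decondensed", "ambiguous")
  tab <- table(factor(sa_all, states), factor(sb_all, states),
               dnn = c("a", "b"))
  n_ca <- sum(tab["condensed", ])
  n_da <- sum(tab["decondensed", ])
  structure(list(
    table = tab,
    pct_condensed_to_decondensed =
      if (n_ca > 0) 100 * tab["condensed", "decondensed"] / n_ca else NA_real_,
    pct_decondensed_to_condensed =
      if (n_da > 0) 100 * tab["decondensed", "condensed"] / n_da else NA_real_,
    n_bins = length(sa_all)), class = "switch_table")
}

#' @export
print.switch_table <- function(x, ...) {
  cat("switch_table over", x$n_bins, "bins\n")
  print(x$table)
  cat(sprintf("  condensed -> decondensed: %.1f%%\n",
              x$pct_condensed_to_decondensed))
  cat(sprintf("  decondensed -> condensed: %.1f%%\n",
              x$pct_decondensed_to_condensed))
  invisible(x)
}

#' Boundary-oriented signal aggregation
#'
#' Averages a track around every boundary separating a decondensed from
#' a condensed domain, oriented so the decondensed side lies upstream
#' (negative offsets). Boundaries flanked by fewer than `min_side` bp
#' of the adjacent domain on either side, or by an ambiguous domain,
#' are excluded.
#'
#' @param track A [binned_track()].
#' @param domains A [domain_set()] on the same genome.
#' @param flank Half-width of the window in bp.
#' @param min_side Minimal flanking-domain extent in bp.
#' @param scale01 Min-max scale the profile to `[0, 1]`.
#' @return An object of class `aggregation_profile`: list with
#'   `offsets` (bp, bin centers relative to the boundary), `mean` and
#'   `n_boundaries`.
#' @export
boundary_aggregate <- function(track, domains, flank = 1e6,
                               min_side = 2e5, scale01 = FALSE) {
  bs <- track$bin_size
  nF <- round(flank / bs)
  prof <- NULL
  nb <- 0L
  for (ch in intersect(names(track$values), unique(domains$chrom))) {
    d <- domains[domains$chrom == ch, ]
    v <- track_values_chrom(track, ch)
    n <- length(v)
    if (nrow(d) < 2) next
    for (r in seq_len(nrow(d) - 1)) {
      s1 <- d$state[r]; s2 <- d$state[r + 1]
      if (d$end[r] != d$start[r + 1]) next
      if (!(identical(sort(c(s1, s2)), c("condensed", "decondensed")))) next
      if (d$end[r] - d$start[r] < min_side ||
          d$end[r + 1] - d$start[r + 1] < min_side) next
      e <- d$end[r] / bs
      if (e != round(e)) next
      idx <- (e - nF + 1):(e + nF)
      vals <- ifelse(idx >= 1 & idx <= n, v[pmin(pmax(idx, 1), n)], NA)
      if (s1 == "condensed") vals <- rev(vals)
      prof <- rbind(prof, vals)
      nb <- nb + 1L
    }
  }
  if (nb == 0)
    stop("no boundaries retained: each needs opposite non-ambiguous ",
         "flanking states with at least min_side = ", min_side,
         " bp on either side")
  p <- colMeans(prof, na.rm = TRUE)
  if (scale01 && max(p, na.rm = TRUE) > min(p, na.rm = TRUE))
    p <- (p - min(p, na.rm = TRUE)) /
      (max(p, na.rm = TRUE) - min(p, na.rm = TRUE))
  structure(list(offsets = ((-nF):(nF - 1) + 0.5) * bs, mean = p,
                 n_boundaries = nb),
            class = "aggregation_profile")
}

#' @export
print.aggregation_profile <- function(x, ...) {
  cat(sprintf(
    "aggregation_profile: %d boundaries, offsets %g to %g bp\n",
    x$n_boundaries, min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.aggregation_profile <- function(x, ...) {
  plot(x$offsets / 1e3, x$mean, type = "l",
       xlab = "offset from boundary (kb)", ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

# One chromosome's values with masked bins as NA.
track_values_chrom <- function(track, ch) {
  v <- track$values[[ch]]
  v[!track$mask[[ch]]] <- NA_real_
  v
}

#' Log2 ratio of two tracks
#'
#' `log2((a + pseudocount) / (b + pseudocount))` per jointly unmasked
#' bin, after scaling both tracks to counts per million (the KO-vs-WT
#' comparison track).
#'
#' @param a,b [binned_track()]s on the same grid.
#' @param pseudocount Added to both terms (CPM units).
#' @param normalize CPM-normalize both tracks first (default).
#' @return A [binned_track()] of log2 ratios.
#' @export
log_ratio_track <- function(a, b, pseudocount = 1.0, normalize = TRUE) {
  stop_unless_same_grid(a, b)
  if (normalize) {
    a <- libsize_normalize(a)
    b <- libsize_normalize(b)
  }
  mask <- track_mask(a) & track_mask(b)
  va <- track_values(a, masked_as_na = FALSE)
  vb <- track_values(b, masked_as_na = FALSE)
  track_like(a, log2((va + pseudocount) / (vb + pseudocount)), mask)
}
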