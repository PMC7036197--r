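#' Parameters of domain calling
#'
#' @param window_w Bins averaged on each side of a candidate boundary.
#' @param fdr Target false discovery rate of boundary calls, in (0, 1).
#' @param n_permutations Within-chromosome permutations used to build
#'   the null score distribution.
#' @param proportion_min Minimal sign proportion for a non-ambiguous
#'   domain state, in (0.5, 1].
#' @param min_local_max_sep Same-direction candidate edges closer than
#'   this many bins are thinned to the strongest.
#' @param seed Seed of the permutation draw.
#' @return An object of class `domain_call_params`.
#' @export
domain_call_params <- function(window_w = 20L, fdr = 0.05,
                               n_permutations = 100L, proportion_min = 0.8,
                               min_local_max_sep = window_w, seed = 1L) {
  stopifnot(window_w >= 1, fdr > 0, fdr < 1,
            proportion_min > 0.5, proportion_min <= 1,
            n_permutations >= 1, min_local_max_sep >= 1)
  structure(list(window_w = as.integer(window_w), fdr = fdr,
                 n_permutations = as.integer(n_permutations),
                 proportion_min = proportion_min,
                 min_local_max_sep = as.integer(min_local_max_sep),
                 seed = as.integer(seed)),
            class = "domain_call_params")
}

#' Binarize a Z-scored track
#'
#' Maps values to +1 where `z >= 0` and -1 where `z < 0` (zero maps to
#' +1 by convention; Z-scores are continuous so exact zeros are
#' measure-zero in practice). The mask is preserved.
#'
#' @param z A Z-scored [binned_track()].
#' @return A [binned_track()] of +1/-1 values.
#' @export
binarize_track <- function(z) {
  v <- track_values(z, masked_as_na = FALSE)
  track_like(z, ifelse(v >= 0, 1, -1), track_mask(z))
}

# Core edge-score computation on one chromosome's +/-1 vector.
# score(e) = mean(b[e+1 .. e+w]) - mean(b[e-w+1 .. e]) over unmasked
# bins, for interior edges e = 1 .. n-1 (edge e sits after bin e).
# Edges with fewer than w/2 unmasked bins on either side are NA.
edge_scores_chrom <- function(b, mask, w) {
  n <- length(b)
  scores <- rep(NA_real_, max(n - 1, 0))
  if (n < 2 * w) return(scores)
  bm <- ifelse(mask, b, 0)
  cs <- cumsum(c(0, bm))
  cm <- cumsum(c(0, as.numeric(mask)))
  e <- seq_len(n - 1)
  llo <- pmax(e - w + 1, 1); lhi <- e
  rlo <- e + 1; rhi <- pmin(e + w, n)
  nl <- cm[lhi + 1] - cm[llo]
  nr <- cm[rhi + 1] - cm[rlo]
  sl <- cs[lhi + 1] - cs[llo]
  sr <- cs[rhi + 1] - cs[rlo]
  ok <- nl >= w / 2 & nr >= w / 2
  scores[ok] <- sr[ok] / nr[ok] - sl[ok] / nl[ok]
  scores
}

#' Boundary scores of a binarized track
#'
#' At each interior bin edge, the mean of the `window_w` bins to the
#' right minus the mean of the `window_w` bins to the left (means over
#' unmasked bins; windows truncated at chromosome ends). Positive
#' scores mean the decondensed (+1) side lies to the right. Edges with
#' fewer than `window_w / 2` unmasked bins on either side, and all
#' edges of chromosomes shorter than `2 * window_w` bins, are masked
#' (`NA`).
#'
#' @param b A binarized [binned_track()] (values +1/-1).
#' @param params A [domain_call_params()].
#' @return An object of class `edge_scores`: list with per-chromosome
#'   numeric vectors (`scores[[chrom]][e]` is the score of the edge
#'   after bin `e`), `bin_size` and `chrom_lengths`.
#' @export
boundary_scores <- function(b, params = domain_call_params()) {
  scores <- mapply(edge_scores_chrom, b$values, b$mask,
                   MoreArgs = list(w = params$window_w), SIMPLIFY = FALSE)
  structure(list(scores = scores, bin_size = b$bin_size,
                 chrom_lengths = b$chrom_lengths),
            class = "edge_scores")
}

#' @export
print.edge_scores <- function(x, ...) {
  s <- unlist(x$scores, use.names = FALSE)
  cat(sprintf("edge_scores: %d edges (%d scoreable), |score| max %.3f\n",
              length(s), sum(!is.na(s)), max(abs(s), na.rm = TRUE)))
  invisible(x)
}

#' Permutation cutoff on boundary scores
#'
#' Permutes the binarized values within each chromosome (unmasked bins
#' only) `n_permutations` times, recomputes the absolute boundary
#' scores, and returns the smallest observed-score threshold `t` whose
#' estimated false discovery rate — mean permutation count of null
#' edges with `|score| >= t`, divided by the count of observed edges
#' with `|score| >= t` — is below `fdr`. Returns `+Inf` with a warning
#' when no threshold qualifies (no callable boundaries).
#'
#' @param b A binarized [binned_track()].
#' @param params A [domain_call_params()] (uses `fdr`,
#'   `n_permutations`, `seed`, `window_w`).
#' @return The score cutoff (numeric scalar, possibly `Inf`).
#' @export
null_cutoff <- function(b, params = domain_call_params()) {
  obs <- sort(abs(unlist(boundary_scores(b, params)$scores,
                         use.names = FALSE)))
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0) {
    warning("no scoreable edges; returning Inf")
    return(Inf)
  }
  null_abs <- with_seed(params$seed, {
    unlist(lapply(seq_len(params$n_permutations), function(p) {
      perm <- b
      for (ch in names(perm$values)) {
        ok <- which(perm$mask[[ch]])
        perm$values[[ch]][ok] <- perm$values[[ch]][sample(ok)]
      }
      abs(unlist(boundary_scores(perm, params)$scores, use.names = FALSE))
    }), use.names = FALSE)
  })
  null_abs <- sort(null_abs[!is.na(null_abs)])
  cand <- unique(obs)
  n_obs_ge <- length(obs) - findInterval(cand - 1e-12, obs)
  n_null_ge <- (length(null_abs) - findInterval(cand - 1e-12, null_abs)) /
    params$n_permutations
  fdr_hat <- n_null_ge / pmax(1, n_obs_ge)
  ok <- which(fdr_hat < params$fdr)
  if (length(ok) == 0) {
    warning("no score threshold reaches FDR < ", params$fdr,
            "; returning Inf (no boundaries callable)")
    return(Inf)
  }
  cand[min(ok)]
}

#' Call boundaries from edge scores
#'
#' Candidate edges are those with `|score| >= cutoff`. Same-direction
#' candidates closer than `min_local_max_sep` bins are thinned to the
#' edge of maximal `|score|` (leftmost on ties); opposite-direction
#' candidates never suppress each other, since they mark distinct
#' transitions. Chromosome ends are never boundaries.
#'
#' @param scores An `edge_scores` object from [boundary_scores()].
#' @param cutoff Score cutoff, typically from [null_cutoff()].
#' @param params A [domain_call_params()].
#' @return A data.frame of class `boundary_set` with columns `chrom`,
#'   `edge` (bins left of the boundary), `pos` (bp), `score`,
#'   `direction`.
#' @export
call_boundaries <- function(scores, cutoff, params = domain_call_params()) {
  stopifnot(inherits(scores, "edge_scores"))
  rows <- list()
  for (ch in names(scores$scores)) {
    s <- scores$scores[[ch]]
    cand <- which(!is.na(s) & abs(s) >= cutoff)
    if (length(cand) == 0) next
    ord <- cand[order(-abs(s[cand]), cand)]
    kept <- integer(0)
    for (e in ord) {
      same <- kept[sign(s[kept]) == sign(s[e])]
      if (!any(abs(same - e) < params$min_local_max_sep))
        kept <- c(kept, e)
    }
    kept <- sort(kept)
    rows[[ch]] <- data.frame(
      chrom = ch, edge = kept, pos = kept * scores$bin_size,
      score = s[kept],
      direction = ifelse(s[kept] > 0, "condensed_to_decondensed",
                         "decondensed_to_condensed"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), edge = integer(0), pos = numeric(0),
               score = numeric(0), direction = character(0))
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Classify inter-boundary regions
#'
#' Each region between consecutive boundaries (chromosome-end flanks
#' included) is labeled by the sign proportion of its unmasked bins:
#' `decondensed` when the +1 share reaches `proportion_min`,
#' `condensed` when the -1 share does, otherwise `ambiguous`. Regions
#' with no unmasked bins are ambiguous with proportion 0.
#'
#' @param b The binarized [binned_track()].
#' @param boundaries A `boundary_set` from [call_boundaries()].
#' @param params A [domain_call_params()].
#' @return A [domain_set()] tiling each chromosome.
#' @export
classify_domains <- function(b, boundaries, params = domain_call_params()) {
  rows <- list()
  for (ch in names(b$values)) {
    v <- b$values[[ch]]; m <- b$mask[[ch]]
    n <- length(v)
    edges <- sort(boundaries$edge[boundaries$chrom == ch])
    brk <- c(0, edges, n)
    for (r in seq_len(length(brk) - 1)) {
      lo <- brk[r] + 1; hi <- brk[r + 1]
      ok <- m[lo:hi]
      if (!any(ok)) {
        state <- "ambiguous"; prop <- 0
      } else {
        share_pos <- mean(v[lo:hi][ok] > 0)
        prop <- max(share_pos, 1 - share_pos)
        state <- if (share_pos >= params$proportion_min) "decondensed"
        else if (1 - share_pos >= params$proportion_min) "condensed"
        else "ambiguous"
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = (lo - 1) * b$bin_size,
        end = min(hi * b$bin_size, b$chrom_lengths[[ch]]),
        state = state, proportion = prop, stringsAsFactors = FALSE)
    }
  }
  domain_set(do.call(rbind, rows))
}

#' Call condensed and decondensed domains from a Z-scored track
#'
#' The full pipeline: binarize, score edges, set the permutation FDR
#' cutoff, call and thin boundaries, classify inter-boundary regions.
#' Deterministic given `params$seed`.
#'
#' @param z A Z-scored [binned_track()].
#' @param params A [domain_call_params()].
#' @return A [domain_set()]; the boundary table and cutoff are attached
#'   as attributes `boundaries` and `cutoff`.
#' @export
call_domains <- function(z, params = domain_call_params()) {
  b <- binarize_track(z)
  sc <- boundary_scores(b, params)
  cutoff <- null_cutoff(b, params)
  bd <- call_boundaries(sc, cutoff, params)
  d <- classify_domains(b, bd, params)
  attr(d, "boundaries") <- bd
  attr(d, "cutoff") <- cutoff
  d
}

# Interior state-transition edges (bp) of a domain set, per chromosome.
domain_boundary_positions <- function(domains) {
  out <- list()
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, ]
    if (nrow(d) < 2) { out[[ch]] <- numeric(0); next }
    out[[ch]] <- d$start[-1]
  }
  out
}

#' Boundary recovery against a reference segmentation
#'
#' Fraction of reference boundaries (interior domain edges) having a
#' called boundary within `tol_bins` bins.
#'
#' @param called A `boundary_set` (or a `domain_set` whose interior
#'   edges are used).
#' @param truth_domains The reference [domain_set()].
#' @param bin_size Bin width in bp.
#' @param tol_bins Matching tolerance in bins.
#' @return Recall in `[0, 1]`.
#' @export
boundary_recall <- function(called, truth_domains, bin_size, tol_bins = 2) {
  true_pos <- domain_boundary_positions(truth_domains)
  called_pos <- if (inherits(called, "boundary_set"))
    split(called$pos, called$chrom) else domain_boundary_positions(called)
  n_true <- 0; n_hit <- 0
  for (ch in names(true_pos)) {
    tp <- true_pos[[ch]]
    n_true <- n_true + length(tp)
    cp <- called_pos[[ch]]
    if (length(cp) == 0 || length(tp) == 0) next
    for (p in tp)
      if (min(abs(cp - p)) <= tol_bins * bin_size) n_hit <- n_hit + 1
  }
  if (n_true == 0) return(NA_real_)
  n_hit / n_true
}

#' Bin-level Jaccard index of one state between two segmentations
#'
#' @param a,b [domain_set()]s on the same genome.
#' @param state State to compare (`"condensed"` or `"decondensed"`).
#' @param bin_size Bin width in bp.
#' @return Jaccard index of the per-bin state indicators.
#' @export
state_jaccard <- function(a, b, state = "condensed", bin_size = 10000) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  lens <- vapply(chroms, function(ch)
    max(c(a$end[a$chrom == ch], b$end[b$chrom == ch])), 0)
  sa <- domain_bin_states(a, bin_size, lens)
  sb <- domain_bin_states(b, bin_size, lens)
  key <- if (state == "condensed") "C" else "D"
  inter <- 0; uni <- 0
  for (ch in chroms) {
    xa <- sa[[ch]] == key; xb <- sb[[ch]] == key
    inter <- inter + sum(xa & xb)
    uni <- uni + sum(xa | xb)
  }
  if (uni == 0) return(NA_real_)
  inter / uni
}
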