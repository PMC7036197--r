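#' Parameters of the synthetic genome generator
#'
#' Defines the statistical structure of a simulated genome: an
#' alternating segmentation into condensed and decondensed domains, the
#' per-bin "visibility" of chromatin to restriction digestion (condensed
#' bins yield `visibility_delta` times the expected reads of decondensed
#' bins), covariate tracks (GC fraction, restriction-site density,
#' mappability), binned 1D read counts, and cis contact matrices with
#' power-law distance decay multiplied by per-bin visibility.
#'
#' @param chrom_names Chromosome identifiers.
#' @param chrom_lengths Chromosome lengths in bp; positive multiples of
#'   `bin_size`.
#' @param bin_size Bin width in bp.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   outputs across all generator functions.
#' @param domain_mean_length Mean domain length in bp (gamma, shape 2).
#' @param condensed_fraction Long-run fraction of the genome in condensed
#'   domains, in (0, 1).
#' @param visibility_delta Expected-count multiplier for condensed bins,
#'   in (0, 1].
#' @param gc_range Range (pair of fractions) spanned by the smoothed GC
#'   field.
#' @param re_rate_per_bin Expected restriction sites per bin at mean GC.
#' @param depth Expected reads per fully visible bin.
#' @param decay_exponent Power-law exponent of contact distance decay.
#' @param tad_boost Within-domain contact multiplier, >= 1.
#' @param mappability_dip_fraction Fraction of bins given mappability
#'   below 0.8, in `[0, 1]`.
#' @param contact_scale Expected contacts between an adjacent pair of
#'   fully visible bins (the overall matrix depth; doubling it doubles
#'   the expected matrix total).
#' @param edge_ramp If `TRUE`, visibility ramps linearly over 2 bins at
#'   domain edges instead of stepping.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_names = c("chr1", "chr2"),
                           chrom_lengths = c(60e6, 60e6),
                           bin_size = 10000,
                           seed = 1L,
                           domain_mean_length = 800000,
                           condensed_fraction = 0.4,
                           visibility_delta = 0.5,
                           gc_range = c(0.35, 0.60),
                           re_rate_per_bin = 40,
                           depth = 200,
                           decay_exponent = 1.0,
                           tad_boost = 2.0,
                           mappability_dip_fraction = 0.02,
                           contact_scale = 3000,
                           edge_ramp = FALSE) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            all(chrom_lengths > 0),
            all(chrom_lengths %% bin_size == 0),
            bin_size > 0,
            condensed_fraction > 0, condensed_fraction < 1,
            visibility_delta > 0, visibility_delta <= 1,
            mappability_dip_fraction >= 0, mappability_dip_fraction <= 1,
            length(gc_range) == 2, gc_range[1] < gc_range[2],
            gc_range[1] > 0, gc_range[2] < 1,
            re_rate_per_bin > 0, depth > 0, tad_boost >= 1,
            domain_mean_length >= bin_size, contact_scale > 0)
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
                 bin_size = bin_size, seed = as.integer(seed),
                 domain_mean_length = domain_mean_length,
                 condensed_fraction = condensed_fraction,
                 visibility_delta = visibility_delta,
                 gc_range = gc_range, re_rate_per_bin = re_rate_per_bin,
                 depth = depth, decay_exponent = decay_exponent,
                 tad_boost = tad_boost,
                 mappability_dip_fraction = mappability_dip_fraction,
                 contact_scale = contact_scale, edge_ramp = edge_ramp),
            class = "synthetic_spec")
}

#' Generate the ground-truth segmentation and visibility track
#'
#' Draws an alternating condensed/decondensed segmentation per
#' chromosome. Domain lengths are gamma distributed with shape 2; the
#' state-specific means are scaled so that the long-run condensed length
#' share equals `condensed_fraction` while the overall mean domain length
#' equals `domain_mean_length`. Lengths are rounded to whole bins
#' (domains rounding to zero bins are dropped, merging their
#' neighbours). The visibility track is `visibility_delta` on condensed
#' bins and 1 elsewhere.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_truth`: list with `domains`
#'   (a [domain_set()]), `visibility` (a [binned_track()]) and `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$chrom_lengths < 2 * spec$domain_mean_length))
    stop("chromosome shorter than 2 domains of mean length")
  f <- spec$condensed_fraction
  mean_c <- 2 * f * spec$domain_mean_length
  mean_d <- 2 * (1 - f) * spec$domain_mean_length
  bs <- spec$bin_size
  with_seed(spec$seed, {
    rows <- list()
    vis <- list()
    for (ch in spec$chrom_names) {
      n <- spec$chrom_lengths[[ch]] / bs
      state <- if (stats::runif(1) < f) "condensed" else "decondensed"
      pos <- 0L
      st <- character(0); nb <- integer(0)
      while (pos < n) {
        m <- if (state == "condensed") mean_c else mean_d
        len <- stats::rgamma(1, shape = 2, scale = m / 2)
        k <- min(round(len / bs), n - pos)
        if (k > 0) {
          st <- c(st, state); nb <- c(nb, k)
          pos <- pos + k
        }
        state <- if (state == "condensed") "decondensed" else "condensed"
      }
      # merge runs of equal state created by dropped zero-bin domains
      if (length(nb) > 1) {
        grp <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
        nb <- as.integer(rowsum(nb, grp))
        st <- st[!duplicated(grp)]
      }
      ends <- cumsum(nb)
      starts <- c(0, ends[-length(ends)])
      rows[[ch]] <- data.frame(chrom = ch, start = starts * bs,
                               end = ends * bs, state = st,
                               proportion = 1, stringsAsFactors = FALSE)
      v <- rep(1, n)
      v[rep(st == "condensed", nb)] <- spec$visibility_delta
      if (spec$edge_ramp && length(nb) > 1) {
        for (e in ends[-length(ends)]) {
          lo <- v[e]; hi <- v[e + 1]
          if (lo != hi) {
            v[e] <- lo + (hi - lo) / 4
            v[e + 1] <- hi - (hi - lo) / 4
          }
        }
      }
      vis[[ch]] <- v
    }
    domains <- domain_set(do.call(rbind, rows))
    visibility <- binned_track(vis, bs, spec$chrom_lengths)
    structure(list(domains = domains, visibility = visibility, spec = spec),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth (seed ", x$spec$seed, ")\n", sep = "")
  print(x$domains)
  share <- with(x$domains,
                sum((end - start)[state == "condensed"]) / sum(end - start))
  cat(sprintf("  condensed length share %.3f (target %.3f), delta %.2f\n",
              share, x$spec$condensed_fraction, x$spec$visibility_delta))
  invisible(x)
}

#' Generate covariate tracks for a synthetic truth
#'
#' GC content is a smoothed uniform field: per-bin uniform draws are
#' moving-averaged over 20 bins and linearly rescaled to span
#' `gc_range`. Restriction-site density is Poisson with rate
#' `re_rate_per_bin * (gc / mean(gc))^2`, so RE density and GC are
#' positively correlated as they are for real restriction enzymes with
#' GC-containing recognition sites. Mappability is 1 except for a random
#' `mappability_dip_fraction` of bins set to values below 0.8.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @return List of three [binned_track()]s: `gc`, `re_density`,
#'   `mappability`.
#' @export
generate_covariates <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$spec
  tpl <- truth$visibility
  nb <- vapply(tpl$values, length, 0L)
  with_seed(spec$seed + 1L, {
    gc <- lapply(nb, function(n)
      moving_average(stats::runif(n, spec$gc_range[1], spec$gc_range[2]), 20))
    flat <- unlist(gc, use.names = FALSE)
    rng <- range(flat)
    flat <- spec$gc_range[1] + (flat - rng[1]) / diff(rng) * diff(spec$gc_range)
    re <- stats::rpois(length(flat),
                       spec$re_rate_per_bin * (flat / mean(flat))^2)
    mp <- rep(1, length(flat))
    ndip <- round(spec$mappability_dip_fraction * length(flat))
    if (ndip > 0) {
      dip <- sample.int(length(flat), ndip)
      mp[dip] <- stats::runif(ndip, 0, 0.8 - 1e-9)
    }
    list(gc = track_like(tpl, flat),
         re_density = track_like(tpl, as.numeric(re)),
         mappability = track_like(tpl, mp))
  })
}

# The two fixed nonlinear bias functions of the count model. h saturates
# in RE density; g is a smooth unimodal bump in GC peaking at 0.45.
# Both are deliberately non-linear so that a linear correction is
# insufficient while a loess fit removes them.
bias_h <- function(re) 2 * re / (re + mean(re))
bias_g <- function(gc) 1 + 0.03 * exp(-(gc - 0.45)^2 / (2 * 0.05^2))

#' Simulate binned 1D read counts
#'
#' Counts are Poisson with expectation
#' `depth * h(re) * g(gc) * v`, where `h(x) = 2x / (x + mean(x))` is a
#' saturating restriction-density effect, `g` is a smooth unimodal GC
#' effect peaking near 0.45, and `v` is the true per-bin visibility
#' (condensed bins are depleted by `visibility_delta`).
#'
#' @param truth A `synthetic_truth`.
#' @param gc,re_density Covariate tracks from [generate_covariates()]
#'   (same bin grid as the truth).
#' @return A [binned_track()] of simulated counts.
#' @export
simulate_counts <- function(truth, gc, re_density) {
  stopifnot(inherits(truth, "synthetic_truth"))
  stop_unless_same_grid(truth$visibility, gc, re_density)
  spec <- truth$spec
  v <- track_values(truth$visibility, masked_as_na = FALSE)
  g <- bias_g(track_values(gc, masked_as_na = FALSE))
  h <- bias_h(track_values(re_density, masked_as_na = FALSE))
  lam <- spec$depth * h * g * v
  with_seed(spec$seed + 2L,
            track_like(truth$visibility,
                       as.numeric(stats::rpois(length(lam), lam))))
}

#' Simulate a cis contact matrix
#'
#' For bins `i < j` on the same chromosome at separation `s` bins, the
#' contact count is Poisson with mean
#' `contact_scale * s^(-decay_exponent) * v_i * v_j * t_ij`, where
#' `t_ij = tad_boost` when both bins lie in the same true domain. Only
#' cis contacts are simulated; the matrix is stored upper-triangular and
#' sparse (zero counts are not stored).
#'
#' @param truth A `synthetic_truth`.
#' @return A [contact_matrix()].
#' @export
simulate_matrix <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$spec
  bs <- spec$bin_size
  bins <- matrix_bins(spec$chrom_lengths, bs)
  offset <- c(0, cumsum(vapply(truth$visibility$values, length, 0L)))
  names(offset) <- c(spec$chrom_names, "..end")
  with_seed(spec$seed + 3L, {
    res <- vector("list", length(spec$chrom_names))
    for (ci in seq_along(spec$chrom_names)) {
      ch <- spec$chrom_names[ci]
      v <- truth$visibility$values[[ch]]
      n <- length(v)
      d <- truth$domains[truth$domains$chrom == ch, ]
      dom <- rep(seq_len(nrow(d)), (d$end - d$start) / bs)
      ii <- jj <- xx <- vector("list", n - 1)
      for (k in seq_len(n - 1)) {
        i <- seq_len(n - k)
        lam <- spec$contact_scale * k^(-spec$decay_exponent) *
          v[i] * v[i + k] *
          ifelse(dom[i] == dom[i + k], spec$tad_boost, 1)
        x <- stats::rpois(n - k, lam)
        nz <- which(x > 0)
        if (length(nz)) {
          ii[[k]] <- nz; jj[[k]] <- nz + k; xx[[k]] <- x[nz]
        }
      }
      res[[ci]] <- data.frame(
        i = unlist(ii, use.names = FALSE) + offset[ci],
        j = unlist(jj, use.names = FALSE) + offset[ci],
        value = as.numeric(unlist(xx, use.names = FALSE)))
    }
    contact_matrix(bins, do.call(rbind, res), bs)
  })
}
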