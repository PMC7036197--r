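#' Parameters of the 1D correction
#'
#' @param loess_span Loess span for covariate fits, in (0, 1].
#' @param loess_degree Local polynomial degree (1).
#' @param mappability_min Bins below this mappability are masked.
#' @param pseudolog If `TRUE`, loess fits operate on `log1p` counts.
#' @param max_fit_points Loess is fitted on at most this many unmasked
#'   bins (seeded uniform subsample) and then evaluated everywhere.
#' @param subsample_seed Seed of the subsample draw.
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(loess_span = 0.3, loess_degree = 1,
                              mappability_min = 0.8, pseudolog = FALSE,
                              max_fit_points = 100000L,
                              subsample_seed = 1L) {
  stopifnot(loess_span > 0, loess_span <= 1,
            mappability_min >= 0, mappability_min <= 1,
            loess_degree %in% c(1, 2), max_fit_points >= 100)
  structure(list(loess_span = loess_span, loess_degree = loess_degree,
                 mappability_min = mappability_min, pseudolog = pseudolog,
                 max_fit_points = as.integer(max_fit_points),
                 subsample_seed = as.integer(subsample_seed)),
            class = "correction_params")
}

#' Bin interval values onto a regular grid
#'
#' Each interval's value is apportioned to the bins it overlaps in
#' proportion to the overlap length; the output covers the full genome
#' with zeros where no interval maps. Intervals extending past a
#' chromosome end are clipped with a warning; intervals on unknown
#' chromosomes are skipped with a warning.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open bp).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named chromosome lengths in bp; defaults to the
#'   last interval end seen per chromosome, rounded up to a full bin.
#' @return A [binned_track()].
#' @export
bin_reads <- function(intervals, bin_size, chrom_lengths = NULL) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "value") %in% names(intervals)),
            bin_size > 0)
  if (is.null(chrom_lengths)) {
    chroms <- unique(intervals$chrom)
    chrom_lengths <- vapply(chroms, function(ch)
      ceiling(max(intervals$end[intervals$chrom == ch]) / bin_size) *
        bin_size, 0)
  }
  unknown <- !(intervals$chrom %in% names(chrom_lengths))
  if (any(unknown)) {
    warning(sum(unknown), " interval(s) on unknown chromosomes skipped")
    intervals <- intervals[!unknown, , drop = FALSE]
  }
  values <- list()
  for (ch in names(chrom_lengths)) {
    n <- ceiling(chrom_lengths[[ch]] / bin_size)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    over <- iv$end > chrom_lengths[[ch]]
    if (any(over)) {
      warning(sum(over), " interval(s) clipped at the end of ", ch)
      iv$end[over] <- chrom_lengths[[ch]]
      iv <- iv[iv$end > iv$start, , drop = FALSE]
    }
    values[[ch]] <- apportion_to_bins(iv$start, iv$end, iv$value,
                                      bin_size, n)
  }
  binned_track(values, bin_size, chrom_lengths)
}

#' Scale a track to counts per million
#'
#' Values are rescaled so that the total over unmasked bins equals 1e6.
#'
#' @param track A [binned_track()] with non-negative values.
#' @return The rescaled [binned_track()].
#' @export
libsize_normalize <- function(track) {
  v <- track_values(track)
  tot <- sum(v, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("track total is zero; cannot normalize")
  track_like(track, track_values(track, masked_as_na = FALSE) * 1e6 / tot,
             track_mask(track))
}

#' Residuals of a track after loess regression on a covariate
#'
#' Fits `values ~ covariate` by loess (degree
#' `params$loess_degree`, span `params$loess_span`) over unmasked bins
#' genome-wide and returns the residuals. The fit uses at most
#' `params$max_fit_points` bins (a seeded uniform subsample) and is then
#' evaluated for every unmasked bin; covariate values outside the fitted
#' range are clamped to it for prediction. A constant covariate
#' degenerates to mean-centering.
#'
#' @param values,covariate [binned_track()]s on the same grid.
#' @param params A [correction_params()].
#' @return A [binned_track()] of residuals; the mask is the AND of both
#'   input masks.
#' @export
loess_residuals <- function(values, covariate, params = correction_params()) {
  stop_unless_same_grid(values, covariate)
  mask <- track_mask(values) & track_mask(covariate)
  y <- track_values(values, masked_as_na = FALSE)
  x <- track_values(covariate, masked_as_na = FALSE)
  if (sum(mask) < 100) stop("fewer than 100 unmasked bins")
  if (isTRUE(params$pseudolog)) y <- log1p(y)
  ym <- y[mask]; xm <- x[mask]
  out <- rep(NA_real_, length(y))
  if (stats::sd(xm) == 0) {
    out[mask] <- ym - mean(ym)
  } else {
    fit_idx <- seq_along(xm)
    if (length(xm) > params$max_fit_points)
      fit_idx <- with_seed(params$subsample_seed,
                           sort(sample.int(length(xm), params$max_fit_points)))
    fit <- stats::loess(
      ym[fit_idx] ~ xm[fit_idx], span = params$loess_span,
      degree = params$loess_degree, family = "gaussian",
      control = stats::loess.control(surface = "interpolate",
                                     statistics = "none"))
    rng <- range(xm[fit_idx])
    pred <- stats::predict(fit, newdata = pmin(pmax(xm, rng[1]), rng[2]))
    out[mask] <- ym - pred
  }
  track_like(values, ifelse(is.na(out), 0, out), mask)
}

#' Correct 1D read counts for restriction-site density and GC content
#'
#' Masks bins with mappability below `params$mappability_min`, then
#' takes loess residuals against RE density and, of those residuals,
#' against GC content — in that order. The result is the
#' doubly-corrected track prior to Z-scoring.
#'
#' @param track Binned read counts (a [binned_track()]).
#' @param re_density,gc,mappability Covariate [binned_track()]s on the
#'   same grid.
#' @param params A [correction_params()].
#' @return The corrected [binned_track()].
#' @export
correct_visibility <- function(track, re_density, gc, mappability,
                               params = correction_params()) {
  stop_unless_same_grid(track, re_density, gc, mappability)
  mask <- track_mask(track) &
    (track_values(mappability, masked_as_na = FALSE) >= params$mappability_min) &
    track_mask(mappability)
  masked <- track_like(track, track_values(track, masked_as_na = FALSE), mask)
  r1 <- loess_residuals(masked, re_density, params)
  p2 <- params
  p2$pseudolog <- FALSE  # residuals are already on the fitted scale
  loess_residuals(r1, gc, p2)
}

#' Z-score a track genome-wide
#'
#' Standardizes unmasked values to zero mean and unit variance (sample
#' standard deviation, denominator n - 1).
#'
#' @param track A [binned_track()] with at least 2 unmasked bins.
#' @return The standardized [binned_track()]; mask preserved.
#' @export
zscore_track <- function(track) {
  v <- track_values(track)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least 2 unmasked bins")
  s <- stats::sd(v[ok])
  if (s == 0) stop("zero standard deviation; cannot Z-score")
  z <- (track_values(track, masked_as_na = FALSE) - mean(v[ok])) / s
  track_like(track, z, track_mask(track))
}
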