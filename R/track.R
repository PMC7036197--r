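#' Fixed-resolution binned genomic signal
#'
#' A `binned_track` stores one numeric value per fixed-size genomic bin,
#' together with a per-bin usability mask. Coordinates are 0-based,
#' half-open: bin `b` (0-based) of a chromosome covers
#' `[b * bin_size, (b + 1) * bin_size)`; the last bin of a chromosome may
#' be shorter than `bin_size`. Masked bins (mask `FALSE`) carry no value
#' in downstream statistics.
#'
#' @param values Named list of per-chromosome numeric vectors, one element
#'   per bin.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Defaults to `length(values[[chrom]]) * bin_size`.
#' @param mask Named list of per-chromosome logical vectors (`TRUE` =
#'   usable). Defaults to all `TRUE`; `NA` values are masked in addition.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_lengths = NULL, mask = NULL) {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)),
            is.numeric(bin_size), length(bin_size) == 1, bin_size > 0)
  chroms <- names(values)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(values, length, 0L) * bin_size
    names(chrom_lengths) <- chroms
  }
  if (!setequal(names(chrom_lengths), chroms))
    stop("chrom_lengths must name the same chromosomes as values")
  chrom_lengths <- chrom_lengths[chroms]
  nb <- ceiling(chrom_lengths / bin_size)
  for (ch in chroms) {
    if (length(values[[ch]]) != nb[[ch]])
      stop(sprintf("chromosome %s: %d values for %d bins", ch,
                   length(values[[ch]]), nb[[ch]]))
  }
  if (is.null(mask)) {
    mask <- lapply(values, function(v) !is.na(v))
  } else {
    if (!setequal(names(mask), chroms)) stop("mask chromosomes mismatch")
    mask <- mask[chroms]
    for (ch in chroms) {
      if (length(mask[[ch]]) != nb[[ch]]) stop("mask length mismatch on ", ch)
      mask[[ch]] <- mask[[ch]] & !is.na(values[[ch]])
    }
  }
  structure(list(values = values, mask = mask, bin_size = bin_size,
                 chrom_lengths = chrom_lengths),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- vapply(x$values, length, 0L)
  cat(sprintf("binned_track: %d chromosome(s), %d bins of %g bp (%d masked)\n",
              length(x$values), sum(nb), x$bin_size,
              sum(!unlist(x$mask, use.names = FALSE))))
  v <- track_values(x)
  if (any(!is.na(v)))
    cat(sprintf("  values: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
                mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method base::summary
summary.binned_track <- function(object, ...) {
  v <- track_values(object)
  c(n_bins = length(v), n_masked = sum(is.na(v)),
    summary(v[!is.na(v)]))
}

#' Unlist a track's values genome-wide
#'
#' @param x A `binned_track`.
#' @param masked_as_na Replace masked bins by `NA` (default `TRUE`).
#' @return Numeric vector over all chromosomes in track order.
#' @export
track_values <- function(x, masked_as_na = TRUE) {
  v <- unlist(x$values, use.names = FALSE)
  if (masked_as_na) v[!unlist(x$mask, use.names = FALSE)] <- NA_real_
  v
}

#' Genome-wide mask of a track
#' @param x A `binned_track`.
#' @return Logical vector, `TRUE` for usable bins.
#' @export
track_mask <- function(x) unlist(x$mask, use.names = FALSE)

# Same chromosomes, bin size and bin counts.
same_grid <- function(a, b) {
  identical(names(a$values), names(b$values)) &&
    isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    identical(vapply(a$values, length, 0L), vapply(b$values, length, 0L))
}

stop_unless_same_grid <- function(...) {
  tr <- list(...)
  for (i in seq_along(tr)[-1])
    if (!same_grid(tr[[1]], tr[[i]]))
      stop("tracks are not on the same bin grid")
  invisible(TRUE)
}

# Build a track shaped like `template` from a genome-wide vector.
track_like <- function(template, values_flat, mask_flat = NULL) {
  nb <- vapply(template$values, length, 0L)
  idx <- rep(seq_along(nb), nb)
  values <- split(values_flat, idx)
  names(values) <- names(template$values)
  mask <- if (is.null(mask_flat)) NULL else {
    m <- split(mask_flat, idx)
    names(m) <- names(template$values)
    m
  }
  binned_track(values, template$bin_size, template$chrom_lengths, mask)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Moving average with truncated windows at the edges (window = 2k+1-ish;
# `half` bins on each side, partial near chromosome ends).
moving_average <- function(x, window) {
  n <- length(x)
  half_l <- floor((window - 1) / 2)
  half_r <- window - 1 - half_l
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
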