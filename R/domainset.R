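#' Construct a domain set
#'
#' A `domain_set` is an ordered, non-overlapping segmentation of each
#' chromosome into intervals labeled `condensed`, `decondensed` or
#' `ambiguous`, each carrying the sign proportion that supported the
#' label. Consecutive intervals share boundaries (the set tiles each
#' chromosome). Coordinates are 0-based half-open bp.
#'
#' @param chrom,start,end,state,proportion Vectors of equal length (or a
#'   single data.frame passed as `chrom`).
#' @return A data.frame of class `domain_set` with those five columns,
#'   sorted by chromosome then start.
#' @export
domain_set <- function(chrom, start = NULL, end = NULL, state = NULL,
                       proportion = NULL) {
  if (is.data.frame(chrom)) {
    d <- chrom
  } else {
    d <- data.frame(chrom = chrom, start = start, end = end, state = state,
                    proportion = proportion, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "state", "proportion") %in%
                  names(d)))
  if (!all(d$state %in% c("condensed", "decondensed", "ambiguous")))
    stop("state must be condensed, decondensed or ambiguous")
  if (any(d$end <= d$start)) stop("empty or inverted interval")
  d <- d[order(match(d$chrom, unique(d$chrom)), d$start), , drop = FALSE]
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)]))
      stop("overlapping intervals on ", ch)
  }
  rownames(d) <- NULL
  class(d) <- c("domain_set", "data.frame")
  d
}

#' @export
print.domain_set <- function(x, ...) {
  tab <- tapply((x$end - x$start) / 1e6, x$state, sum)
  cat(sprintf("domain_set: %d intervals on %d chromosome(s)\n", nrow(x),
              length(unique(x$chrom))))
  for (s in names(tab))
    cat(sprintf("  %-11s %4d intervals, %8.2f Mb\n", s, sum(x$state == s),
                tab[[s]]))
  invisible(x)
}

# Apportion interval values onto a regular bin grid of one chromosome.
# Each interval contributes value * overlap_bp / interval_bp to a bin
# (or raw overlap bp when per_bp = TRUE). Vectorized over intervals.
apportion_to_bins <- function(start, end, value, bin_size, n_bins,
                              per_bp = FALSE) {
  out <- numeric(n_bins)
  if (length(start) == 0) return(out)
  first <- pmax(floor(start / bin_size), 0)
  last <- pmin(floor((end - 1) / bin_size), n_bins - 1)
  nspan <- pmax(last - first + 1, 0)
  keep <- nspan > 0
  if (!any(keep)) return(out)
  idx <- rep(which(keep), nspan[keep])
  b <- sequence(nspan[keep]) - 1 + first[idx]
  ov <- pmin(end[idx], (b + 1) * bin_size) - pmax(start[idx], b * bin_size)
  w <- if (per_bp) ov else value[idx] * ov / (end[idx] - start[idx])
  acc <- rowsum(w, b)
  out[as.integer(rownames(acc)) + 1] <- acc[, 1]
  out
}

#' Map domain states onto a bin grid
#'
#' Assigns each fixed-size bin the state covering more than half of its
#' length: `"C"` for condensed, `"D"` for decondensed, `"other"` when
#' neither state reaches a majority (including majority-ambiguous bins).
#'
#' @param domains A [domain_set()].
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named chromosome lengths in bp; defaults to the
#'   maximum domain end per chromosome.
#' @return Named list of per-chromosome character vectors in
#'   `c("C", "D", "other")`.
#' @export
domain_bin_states <- function(domains, bin_size, chrom_lengths = NULL) {
  chroms <- unique(domains$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(domains$end[domains$chrom == ch]), 0)
  }
  out <- list()
  for (ch in chroms) {
    n <- ceiling(chrom_lengths[[ch]] / bin_size)
    d <- domains[domains$chrom == ch, ]
    width <- pmin(seq_len(n) * bin_size, chrom_lengths[[ch]]) -
      (seq_len(n) - 1) * bin_size
    cb <- apportion_to_bins(d$start[d$state == "condensed"],
                            d$end[d$state == "condensed"],
                            NULL, bin_size, n, per_bp = TRUE)
    db <- apportion_to_bins(d$start[d$state == "decondensed"],
                            d$end[d$state == "decondensed"],
                            NULL, bin_size, n, per_bp = TRUE)
    st <- rep("other", n)
    st[cb > width / 2] <- "C"
    st[db > width / 2] <- "D"
    out[[ch]] <- st
  }
  out
}
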