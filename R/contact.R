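#' Binned contact matrix
#'
#' Symmetric binned contact data stored as an upper-triangular sparse
#' triplet list tied to a genome-wide bin table. Bin ids are dense,
#' 0-based and sorted by (chromosome, start); internally entries index
#' rows of the bin table 1-based with `i <= j`.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `bin_id`
#'   (0-based, dense, sorted).
#' @param entries data.frame with columns `i`, `j` (1-based row indices
#'   into `bins`) and `value` (finite, non-negative).
#' @param resolution Bin width in bp.
#' @param allow_negative Permit negative values (used for unclipped
#'   DiSCO output; input matrices are always non-negative).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, entries, resolution,
                           allow_negative = FALSE) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "bin_id") %in% names(bins)),
            is.data.frame(entries),
            all(c("i", "j", "value") %in% names(entries)))
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
    stop("bin_ids must be dense and sorted")
  if (nrow(entries)) {
    if (any(entries$i < 1 | entries$j > nrow(bins)))
      stop("entry indices out of range")
    if (any(!is.finite(entries$value)) ||
        (!allow_negative && any(entries$value < 0)))
      stop("entry values must be finite and non-negative")
    sw <- entries$i > entries$j
    if (any(sw)) {
      tmp <- entries$i[sw]
      entries$i[sw] <- entries$j[sw]
      entries$j[sw] <- tmp
    }
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(bins = bins, entries = entries, resolution = resolution),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins (%g bp) on %d chromosome(s), %d entries, sum %.4g\n",
    nrow(x$bins), x$resolution, length(unique(x$bins$chrom)),
    nrow(x$entries), sum(x$entries$value)))
  invisible(x)
}

# Genome-wide bin table for given chromosome lengths.
matrix_bins <- function(chrom_lengths, bin_size) {
  rows <- lapply(names(chrom_lengths), function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / bin_size)
    s <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = ch, start = s,
               end = pmin(s + bin_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, rows)
  b$bin_id <- seq_len(nrow(b)) - 1L
  b
}

# Symmetric per-bin marginal of a triplet list (diagonal counted once).
entry_marginals <- function(i, j, value, n_bins) {
  out <- numeric(n_bins)
  off <- i != j
  acc <- rowsum(c(value, value[off]), c(i, j[off]))
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' 1D coverage of a contact matrix
#'
#' Sums each column of the full symmetric matrix (the diagonal counted
#' once), the marginal used to compare condensed and decondensed
#' coverage in contact data.
#'
#' @param matrix A [contact_matrix()].
#' @return A [binned_track()] at the matrix resolution. Bins dropped by
#'   balancing (if any) are masked.
#' @export
matrix_coverage_1d <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  cov <- entry_marginals(matrix$entries$i, matrix$entries$j,
                         matrix$entries$value, nrow(matrix$bins))
  chroms <- unique(matrix$bins$chrom)
  chrom_lengths <- vapply(chroms, function(ch)
    max(matrix$bins$end[matrix$bins$chrom == ch]), 0)
  values <- split(cov, match(matrix$bins$chrom, chroms))
  names(values) <- chroms
  tr <- binned_track(values, matrix$resolution, chrom_lengths)
  dropped <- attr(matrix, "dropped")
  if (length(dropped)) {
    m <- track_mask(tr)
    m[dropped] <- FALSE
    tr <- track_like(tr, track_values(tr, masked_as_na = FALSE), m)
  }
  tr
}
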