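#' Read a bedGraph file
#'
#' Four whitespace-delimited columns (chrom, start, end, value),
#' 0-based half-open. `track`, `browser` and comment lines are
#' skipped. Records with `end <= start` are rejected individually with
#' a warning naming the line; a non-numeric value rejects the whole
#' file.
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`,
#'   sorted by chromosome (order of first appearance) then start.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^\\s*(track|browser|#)", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (length(keep) == 0) stop("no data lines in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  ncol_ok <- lengths(parts) >= 4
  if (any(!ncol_ok))
    stop("line ", keep[which(!ncol_ok)[1]], ": fewer than 4 columns")
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4)))
  if (anyNA(start) || anyNA(end))
    stop("line ", keep[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinate")
  if (anyNA(value))
    stop("line ", keep[which(is.na(value))[1]],
         ": non-numeric value; file rejected")
  bad <- end <= start
  if (any(bad)) {
    warning(sum(bad), " record(s) with end <= start rejected (first at line ",
            keep[which(bad)[1]], ")")
    chrom <- chrom[!bad]; start <- start[!bad]
    end <- end[!bad]; value <- value[!bad]
  }
  d <- data.frame(chrom = chrom, start = start, end = end, value = value,
                  stringsAsFactors = FALSE)
  d <- d[order(match(d$chrom, unique(d$chrom)), d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a track (or intervals) as bedGraph
#'
#' Tracks are written one record per unmasked bin; masked bins are
#' omitted. A plain interval data.frame is written as is.
#'
#' @param x A [binned_track()] or a data.frame with `chrom`, `start`,
#'   `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  if (inherits(x, "binned_track")) {
    rows <- lapply(names(x$values), function(ch) {
      ok <- which(x$mask[[ch]])
      if (length(ok) == 0) return(NULL)
      s <- (ok - 1) * x$bin_size
      data.frame(chrom = ch, start = s,
                 end = pmin(s + x$bin_size, x$chrom_lengths[[ch]]),
                 value = x$values[[ch]][ok], stringsAsFactors = FALSE)
    })
    x <- do.call(rbind, rows)
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), formatC(x$value, digits = 10,
                                              format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a bedGraph interval table into a binned track
#'
#' Convenience wrapper around [bin_reads()].
#'
#' @inheritParams bin_reads
#' @export
bedgraph_to_track <- function(intervals, bin_size, chrom_lengths = NULL)
  bin_reads(intervals, bin_size, chrom_lengths)

#' Read a COO triplet contact matrix with its bin table
#'
#' The bin table is TSV `chrom start end bin_id` with dense, sorted
#' 0-based ids; the matrix file is `bin1_id bin2_id count`. Triplets
#' are canonicalized to the upper triangle and duplicate pairs are
#' summed. Out-of-range ids and negative counts reject the file with
#' the offending line number.
#'
#' @param matrix_path,bins_path File paths.
#' @return A [contact_matrix()].
#' @export
read_matrix_coo <- function(matrix_path, bins_path) {
  bins <- utils::read.table(bins_path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "bin_id"),
                            stringsAsFactors = FALSE)
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
    stop("bin ids must be dense, 0-based and sorted")
  trip <- utils::read.table(matrix_path, header = FALSE,
                            col.names = c("bin1", "bin2", "value"))
  out_of_range <- trip$bin1 < 0 | trip$bin1 >= nrow(bins) |
    trip$bin2 < 0 | trip$bin2 >= nrow(bins)
  if (any(out_of_range))
    stop("line ", which(out_of_range)[1], ": bin id out of range")
  if (any(trip$value < 0))
    stop("line ", which(trip$value < 0)[1], ": negative count")
  i <- pmin(trip$bin1, trip$bin2) + 1L
  j <- pmax(trip$bin1, trip$bin2) + 1L
  key <- i * (nrow(bins) + 1) + j
  if (anyDuplicated(key)) {
    acc <- rowsum(trip$value, key)
    key_u <- as.numeric(rownames(acc))
    i <- as.integer(key_u %/% (nrow(bins) + 1))
    j <- as.integer(key_u %% (nrow(bins) + 1))
    entries <- data.frame(i = i, j = j, value = acc[, 1])
  } else {
    entries <- data.frame(i = i, j = j, value = trip$value)
  }
  res <- stats::median(bins$end - bins$start)
  contact_matrix(bins, entries, res)
}

#' Write a contact matrix as COO triplets plus a bin table
#'
#' @param matrix A [contact_matrix()].
#' @param matrix_path,bins_path Output paths.
#' @export
write_matrix_coo <- function(matrix, matrix_path, bins_path) {
  b <- matrix$bins
  writeLines(sprintf("%s\t%d\t%d\t%d", b$chrom, as.integer(b$start),
                     as.integer(b$end), as.integer(b$bin_id)), bins_path)
  e <- matrix$entries
  writeLines(sprintf("%d\t%d\t%s", e$i - 1L, e$j - 1L,
                     formatC(e$value, digits = 10, format = "g")),
             matrix_path)
  invisible(matrix_path)
}

#' Write a domain set as BED6
#'
#' Name is the state; score is `round(1000 * proportion)`; strand is
#' `"."`.
#'
#' @param domains A [domain_set()].
#' @param path Output path.
#' @export
write_domains_bed <- function(domains, path) {
  score <- round(1000 * ifelse(is.na(domains$proportion), 0,
                               domains$proportion))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", domains$chrom,
                     as.integer(domains$start), as.integer(domains$end),
                     domains$state, as.integer(score)), path)
  invisible(path)
}

#' Read a BED6 domain file back into a domain set
#'
#' @param path File path (as written by [write_domains_bed()]).
#' @return A [domain_set()].
#' @export
read_domains_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[1:5] <- c("chrom", "start", "end", "state", "score")
  domain_set(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                        state = d$state, proportion = d$score / 1000,
                        stringsAsFactors = FALSE))
}

#' Write all synthetic outputs of one simulated genome
#'
#' bedGraph tracks for counts and covariates, BED6 for the true
#' domains (score = `1000 * visibility`), the contact matrix as COO +
#' bin table, and a JSON sidecar with the full generator spec.
#'
#' @param truth A `synthetic_truth`.
#' @param outdir Output directory (created if missing).
#' @param matrix Also simulate and write the contact matrix.
#' @return `outdir`, invisibly.
#' @export
write_synthetic_outputs <- function(truth, outdir, matrix = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  covs <- generate_covariates(truth)
  counts <- simulate_counts(truth, covs$gc, covs$re_density)
  write_bedgraph(covs$gc, file.path(outdir, "gc.bedGraph"))
  write_bedgraph(covs$re_density, file.path(outdir, "re_density.bedGraph"))
  write_bedgraph(covs$mappability, file.path(outdir, "mappability.bedGraph"))
  write_bedgraph(counts, file.path(outdir, "counts.bedGraph"))
  d <- truth$domains
  v <- ifelse(d$state == "condensed", truth$spec$visibility_delta, 1)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", d$chrom, as.integer(d$start),
                     as.integer(d$end), d$state, as.integer(round(1000 * v))),
             file.path(outdir, "true_domains.bed"))
  if (matrix) {
    cm <- simulate_matrix(truth)
    write_matrix_coo(cm, file.path(outdir, "matrix.coo"),
                     file.path(outdir, "bins.tsv"))
  }
  spec <- truth$spec
  spec$chrom_lengths <- as.list(spec$chrom_lengths)
  jsonlite::write_json(unclass(spec), file.path(outdir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read and validate a run configuration
#'
#' A YAML document with optional sections `synthetic`, `correction` and
#' `domain_calling` plus top-level `seed`; unknown keys anywhere are
#' rejected. Section contents are validated by the corresponding
#' parameter constructors.
#'
#' @param path YAML file path.
#' @return List with elements `synthetic` ([synthetic_spec()]),
#'   `correction` ([correction_params()]), `domain_calling`
#'   ([domain_call_params()]) and `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("synthetic", "correction", "domain_calling", "seed")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_args <- function(args, fn, section) {
    if (is.null(args)) return(list())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown key(s) in ", section, ": ", paste(bad, collapse = ", "))
    args
  }
  syn <- cfg$synthetic
  if (!is.null(syn)) {
    syn <- check_args(syn, synthetic_spec, "synthetic")
    if (!is.null(syn$chrom_lengths)) syn$chrom_lengths <-
        as.numeric(unlist(syn$chrom_lengths))
    if (!is.null(syn$chrom_names)) syn$chrom_names <-
        as.character(unlist(syn$chrom_names))
    if (!is.null(syn$gc_range)) syn$gc_range <- as.numeric(unlist(syn$gc_range))
    if (!is.null(cfg$seed) && is.null(syn$seed)) syn$seed <- cfg$seed
  }
  list(
    synthetic = if (is.null(syn)) NULL else do.call(synthetic_spec, syn),
    correction = do.call(correction_params,
                         check_args(cfg$correction, correction_params,
                                    "correction")),
    domain_calling = do.call(domain_call_params,
                             check_args(cfg$domain_calling,
                                        domain_call_params, "domain_calling")),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
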