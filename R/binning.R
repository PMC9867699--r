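#' Fixed-width genome binning
#'
#' Tiles every chromosome with consecutive fixed-width bins (the last bin of
#' a chromosome may be short). Bin indices are contiguous row numbers ordered
#' by chromosome order, then start. Coordinates are 0-based half-open
#' internally, matching BED/bedGraph on disk.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, in
#'   the desired chromosome order.
#' @param bin_size Bin width in bp.
#' @param bin_size_overrides Optional named vector giving a different bin
#'   width for specific chromosomes (e.g. a finer-binned artificial rDNA
#'   chromosome).
#' @return A `GenomeBinning` object: list with `chrom_sizes`, `bin_size`,
#'   `bin_size_by_chrom`, `bins` (data.frame with `chrom`, `start`, `end`)
#'   and `n` (bin count).
#' @export
genome_binning <- function(chrom_sizes, bin_size,
                           bin_size_overrides = NULL) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
            !is.null(names(chrom_sizes)), all(chrom_sizes >= 1),
            is.numeric(bin_size), length(bin_size) == 1, bin_size >= 1)
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names in chrom_sizes")
  bin_size <- as.integer(bin_size)
  bs <- stats::setNames(rep(bin_size, length(chrom_sizes)),
                        names(chrom_sizes))
  if (!is.null(bin_size_overrides)) {
    stopifnot(all(names(bin_size_overrides) %in% names(chrom_sizes)))
    bs[names(bin_size_overrides)] <- as.integer(bin_size_overrides)
  }
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    len <- as.numeric(chrom_sizes[[ch]])
    starts <- seq(0, len - 1, by = bs[[ch]])
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bs[[ch]], len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  rownames(bins) <- NULL
  structure(list(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 bin_size_by_chrom = bs, bins = bins, n = nrow(bins)),
            class = "GenomeBinning")
}

#' @export
print.GenomeBinning <- function(x, ...) {
  cat(sprintf("GenomeBinning: %d chromosomes, bin size %d bp, %d bins\n",
              length(x$chrom_sizes), x$bin_size, x$n))
  invisible(x)
}

#' Number of bins in a binning
#' @param binning A `GenomeBinning`.
#' @return Integer bin count.
#' @export
n_bins <- function(binning) binning$n

#' First bin index (1-based) of each chromosome
#' @keywords internal
chrom_offsets <- function(binning) {
  idx <- which(!duplicated(binning$bins$chrom))
  stats::setNames(idx, binning$bins$chrom[idx])
}

#' Map genomic positions to bin indices
#'
#' @param binning A `GenomeBinning`.
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions.
#' @return Integer vector of 1-based bin row indices.
#' @export
bin_index <- function(binning, chrom, pos) {
  offs <- chrom_offsets(binning)
  if (!all(chrom %in% names(offs)))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[!chrom %in% names(offs)]), collapse = ", "))
  as.integer(offs[chrom] + pos %/% binning$bin_size_by_chrom[chrom])
}

same_binning <- function(a, b) {
  identical(a$bin_size_by_chrom, b$bin_size_by_chrom) &&
    identical(a$chrom_sizes, b$chrom_sizes)
}

#' Per-bin scalar track on a genome binning
#'
#' @param binning A `GenomeBinning`.
#' @param values Numeric vector, one value per bin; `NA` marks unmappable
#'   bins.
#' @return A `BinnedTrack`.
#' @export
binned_track <- function(binning, values) {
  stopifnot(inherits(binning, "GenomeBinning"),
            length(values) == binning$n)
  structure(list(binning = binning, values = as.numeric(values)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d bins (%d NA), range [%.4g, %.4g]\n",
              length(x$values), sum(is.na(x$values)),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Labelled genomic interval set
#'
#' Ordered, 0-based half-open intervals with a label and an optional score.
#' Intervals sharing one label must not overlap each other; intervals of
#' different labels may.
#'
#' @param chrom,start,end Interval coordinates (start < end, 0-based
#'   half-open).
#' @param label Character label per interval (e.g. "NAD", "hNAD", "TAD").
#' @param score Optional numeric score per interval.
#' @return A `DomainSet` (data.frame subclass), sorted by chromosome then
#'   start.
#' @export
domain_set <- function(chrom = character(), start = numeric(),
                       end = numeric(), label = "domain", score = NA_real_) {
  n <- length(chrom)
  d <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end),
                  label = rep_len(as.character(label), n),
                  score = rep_len(as.numeric(score), n),
                  stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(d$start >= d$end))
      stop("interval with start >= end at row(s): ",
           paste(which(d$start >= d$end), collapse = ", "))
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    rownames(d) <- NULL
    for (lab in unique(d$label)) {
      dl <- d[d$label == lab, , drop = FALSE]
      bad <- which(dl$chrom[-1] == dl$chrom[-nrow(dl)] &
                     dl$start[-1] < dl$end[-nrow(dl)])
      if (length(bad))
        stop(sprintf(
          "overlapping intervals within label '%s': %s:%d-%d and %s:%d-%d",
          lab, dl$chrom[bad[1]], dl$start[bad[1]], dl$end[bad[1]],
          dl$chrom[bad[1] + 1], dl$start[bad[1] + 1], dl$end[bad[1] + 1]))
    }
  }
  class(d) <- c("DomainSet", "data.frame")
  d
}

#' Convert a DomainSet to GRanges
#'
#' Coordinates become 1-based closed as GRanges requires.
#' @param domains A `DomainSet`.
#' @param label Optional label to subset to first.
#' @return A `GRanges` object.
#' @export
domains_to_granges <- function(domains, label = NULL) {
  d <- as.data.frame(domains)
  if (!is.null(label)) d <- d[d$label %in% label, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1, end = d$end),
    label = d$label, score = d$score)
}

#' Flag bins overlapping a domain set
#'
#' A bin is flagged when any part of it intersects an interval of the set.
#' @param binning A `GenomeBinning`.
#' @param domains A `DomainSet`.
#' @param label Optional label subset.
#' @return Logical vector over bins.
#' @export
bins_in_domains <- function(binning, domains, label = NULL) {
  out <- logical(binning$n)
  d <- as.data.frame(domains)
  if (!is.null(label)) d <- d[d$label %in% label, , drop = FALSE]
  if (nrow(d) == 0) return(out)
  gr_bins <- GenomicRanges::GRanges(
    binning$bins$chrom,
    IRanges::IRanges(binning$bins$start + 1, binning$bins$end))
  gr_dom <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1, d$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_dom)
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Merge contiguous flagged bins into intervals
#'
#' @param binning A `GenomeBinning`.
#' @param flags Logical vector over bins.
#' @param label Label for the resulting intervals.
#' @param score Optional per-bin score; each interval records the maximum
#'   over its bins.
#' @return A `DomainSet`.
#' @export
flags_to_domains <- function(binning, flags, label = "domain",
                             score = NULL) {
  stopifnot(length(flags) == binning$n)
  flags[is.na(flags)] <- FALSE
  b <- binning$bins
  # run starts: flagged bin whose predecessor is unflagged or on another chrom
  prev_same <- c(FALSE, flags[-binning$n] &
                   b$chrom[-1] == b$chrom[-binning$n])
  starts <- which(flags & !prev_same)
  if (length(starts) == 0)
    return(domain_set(label = label))
  ends <- vapply(starts, function(s) {
    e <- s
    while (e < binning$n && flags[e + 1L] && b$chrom[e + 1L] == b$chrom[s])
      e <- e + 1L
    e
  }, integer(1))
  sc <- if (is.null(score)) NA_real_ else
    mapply(function(s, e) suppressWarnings(max(score[s:e], na.rm = TRUE)),
           starts, ends)
  sc[!is.finite(sc)] <- NA_real_
  domain_set(chrom = b$chrom[starts], start = b$start[starts],
             end = b$end[ends], label = label, score = sc)
}
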