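#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#' @param path File path.
#' @return Named numeric vector in file order.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$size, d$chrom)
}

#' Read a bedGraph onto a genome binning
#'
#' Each bin's value is the length-weighted mean of overlapping bedGraph
#' records, counting uncovered parts of the bin as zero: the record mass
#' is distributed over the bases it covers, so partially overlapping
#' records contribute proportionally. Bins with no coverage get 0.
#'
#' @param path 4-column bedGraph (chrom, start, end, value; 0-based
#'   half-open).
#' @param binning A `GenomeBinning`; records on chromosomes absent from it
#'   are an error.
#' @return A `BinnedTrack`.
#' @export
read_bedgraph <- function(path, binning) {
  d <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = character(), V2 = numeric(),
                          V3 = numeric(), V4 = numeric()))
      stop("malformed bedGraph '", path, "': ", conditionMessage(e))
    })
  if (ncol(d) < 4)
    stop("bedGraph '", path, "' has fewer than 4 columns")
  names(d)[1:4] <- c("chrom", "start", "end", "value")
  vals <- numeric(binning$n)
  if (nrow(d) > 0) {
    bad <- which(!(d$chrom %in% names(binning$chrom_sizes)))
    if (length(bad))
      stop("bedGraph line ", bad[1], ": unknown chromosome '",
           d$chrom[bad[1]], "'")
    bad <- which(!is.finite(d$start) | !is.finite(d$end) |
                   d$start < 0 | d$start >= d$end)
    if (length(bad))
      stop("bedGraph line ", bad[1], ": invalid interval ",
           d$start[bad[1]], "-", d$end[bad[1]])
    gr_rec <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start + 1, d$end))
    b <- binning$bins
    gr_bins <- GenomicRanges::GRanges(
      b$chrom, IRanges::IRanges(b$start + 1, b$end))
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_rec)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(b$end[qi], d$end[si]) - pmax(b$start[qi], d$start[si])
    mass <- rowsum(ov * d$value[si], qi)
    idx <- as.integer(rownames(mass))
    vals[idx] <- mass[, 1] / (b$end[idx] - b$start[idx])
  }
  binned_track(binning, vals)
}

#' Write a BinnedTrack as bedGraph
#'
#' One record per bin; `NA` bins are omitted.
#' @param track A `BinnedTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  b <- track$binning$bins
  keep <- !is.na(track$values)
  d <- data.frame(b$chrom[keep], format(b$start[keep], scientific = FALSE,
                                        trim = TRUE),
                  format(b$end[keep], scientific = FALSE, trim = TRUE),
                  formatC(track$values[keep], format = "g", digits = 10))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a HiC-Pro style matrix + bed pair
#'
#' The bed companion lists the bins (chrom, start, end, 1-based id); the
#' matrix file holds triplets (id_i, id_j, count). Triplets are mirrored
#' into canonical upper-triangle storage; duplicate entries are summed.
#'
#' @param matrix_path Triplet matrix file.
#' @param bed_path Bin table; ids must be consecutive starting at 1.
#' @return A `ContactMatrix` on the binning implied by the bed file.
#' @export
read_contact_matrix <- function(matrix_path, bed_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric",
                                          "numeric", "integer"))
  names(bed) <- c("chrom", "start", "end", "id")
  if (!identical(bed$id, seq_len(nrow(bed))))
    stop("bed bin ids are not consecutive from 1")
  chroms <- unique(bed$chrom)
  sizes <- vapply(chroms, function(ch) max(bed$end[bed$chrom == ch]),
                  numeric(1))
  bs_chrom <- vapply(chroms, function(ch)
    max(bed$end[bed$chrom == ch] - bed$start[bed$chrom == ch]), numeric(1))
  bin_size <- max(bs_chrom)
  over <- bs_chrom[bs_chrom != bin_size]
  binning <- genome_binning(stats::setNames(sizes, chroms), bin_size,
                            bin_size_overrides =
                              if (length(over)) over else NULL)
  if (binning$n != nrow(bed) ||
      !all(binning$bins$start == bed$start &
             binning$bins$chrom == bed$chrom))
    stop("bed bins do not tile chromosomes at a fixed bin size")
  trip <- tryCatch(
    utils::read.table(matrix_path, sep = "\t", header = FALSE,
                      colClasses = c("integer", "integer", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = integer(), V2 = integer(), V3 = numeric()))
      stop("malformed matrix '", matrix_path, "': ", conditionMessage(e))
    })
  if (nrow(trip) > 0 &&
      (min(trip$V1, trip$V2) < 1 || max(trip$V1, trip$V2) > nrow(bed)))
    stop("triplet references bin id absent from bed")
  contact_matrix(binning, trip$V1, trip$V2, trip$V3)
}

#' Write a ContactMatrix in HiC-Pro matrix + bed dialect
#'
#' @param cm A `ContactMatrix`.
#' @param matrix_path,bed_path Output paths.
#' @export
write_contact_matrix <- function(cm, matrix_path, bed_path) {
  b <- cm$binning$bins
  utils::write.table(
    data.frame(b$chrom, format(b$start, scientific = FALSE, trim = TRUE),
               format(b$end, scientific = FALSE, trim = TRUE),
               seq_len(nrow(b))),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(cm$i, cm$j, formatC(cm$x, format = "g", digits = 12)),
    matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(matrix_path)
}

#' Write a DomainSet as BED5
#'
#' BED columns: chrom, start, end, label, score (score "." when NA).
#' @param domains A `DomainSet`.
#' @param path Output path.
#' @export
write_domains_bed <- function(domains, path) {
  d <- as.data.frame(domains)
  sc <- ifelse(is.na(d$score), ".",
               formatC(d$score, format = "g", digits = 10))
  utils::write.table(
    data.frame(d$chrom, format(d$start, scientific = FALSE, trim = TRUE),
               format(d$end, scientific = FALSE, trim = TRUE), d$label, sc),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4/BED5 file as a DomainSet
#'
#' Input may be unsorted; intervals are sorted on read. Overlap within one
#' label class is an error.
#' @param path BED file (0-based half-open).
#' @param default_label Label for 3-column records.
#' @return A `DomainSet`.
#' @export
read_domains_bed <- function(path, default_label = "domain") {
  d <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("malformed BED '", path, "': ", conditionMessage(e))
    })
  if (is.null(d)) return(domain_set())
  label <- if (ncol(d) >= 4) as.character(d$V4) else default_label
  score <- if (ncol(d) >= 5)
    suppressWarnings(as.numeric(ifelse(d$V5 == ".", NA, d$V5)))
  else NA_real_
  domain_set(chrom = d$V1, start = d$V2, end = d$V3,
             label = label, score = score)
}
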