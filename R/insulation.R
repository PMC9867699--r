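#' Diamond insulation score
#'
#' For each bin b, the mean (balanced) signal in the `w x w` square
#' spanning the `w` bins upstream by the `w` bins starting at b — the
#' contacts crossing the bin's left edge. The score is
#' `log2(diamond mean / chromosome mean of diamond means)`, so it is
#' invariant to global count scaling; bins within `w` of a chromosome
#' edge are `NA`.
#'
#' @param cm A `ContactMatrix`; balanced weights are used when present.
#' @param window_bins Diamond window size `w` in bins.
#' @return An `InsulationTrack` (`BinnedTrack` subclass with
#'   `window_bins`).
#' @export
insulation_score <- function(cm, window_bins = 10) {
  binning <- cm$binning
  balanced <- !is.null(cm$weights)
  score <- rep(NA_real_, binning$n)
  for (ch in names(binning$chrom_sizes)) {
    bi <- bins_of_chrom(binning, ch)
    n <- length(bi)
    if (n <= 2 * window_bins) {
      warning("chromosome ", ch, " shorter than insulation window, skipped")
      next
    }
    m <- dense_matrix(cm, bi, balanced = balanced)
    dm <- rep(NA_real_, n)
    for (b in (window_bins + 1):(n - window_bins + 1)) {
      sq <- m[(b - window_bins):(b - 1), b:(b + window_bins - 1)]
      dm[b] <- mean(sq, na.rm = TRUE)
    }
    mu <- mean(dm, na.rm = TRUE)
    if (is.finite(mu) && mu > 0) score[bi] <- log2(dm / mu)
  }
  out <- binned_track(binning, score)
  out$window_bins <- window_bins
  class(out) <- c("InsulationTrack", class(out))
  out
}

#' Call TAD boundaries at insulation minima
#'
#' Local minima of the insulation score whose prominence — the mean of
#' the flanking maxima (between neighbouring minima) minus the minimum —
#' reaches `delta_threshold` become boundaries; TADs are the intervals
#' between consecutive boundaries within each contiguous scored run.
#'
#' @param ins An `InsulationTrack`.
#' @param delta_threshold Minimum prominence.
#' @return List with `boundaries` (`DomainSet`, one bin per boundary,
#'   score = prominence) and `tads` (`DomainSet`).
#' @export
call_boundaries <- function(ins, delta_threshold = 0.1) {
  binning <- ins$binning
  b <- binning$bins
  bnd_idx <- integer(0); bnd_prom <- numeric(0)
  tad_chrom <- character(0); tad_start <- numeric(0); tad_end <- numeric(0)
  for (seg in track_segments(ins)) {
    v <- ins$values[seg]
    n <- length(v)
    if (n < 3) { seg_tads <- seg } else {
      is_min <- vapply(2:(n - 1), function(i)
        v[i] <= v[i - 1] & v[i] <= v[i + 1] &
          (v[i] < v[i - 1] | v[i] < v[i + 1]), logical(1))
      mins <- which(is_min) + 1
      # drop later members of flat minima runs
      if (length(mins) > 1)
        mins <- mins[c(TRUE, diff(mins) > 1 |
                         v[mins[-1]] != v[mins[-length(mins)]])]
      keep <- logical(length(mins))
      prom <- numeric(length(mins))
      for (k in seq_along(mins)) {
        lo <- if (k == 1) 1 else mins[k - 1]
        hi <- if (k == length(mins)) n else mins[k + 1]
        lmax <- max(v[lo:mins[k]]); rmax <- max(v[mins[k]:hi])
        prom[k] <- mean(c(lmax, rmax)) - v[mins[k]]
        keep[k] <- prom[k] >= delta_threshold
      }
      sel <- mins[keep]
      bnd_idx <- c(bnd_idx, seg[sel])
      bnd_prom <- c(bnd_prom, prom[keep])
      cuts <- c(1, sel, n + 1)
      for (k in seq_len(length(cuts) - 1)) {
        lo <- seg[cuts[k]]; hi <- seg[cuts[k + 1] - 1]
        tad_chrom <- c(tad_chrom, b$chrom[lo])
        tad_start <- c(tad_start, b$start[lo])
        tad_end <- c(tad_end, b$end[hi])
      }
      next
    }
    tad_chrom <- c(tad_chrom, b$chrom[seg_tads[1]])
    tad_start <- c(tad_start, b$start[seg_tads[1]])
    tad_end <- c(tad_end, b$end[seg_tads[length(seg_tads)]])
  }
  boundaries <- if (length(bnd_idx))
    domain_set(b$chrom[bnd_idx], b$start[bnd_idx], b$end[bnd_idx],
               label = "boundary", score = bnd_prom)
  else domain_set(label = "boundary")
  tads <- domain_set(tad_chrom, tad_start, tad_end, label = "TAD")
  list(boundaries = boundaries, tads = tads)
}

# boundary positions (bp) of a domain set: starts and ends
domain_edges <- function(domains) {
  if (nrow(domains) == 0)
    return(data.frame(chrom = character(), pos = numeric()))
  unique(data.frame(chrom = rep(domains$chrom, 2),
                    pos = c(domains$start, domains$end)))
}

#' NAD-boundary / TAD-boundary coincidence
#'
#' Matches each NAD edge to the nearest TAD boundary on the same
#' chromosome within `tolerance_bins` bins, and (when an insulation track
#' and hNAD flags are given) compares the absolute insulation score at
#' hNAD edges vs other-NAD edges with a two-sided Wilcoxon test.
#'
#' @param nads `DomainSet` of NADs, or a `NADCall`.
#' @param tad_boundaries `DomainSet` of boundary bins (from
#'   [call_boundaries()]).
#' @param binning The shared `GenomeBinning`.
#' @param tolerance_bins Matching tolerance.
#' @param insulation Optional `InsulationTrack` for the score comparison.
#' @return List: `edges` (per-edge data.frame with `matched`, `dist_bp`,
#'   `insulation`, `is_hnad`), `match_rate`, and `wilcox_p` when both
#'   optional inputs allow it.
#' @export
boundary_coincidence <- function(nads, tad_boundaries, binning,
                                 tolerance_bins = 1, insulation = NULL) {
  is_hnad_dom <- NULL
  if (inherits(nads, "NADCall")) {
    is_hnad_dom <- nads$is_hnad
    nads <- nads$nads
  }
  ne <- data.frame(chrom = rep(nads$chrom, 2),
                   pos = c(nads$start, nads$end),
                   is_hnad = if (is.null(is_hnad_dom)) NA else
                     rep(is_hnad_dom, 2))
  te <- tad_boundaries
  tol_bp <- tolerance_bins * binning$bin_size
  ne$dist_bp <- NA_real_
  for (i in seq_len(nrow(ne))) {
    cand <- te[te$chrom == ne$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    # distance from the edge position to the boundary bin interval
    d <- pmax(0, pmax(cand$start - ne$pos[i], ne$pos[i] - cand$end))
    ne$dist_bp[i] <- min(d)
  }
  ne$matched <- !is.na(ne$dist_bp) & ne$dist_bp <= tol_bp
  if (!is.null(insulation)) {
    inside <- pmin(pmax(ne$pos, 0), binning$chrom_sizes[ne$chrom] - 1)
    ne$insulation <- insulation$values[bin_index(binning, ne$chrom, inside)]
  }
  out <- list(edges = ne, match_rate = mean(ne$matched))
  if (!is.null(insulation) && !all(is.na(ne$is_hnad))) {
    a <- abs(ne$insulation[ne$is_hnad %in% TRUE])
    b <- abs(ne$insulation[ne$is_hnad %in% FALSE])
    if (sum(is.finite(a)) > 0 && sum(is.finite(b)) > 0)
      out$wilcox_p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  out
}

#' Inter-TAD interaction change between two conditions
#'
#' For each pair of adjacent TADs, the inter-TAD mean over the intra-TAD
#' mean of the O/E-normalized matrix, per condition; the change is
#' `log2(condition_b / condition_a)` (scale invariant). Pairs are
#' stratified by whether the shared boundary lies within
#' `tolerance_bins` of an hNAD edge; strata are compared with a
#' two-sided Wilcoxon test.
#'
#' @param cm_a,cm_b `ContactMatrix`es on the same binning.
#' @param tads `DomainSet` of TADs (shared between conditions).
#' @param hnads Optional `DomainSet` of hNADs for stratification.
#' @param tolerance_bins Boundary-matching tolerance.
#' @param min_bins TADs with fewer bins are excluded.
#' @return List: `pairs` (per-boundary data.frame with `change`,
#'   `at_hnad_boundary`), and `wilcox_p` when both strata are non-empty.
#' @export
inter_tad_change <- function(cm_a, cm_b, tads, hnads = NULL,
                             tolerance_bins = 1, min_bins = 2) {
  if (!same_binning(cm_a$binning, cm_b$binning))
    stop("condition matrices are on different binnings")
  binning <- cm_a$binning
  tol_bp <- tolerance_bins * binning$bin_size
  hnad_edges <- if (is.null(hnads)) NULL else domain_edges(hnads)
  res <- list()
  for (ch in unique(tads$chrom)) {
    td <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(td) < 2) next
    bi <- bins_of_chrom(binning, ch)
    oe_a <- oe_transform(dense_matrix(cm_a, bi,
                                      balanced = !is.null(cm_a$weights)))
    oe_b <- oe_transform(dense_matrix(cm_b, bi,
                                      balanced = !is.null(cm_b$weights)))
    off <- bi[1] - 1
    for (k in seq_len(nrow(td) - 1)) {
      if (td$end[k] != td$start[k + 1]) next  # not adjacent
      r1 <- (bin_index(binning, ch, td$start[k]) - off):
        (bin_index(binning, ch, td$end[k] - 1) - off)
      r2 <- (bin_index(binning, ch, td$start[k + 1]) - off):
        (bin_index(binning, ch, td$end[k + 1] - 1) - off)
      if (length(r1) < min_bins || length(r2) < min_bins) next
      ratio <- function(oe) {
        inter <- mean(oe[r1, r2], na.rm = TRUE)
        intra <- mean(c(mean(oe[r1, r1], na.rm = TRUE),
                        mean(oe[r2, r2], na.rm = TRUE)))
        inter / intra
      }
      ra <- ratio(oe_a); rb <- ratio(oe_b)
      if (!is.finite(ra) || !is.finite(rb) || ra <= 0 || rb <= 0) next
      at_hnad <- FALSE
      if (!is.null(hnad_edges)) {
        he <- hnad_edges[hnad_edges$chrom == ch, , drop = FALSE]
        at_hnad <- nrow(he) > 0 &&
          min(abs(he$pos - td$start[k + 1])) <= tol_bp
      }
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, boundary = td$start[k + 1],
        ratio_a = ra, ratio_b = rb, change = log2(rb / ra),
        at_hnad_boundary = at_hnad)
    }
  }
  pairs <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), boundary = numeric(),
               ratio_a = numeric(), ratio_b = numeric(),
               change = numeric(), at_hnad_boundary = logical())
  out <- list(pairs = pairs)
  a <- pairs$change[pairs$at_hnad_boundary]
  b <- pairs$change[!pairs$at_hnad_boundary]
  if (length(a) > 0 && length(b) > 0)
    out$wilcox_p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  out
}
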