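#' ICE balancing of a contact matrix
#'
#' Iterative correction toward equal per-bin visibility: finds per-bin
#' weights such that the row sums of the balanced matrix
#' (`count * w_i * w_j`) are equal across retained bins. Sparse bins with
#' log coverage more than `mad_filter` MADs below the median are masked
#' (`NA` weight) before iteration, as are zero-coverage bins. Weights are
#' scaled so the balanced total equals the raw total over retained
#' entries.
#'
#' @param cm A `ContactMatrix` of raw counts.
#' @param max_iter Maximum iterations.
#' @param tol Convergence: maximum relative deviation of retained row
#'   sums from their mean.
#' @param mad_filter MAD multiplier for the low-coverage mask.
#' @return The `ContactMatrix` with `weights` set.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5, mad_filter = 3) {
  n <- cm$binning$n
  cov <- bin_coverage(cm)
  retained <- cov > 0
  if (mad_filter > 0 && any(retained)) {
    lc <- log(cov[retained])
    cut <- stats::median(lc) - mad_filter * stats::mad(lc)
    retained[retained] <- lc >= cut
  }
  if (!any(retained)) stop("no bins retained for balancing")
  keep <- retained[cm$i] & retained[cm$j]
  i <- cm$i[keep]; j <- cm$j[keep]; x <- cm$x[keep]
  off <- i != j
  w <- rep(1, n)
  resid <- Inf
  for (iter in seq_len(max_iter)) {
    bx <- x * w[i] * w[j]
    r <- tapply_add(i, bx, n) + tapply_add(j[off], bx[off], n)
    rr <- r[retained]
    rbar <- mean(rr)
    resid <- max(abs(rr / rbar - 1))
    if (resid < tol) break
    b <- rep(1, n)
    b[retained] <- rr / rbar
    w <- w / b
  }
  if (resid >= tol)
    stop(sprintf(
      "ICE did not converge after %d iterations (residual %.3g > %.3g)",
      max_iter, resid, tol))
  # preserve total mass over retained entries
  bx <- x * w[i] * w[j]
  if (sum(bx) > 0) w <- w * sqrt(sum(x) / sum(bx))
  w[!retained] <- NA_real_
  cm$weights <- w
  cm
}

# observed/expected of a dense cis matrix: expected is the mean over each
# |i - j| diagonal (NA-aware); diagonals with zero mean stay NA
oe_transform <- function(m) {
  n <- nrow(m)
  d <- abs(row(m) - col(m))
  expd <- vapply(0:(n - 1), function(k)
    mean(m[d == k], na.rm = TRUE), numeric(1))
  expd[!is.finite(expd) | expd == 0] <- NA_real_
  m / expd[d + 1]
}

bins_of_chrom <- function(binning, ch) which(binning$bins$chrom == ch)

#' A/B compartment assignment from the first principal component
#'
#' Per chromosome: balanced cis matrix, observed/expected by diagonal,
#' Pearson correlation matrix, first eigenvector. The eigenvector sign is
#' oriented so its correlation with `orientation_track` (e.g. gene
#' density, or the planted A profile in simulations) is positive; bins
#' with positive PC1 are labelled A, negative B.
#'
#' @param cm A balanced `ContactMatrix`.
#' @param orientation_track `BinnedTrack` used to fix the eigenvector
#'   sign per chromosome.
#' @param min_bins Chromosomes with fewer informative bins are skipped
#'   with a warning.
#' @return A `CompartmentTrack`: `pc1` (`BinnedTrack`), `labels`
#'   (character "A"/"B"/NA per bin).
#' @export
compartment_pc1 <- function(cm, orientation_track, min_bins = 10) {
  if (is.null(cm$weights)) stop("balance the matrix first (ice_balance)")
  binning <- cm$binning
  stopifnot(same_binning(binning, orientation_track$binning))
  pc1 <- rep(NA_real_, binning$n)
  for (ch in names(binning$chrom_sizes)) {
    bi <- bins_of_chrom(binning, ch)
    m <- dense_matrix(cm, bi, balanced = TRUE)
    info <- which(!is.na(cm$weights[bi]) & colSums(m, na.rm = TRUE) > 0)
    if (length(info) < min_bins) {
      warning("chromosome ", ch, ": fewer than ", min_bins,
              " informative bins, skipped")
      next
    }
    oe <- oe_transform(m[info, info, drop = FALSE])
    oe[!is.finite(oe)] <- NA_real_
    cc <- suppressWarnings(stats::cor(oe, use = "pairwise.complete.obs"))
    ok <- which(apply(cc, 1, function(r) sum(is.finite(r)) > 2))
    if (length(ok) < min_bins) {
      warning("chromosome ", ch, ": degenerate correlation structure, skipped")
      next
    }
    cc <- cc[ok, ok, drop = FALSE]
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    v <- ev$vectors[, 1]
    ref <- orientation_track$values[bi][info][ok]
    if (sum(v * ref, na.rm = TRUE) < 0) v <- -v
    pc1[bi[info][ok]] <- v
  }
  structure(list(pc1 = binned_track(binning, pc1),
                 labels = ifelse(is.na(pc1), NA_character_,
                                 ifelse(pc1 > 0, "A", "B"))),
            class = "CompartmentTrack")
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  tb <- table(factor(x$labels, c("A", "B")))
  cat(sprintf("CompartmentTrack: %d A bins, %d B bins, %d unassigned\n",
              tb["A"], tb["B"], sum(is.na(x$labels))))
  invisible(x)
}

#' Compartment saddle and strength
#'
#' Bins are ranked genome-wide by PC1 into `n_quantiles` quantiles
#' (ascending: quantile 1 = strongest B). The saddle is the mean cis
#' observed/expected per quantile pair; compartment strength is
#' `sqrt(AA * BB) / AB` where the corners are the extreme
#' `corner_frac` quantiles.
#'
#' @param cm A balanced `ContactMatrix`.
#' @param compartments A `CompartmentTrack` (or a `BinnedTrack` of PC1).
#' @param n_quantiles Saddle grid size.
#' @param corner_frac Fraction of quantiles counted as each corner.
#' @return A `SaddleSummary`: `saddle` matrix, `strength`, corner means
#'   `AA`, `BB`, `AB`.
#' @export
saddle_strength <- function(cm, compartments, n_quantiles = 10,
                            corner_frac = 0.2) {
  if (is.null(cm$weights)) stop("balance the matrix first (ice_balance)")
  pc1 <- if (inherits(compartments, "CompartmentTrack"))
    compartments$pc1$values else compartments$values
  binning <- cm$binning
  qrank <- rep(NA_integer_, binning$n)
  ok <- is.finite(pc1)
  qrank[ok] <- as.integer(cut(rank(pc1[ok], ties.method = "first"),
                              breaks = n_quantiles, labels = FALSE))
  ssum <- matrix(0, n_quantiles, n_quantiles)
  scnt <- matrix(0, n_quantiles, n_quantiles)
  for (ch in names(binning$chrom_sizes)) {
    bi <- bins_of_chrom(binning, ch)
    oe <- oe_transform(dense_matrix(cm, bi, balanced = TRUE))
    q <- qrank[bi]
    sel <- which(!is.na(q))
    if (length(sel) == 0) next
    oes <- oe[sel, sel, drop = FALSE]
    qs <- q[sel]
    qi <- matrix(qs, length(qs), length(qs))
    cls <- qi + (t(qi) - 1L) * n_quantiles  # column-major saddle index
    fin <- is.finite(oes)
    if (any(fin)) {
      add <- rowsum(oes[fin], cls[fin])
      cnt <- rowsum(rep(1, sum(fin)), cls[fin])
      at <- as.integer(rownames(add))
      ssum[at] <- ssum[at] + add[, 1]
      scnt[at] <- scnt[at] + cnt[, 1]
    }
  }
  saddle <- ssum / scnt
  k <- max(1L, round(corner_frac * n_quantiles))
  lo <- seq_len(k); hi <- n_quantiles + 1 - seq_len(k)
  bb <- mean(saddle[lo, lo], na.rm = TRUE)
  aa <- mean(saddle[hi, hi], na.rm = TRUE)
  ab <- mean(c(saddle[lo, hi], saddle[hi, lo]), na.rm = TRUE)
  structure(list(saddle = saddle, n_quantiles = n_quantiles,
                 corner_frac = corner_frac, AA = aa, BB = bb, AB = ab,
                 strength = sqrt(aa * bb) / ab),
            class = "SaddleSummary")
}

#' @export
print.SaddleSummary <- function(x, ...) {
  cat(sprintf(
    "SaddleSummary: %dx%d, AA %.3f, BB %.3f, AB %.3f, strength %.3f\n",
    x$n_quantiles, x$n_quantiles, x$AA, x$BB, x$AB, x$strength))
  invisible(x)
}

#' Partition of total contacts by cis/trans and compartment pair class
#'
#' @param cm A `ContactMatrix` (raw counts).
#' @param compartments A `CompartmentTrack`.
#' @return List with `fractions` (named: cisAA, cisBB, cisAB, transAA,
#'   transBB, transAB; sums to 1 over labelled pairs), `excluded_fraction`
#'   (count share involving unlabeled bins), `counts`.
#' @export
interaction_partition <- function(cm, compartments) {
  lab <- compartments$labels
  chrom <- bin_chrom(cm$binning)
  li <- lab[cm$i]; lj <- lab[cm$j]
  labelled <- !is.na(li) & !is.na(lj)
  cis <- chrom[cm$i] == chrom[cm$j]
  pair <- ifelse(li == lj, paste0(li, li), "AB")
  cls <- paste0(ifelse(cis, "cis", "trans"), pair)
  counts <- stats::setNames(numeric(6),
                            c("cisAA", "cisBB", "cisAB",
                              "transAA", "transBB", "transAB"))
  agg <- tapply(cm$x[labelled], cls[labelled], sum)
  counts[names(agg)] <- agg
  tot <- sum(counts)
  list(fractions = if (tot > 0) counts / tot else counts,
       excluded_fraction = if (cm$total > 0)
         sum(cm$x[!labelled]) / cm$total else 0,
       counts = counts)
}
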