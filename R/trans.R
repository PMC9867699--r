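# per-bin hNAD membership index (0 = none); hNADs never overlap, so the
# assignment is unique
hnad_bin_assignment <- function(binning, hnads) {
  assign <- integer(binning$n)
  for (k in seq_len(nrow(hnads))) {
    fl <- bins_in_domains(binning, hnads[k, , drop = FALSE])
    assign[fl] <- k
  }
  assign
}

#' hNAD-by-hNAD mean normalized interaction matrix
#'
#' Entry (p, q) is the total contact count between bins of hNAD p and
#' hNAD q, scaled to reads per million of the whole matrix, divided by
#' the number of bin pairs (`n_bins_p * n_bins_q`) — a mean per-bin-pair
#' RPM, invariant to uniform count rescaling.
#'
#' @param cm A `ContactMatrix` of raw counts.
#' @param hnads A `DomainSet` of hNADs.
#' @return An `HnadInteractionMatrix`: `matrix`, `cis_mask`, `hnads`,
#'   `n_bins` per hNAD, `chrom` per hNAD.
#' @export
hnad_interaction_matrix <- function(cm, hnads) {
  if (nrow(hnads) == 0) stop("empty hNAD set")
  binning <- cm$binning
  assign <- hnad_bin_assignment(binning, hnads)
  nb <- tabulate(assign, nbins = nrow(hnads))
  if (any(nb == 0)) {
    warning("dropping hNAD(s) with no mappable bins: ",
            paste(which(nb == 0), collapse = ", "))
    hnads <- hnads[nb > 0, , drop = FALSE]
    class(hnads) <- c("DomainSet", "data.frame")
    assign <- hnad_bin_assignment(binning, hnads)
    nb <- tabulate(assign, nbins = nrow(hnads))
  }
  np <- nrow(hnads)
  ai <- assign[cm$i]; aj <- assign[cm$j]
  sel <- ai > 0 & aj > 0
  m <- matrix(0, np, np)
  if (any(sel)) {
    p <- pmin(ai[sel], aj[sel]); q <- pmax(ai[sel], aj[sel])
    rpm <- cm$x[sel] * 1e6 / cm$total
    agg <- rowsum(rpm, p + (q - 1) * np)
    at <- as.integer(rownames(agg))
    m[at] <- agg[, 1]
    m <- m + t(m) - diag(diag(m))
  }
  m <- m / (nb %o% nb)
  cis <- outer(hnads$chrom, hnads$chrom, `==`)
  structure(list(matrix = m, cis_mask = cis, hnads = hnads,
                 n_bins = nb, chrom = hnads$chrom),
            class = "HnadInteractionMatrix")
}

#' Trans-contact enrichment between hNAD bins
#'
#' Mean trans contact count per hNAD-hNAD bin pair divided by the mean
#' per bin pair with neither end in an hNAD. Zero-count pairs enter the
#' means, so the ratio estimates the generative boost directly.
#'
#' @param cm A `ContactMatrix` of raw counts.
#' @param hnads A `DomainSet`.
#' @return List: `ratio`, `hnad_pair_mean`, `background_mean` (counts per
#'   bin pair).
#' @export
trans_hnad_enrichment <- function(cm, hnads) {
  binning <- cm$binning
  in_h <- bins_in_domains(binning, hnads)
  chrom <- bin_chrom(binning)
  n_by <- table(chrom)[unique(chrom)]
  h_by <- tapply(in_h, chrom, sum)[unique(chrom)]
  # bin-pair counts across distinct chromosomes
  pairs_of <- function(v) (sum(v)^2 - sum(v^2)) / 2
  both_pairs <- pairs_of(h_by)
  none_pairs <- pairs_of(n_by - h_by)
  trans <- chrom[cm$i] != chrom[cm$j]
  both <- trans & in_h[cm$i] & in_h[cm$j]
  none <- trans & !in_h[cm$i] & !in_h[cm$j]
  hm <- sum(cm$x[both]) / both_pairs
  bm <- sum(cm$x[none]) / none_pairs
  list(ratio = hm / bm, hnad_pair_mean = hm, background_mean = bm)
}

#' Cluster chromosomes by their hNAD trans interactions
#'
#' The chromosome-level matrix is the mean of trans hNAD-pair entries per
#' chromosome pair; chromosomes are clustered hierarchically (average
#' linkage, Euclidean distance on interaction profiles with the
#' self-entry treated as missing). Rows are pre-ordered by chromosome
#' name so the dendrogram is deterministic under input permutation.
#'
#' @param hm An `HnadInteractionMatrix`.
#' @return List with `tree` (`hclust`), `labels` (leaf order),
#'   `chrom_matrix`.
#' @export
cluster_chromosomes <- function(hm) {
  chroms <- sort(unique(hm$chrom))
  if (length(chroms) < 3) stop("need >= 3 chromosomes with hNADs")
  nc <- length(chroms)
  cmx <- matrix(NA_real_, nc, nc, dimnames = list(chroms, chroms))
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    if (a == b) next
    sel_a <- hm$chrom == chroms[a]; sel_b <- hm$chrom == chroms[b]
    cmx[a, b] <- mean(hm$matrix[sel_a, sel_b])
  }
  tree <- stats::hclust(stats::dist(cmx), method = "average")
  list(tree = tree, labels = tree$labels[tree$order], chrom_matrix = cmx)
}

#' Cluster hNADs into the G1/G2/G3 trans-interaction groups
#'
#' Hierarchical clustering (Ward linkage, Euclidean distance) on
#' trans-only interaction profiles (cis entries zeroed), cut into `k`
#' groups, then relabelled canonically by mean trans level: G2 = lowest
#' (centromere-proximal, near-silent), G3 = highest (nucleolus-proximal),
#' G1 = the remainder. Euclidean distance is used rather than a
#' correlation distance because the groups differ foremost in
#' interaction *level*, which correlation deliberately ignores.
#'
#' @param hm An `HnadInteractionMatrix`.
#' @param k Number of groups (3 canonical).
#' @param centromeres,lads Optional `DomainSet`s for per-group summaries.
#' @return An `HnadGroups`: `assignment` (factor per hNAD), `hnads`,
#'   `summary` (per-group data.frame), `tree`.
#' @export
cluster_hnads <- function(hm, k = 3, centromeres = NULL, lads = NULL) {
  np <- nrow(hm$hnads)
  if (k > np) stop("k = ", k, " exceeds number of hNADs (", np, ")")
  feat <- hm$matrix
  feat[hm$cis_mask] <- NA_real_
  trans_level <- rowMeans(feat, na.rm = TRUE)
  feat0 <- feat; feat0[is.na(feat0)] <- 0
  tree <- stats::hclust(stats::dist(feat0), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  cl_mean <- tapply(trans_level, cl, mean)
  ord <- order(cl_mean)  # ascending trans
  # canonical names: lowest mean trans -> G2, highest -> G3, middle -> G1
  labs <- if (k == 3) c("G2", "G1", "G3") else paste0("G", seq_len(k))
  map <- character(k)
  map[ord] <- labs
  assignment <- factor(map[cl], levels = sort(unique(labs)))
  cis_level <- diag(hm$matrix)
  summ <- data.frame(group = levels(assignment))
  summ$n <- as.integer(table(assignment)[summ$group])
  summ$mean_trans <- as.numeric(tapply(trans_level, assignment,
                                       mean)[summ$group])
  summ$mean_cis <- as.numeric(tapply(cis_level, assignment,
                                     mean)[summ$group])
  if (!is.null(centromeres)) {
    cd <- centromere_distance(hm$hnads, centromeres)
    summ$mean_centromere_dist <- as.numeric(
      tapply(cd, assignment, mean, na.rm = TRUE)[summ$group])
  }
  groups <- structure(list(assignment = assignment, hnads = hm$hnads,
                           summary = summ, tree = tree),
                      class = "HnadGroups")
  if (!is.null(lads))
    groups$summary$lad_overlap_pct <-
      lad_overlap_percent(groups, lads)[summ$group]
  groups
}

#' @export
print.HnadGroups <- function(x, ...) {
  cat("hNAD groups:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Distance of each domain to the nearest centromere
#'
#' Zero when the domain overlaps a centromere interval, otherwise the gap
#' between the nearest edges; `NA` (with a warning) for chromosomes
#' without a centromere record.
#'
#' @param domains,centromeres `DomainSet`s.
#' @return Numeric vector of distances in bp, one per domain.
#' @export
centromere_distance <- function(domains, centromeres) {
  n <- nrow(domains)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cen <- centromeres[centromeres$chrom == domains$chrom[i], , drop = FALSE]
    if (nrow(cen) == 0) next
    gaps <- pmax(0, pmax(cen$start - domains$end[i],
                         domains$start[i] - cen$end))
    out[i] <- min(gaps)
  }
  if (anyNA(out))
    warning("no centromere record for chromosome(s): ",
            paste(unique(domains$chrom[is.na(out)]), collapse = ", "))
  out
}

#' Correlation of per-bin NAD-trans contacts with centromere distance
#'
#' For every bin, sums its trans contacts (RPM) to NAD bins on other
#' chromosomes, computes the bin's distance to its chromosome's
#' centromere, and tests the Pearson correlation (two-sided). A negative
#' correlation means NAD-associated trans contacts concentrate near
#' centromeres.
#'
#' @param cm A `ContactMatrix` of raw counts.
#' @param nads A `DomainSet` of NADs (or hNADs).
#' @param centromeres A `DomainSet` of centromere intervals.
#' @return List with `r`, `p`, `n`, and the per-bin `trans_rpm` and
#'   `distance` vectors.
#' @export
trans_centromere_correlation <- function(cm, nads, centromeres) {
  binning <- cm$binning
  in_nad <- bins_in_domains(binning, nads)
  chrom <- bin_chrom(binning)
  trans <- chrom[cm$i] != chrom[cm$j]
  tsum <- numeric(binning$n)
  sel_i <- trans & in_nad[cm$j]
  sel_j <- trans & in_nad[cm$i]
  tsum <- tapply_add(cm$i[sel_i], cm$x[sel_i], binning$n) +
    tapply_add(cm$j[sel_j], cm$x[sel_j], binning$n)
  tsum <- tsum * 1e6 / cm$total
  b <- binning$bins
  bin_dom <- domain_set(b$chrom, b$start, b$end, label = "bin")
  dist <- suppressWarnings(centromere_distance(bin_dom, centromeres))
  ok <- !is.na(dist)
  if (sum(ok) < 3) stop("fewer than 3 informative bins")
  if (stats::sd(tsum[ok]) == 0 || stats::sd(dist[ok]) == 0)
    stop("correlation undefined: constant input")
  ct <- stats::cor.test(dist[ok], tsum[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       trans_rpm = tsum, distance = dist)
}

#' Per-group base-pair overlap of hNADs with LADs
#'
#' @param groups An `HnadGroups`.
#' @param lads A `DomainSet` of lamina-associated domains.
#' @return Named numeric: percent of each group's hNAD bases covered by
#'   LADs.
#' @export
lad_overlap_percent <- function(groups, lads) {
  levs <- levels(groups$assignment)
  out <- stats::setNames(numeric(length(levs)), levs)
  if (nrow(lads) == 0) return(out)
  gl <- GenomicRanges::reduce(domains_to_granges(lads))
  for (g in levs) {
    d <- groups$hnads[groups$assignment == g, , drop = FALSE]
    if (nrow(d) == 0) { out[g] <- NA_real_; next }
    gd <- GenomicRanges::reduce(domains_to_granges(d))
    ov <- sum(IRanges::width(suppressWarnings(
      GenomicRanges::intersect(gd, gl))))
    out[g] <- 100 * ov / sum(IRanges::width(gd))
  }
  out
}
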