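rdna_bins <- function(cm, unit) {
  if (!unit$chrom %in% names(cm$binning$chrom_sizes))
    stop("artificial chromosome '", unit$chrom, "' absent from matrix")
  bins_of_chrom(cm$binning, unit$chrom)
}

#' Accounting of rDNA repeat-unit interactions
#'
#' Totals over contacts touching the rDNA artificial chromosome: contacts
#' with both ends inside the unit are cis (within-unit), contacts linking
#' the unit to the rest of the genome are trans. `cis + trans = total`
#' exactly.
#'
#' @param cm A `ContactMatrix` including the artificial chromosome.
#' @param unit An `RdnaUnit`.
#' @return List: `total`, `cis_within_unit`, `trans_to_genome`,
#'   `cis_fraction` (NA when the unit has no contacts).
#' @export
rdna_interaction_counts <- function(cm, unit) {
  rb <- rdna_bins(cm, unit)
  in_r_i <- cm$i %in% rb; in_r_j <- cm$j %in% rb
  any_r <- in_r_i | in_r_j
  both_r <- in_r_i & in_r_j
  total <- sum(cm$x[any_r])
  cis <- sum(cm$x[both_r])
  list(total = total, cis_within_unit = cis,
       trans_to_genome = total - cis,
       cis_fraction = if (total > 0) cis / total else NA_real_)
}

#' Fold enrichment of rDNA-associated contacts between two libraries
#'
#' Ratio of per-million rDNA-associated totals (treatment over control),
#' so library size cancels.
#'
#' @param cm_treatment,cm_control `ContactMatrix`es sharing the
#'   artificial chromosome.
#' @param unit An `RdnaUnit`.
#' @return Scalar fold enrichment.
#' @export
rdna_fold_enrichment <- function(cm_treatment, cm_control, unit) {
  a <- rdna_interaction_counts(cm_treatment, unit)
  b <- rdna_interaction_counts(cm_control, unit)
  (a$total / cm_treatment$total) / (b$total / cm_control$total)
}

#' Per-chromosome normalized rDNA trans interactions
#'
#' Trans rDNA contacts per genome chromosome, normalized per Mb of
#' chromosome length and per million total pairs of the matrix.
#'
#' @param cm A `ContactMatrix` including the artificial chromosome.
#' @param unit An `RdnaUnit`.
#' @return Named numeric over genome chromosomes.
#' @export
rdna_per_chromosome <- function(cm, unit) {
  rb <- rdna_bins(cm, unit)
  chrom <- bin_chrom(cm$binning)
  in_r_i <- cm$i %in% rb; in_r_j <- cm$j %in% rb
  trans <- xor(in_r_i, in_r_j)
  other <- ifelse(in_r_i[trans], cm$j[trans], cm$i[trans])
  chroms <- setdiff(names(cm$binning$chrom_sizes), unit$chrom)
  counts <- stats::setNames(numeric(length(chroms)), chroms)
  agg <- tapply(cm$x[trans], chrom[other], sum)
  counts[names(agg)] <- agg
  len_mb <- cm$binning$chrom_sizes[chroms] / 1e6
  counts / len_mb / (cm$total / 1e6)
}

#' Within-unit rDNA contact map and TR/IGS block contrast
#'
#' Dense symmetric within-unit map plus block means over the 5'
#' transcribed region (TR) and 3' intergenic spacer (IGS). The contrast
#' score, `mean(within-TR, within-IGS) / mean(TR-IGS)`, is scale
#' invariant and exceeds 1 when TR and IGS form separate domains.
#'
#' @param cm A `ContactMatrix` including the artificial chromosome.
#' @param unit An `RdnaUnit`.
#' @return List: `map` (dense matrix), `tr_bins`, `block_means`
#'   (`within_TR`, `within_IGS`, `TR_IGS`), `contrast`.
#' @export
rdna_unit_matrix <- function(cm, unit) {
  rb <- rdna_bins(cm, unit)
  m <- dense_matrix(cm, rb)
  starts <- cm$binning$bins$start[rb]
  tr <- starts < unit$tr_igs_split_bp
  w_tr <- mean(m[tr, tr]); w_igs <- mean(m[!tr, !tr])
  cross <- mean(m[tr, !tr])
  contrast <- if (cross > 0) mean(c(w_tr, w_igs)) / cross else Inf
  list(map = m, tr_bins = tr,
       block_means = c(within_TR = w_tr, within_IGS = w_igs,
                       TR_IGS = cross),
       contrast = contrast)
}
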