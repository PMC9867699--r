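#' Pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. The
#' depth pair drives NAD calling; the contact matrix (optional) drives
#' compartment, trans, insulation and rDNA stages.
#'
#' @param treatment_bedgraph,control_bedgraph Depth tracks (e.g.
#'   nucleolar Hi-C vs in situ Hi-C depth).
#' @param chrom_sizes chrom.sizes file.
#' @param nad_bin_size Binning for ER/NAD calling (bp).
#' @param matrix_path,bed_path Optional HiC-Pro matrix + bed pair.
#' @param centromeres_bed,lads_bed Optional BED inputs.
#' @param orientation_bedgraph Optional PC1 orientation reference; when
#'   absent the negated ER track (rebinned) is used, since nucleolar
#'   enrichment marks the B compartment.
#' @param rdna_chrom Name of the rDNA artificial chromosome if present in
#'   the matrix.
#' @param pseudocount,hnad_threshold,hnad_min_bins NAD/hNAD parameters.
#' @param insulation_window,boundary_delta Insulation parameters (bins,
#'   score units).
#' @param saddle_quantiles,corner_frac Saddle parameters.
#' @param n_hnad_groups Number of trans-interaction groups.
#' @param seed Seed recorded in the report.
#' @param out_dir Output directory.
#' @return A `RunConfig` list.
#' @export
run_config <- function(treatment_bedgraph, control_bedgraph, chrom_sizes,
                       out_dir, nad_bin_size = 10000,
                       matrix_path = NULL, bed_path = NULL,
                       centromeres_bed = NULL, lads_bed = NULL,
                       orientation_bedgraph = NULL, rdna_chrom = "rDNA",
                       pseudocount = 1, hnad_threshold = 1,
                       hnad_min_bins = 1, insulation_window = 10,
                       boundary_delta = 0.1, saddle_quantiles = 10,
                       corner_frac = 0.2, n_hnad_groups = 3, seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full NAD/Hi-C analysis pipeline
#'
#' Stages: depth to ER, HMM segmentation, hNAD filter; then, when a
#' contact matrix is supplied: ICE balancing, compartments, saddle
#' strength, interaction partition, hNAD trans grouping, insulation and
#' boundary coincidence, and rDNA accounting when the artificial
#' chromosome is present. Every stage writes its standard-format output
#' under `out_dir`, and a machine-readable `report.json` records
#' parameters, summary numbers and output checksums. Reruns with the
#' same inputs and config are bit-identical.
#'
#' @param config A `RunConfig`.
#' @return The report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(
    tool = "nadscope",
    version = as.character(utils::packageVersion("nadscope")),
    seed = config$seed,
    parameters = config[!(names(config) %in% "out_dir")],
    inputs = list())
  for (f in c("treatment_bedgraph", "control_bedgraph", "chrom_sizes",
              "matrix_path", "bed_path", "centromeres_bed", "lads_bed")) {
    if (!is.null(config[[f]]) && file.exists(config[[f]]))
      report$inputs[[f]] <- unname(tools::md5sum(config[[f]]))
  }

  sizes <- stage("read-inputs", read_chrom_sizes(config$chrom_sizes))
  binning <- genome_binning(sizes, config$nad_bin_size)
  trt <- stage("read-inputs",
               read_bedgraph(config$treatment_bedgraph, binning))
  ctl <- stage("read-inputs",
               read_bedgraph(config$control_bedgraph, binning))

  er <- stage("compute-er", compute_er(trt, ctl, config$pseudocount))
  model <- stage("fit-hmm", fit_hmm(er))
  call <- stage("segment", viterbi_segment(er, model))
  call <- stage("hnad-filter",
                filter_hnads(call, er, config$hnad_threshold,
                             config$hnad_min_bins))
  hnads <- hnad_set(call)
  write_bedgraph(er, out("er.bedgraph"))
  write_bedgraph(call$posterior, out("posterior.bedgraph"))
  write_domains_bed(call$nads, out("nads.bed"))
  write_domains_bed(hnads, out("hnads.bed"))
  write_report_json(list(means = model$means, variances = model$variances,
                         transition = model$transition,
                         initial = model$initial, loglik = model$loglik,
                         n_iter = model$n_iter), out("model.json"))
  report$nads <- list(n = nrow(call$nads), n_hnads = nrow(hnads),
                      mb = sum(call$nads$end - call$nads$start) / 1e6,
                      hnad_mb = sum(hnads$end - hnads$start) / 1e6,
                      state_means = model$means)

  cen <- if (!is.null(config$centromeres_bed))
    read_domains_bed(config$centromeres_bed, "centromere") else NULL
  lads <- if (!is.null(config$lads_bed))
    read_domains_bed(config$lads_bed, "LAD") else NULL
  if (is.null(lads)) report$lad_overlap <- "skipped (no LAD input)"

  if (!is.null(config$matrix_path)) {
    cm <- stage("read-matrix",
                read_contact_matrix(config$matrix_path, config$bed_path))
    has_rdna <- config$rdna_chrom %in% names(cm$binning$chrom_sizes)
    cmb <- stage("ice", ice_balance(cm))
    orient <- if (!is.null(config$orientation_bedgraph))
      read_bedgraph(config$orientation_bedgraph, cm$binning)
    else {
      ## negated ER, length-weighted onto the matrix binning
      tmp <- tempfile(fileext = ".bedgraph")
      on.exit(unlink(tmp), add = TRUE)
      neg <- binned_track(er$binning,
                          ifelse(is.na(er$values), 0, -er$values))
      write_bedgraph(neg, tmp)
      read_bedgraph(tmp, cm$binning)
    }
    comp <- stage("compartments",
                  suppressWarnings(compartment_pc1(cmb, orient)))
    sad <- stage("saddle",
                 saddle_strength(cmb, comp, config$saddle_quantiles,
                                 config$corner_frac))
    part <- interaction_partition(cm, comp)
    write_bedgraph(comp$pc1, out("pc1.bedgraph"))
    write_domains_bed(
      flags_to_domains(cm$binning, comp$labels %in% "A", "A") |>
        rbind(flags_to_domains(cm$binning, comp$labels %in% "B", "B")) |>
        (\(d) domain_set(d$chrom, d$start, d$end, d$label))(),
      out("compartments.bed"))
    utils::write.table(sad$saddle, out("saddle.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    report$compartments <- list(strength = sad$strength, AA = sad$AA,
                                BB = sad$BB, AB = sad$AB,
                                fractions = as.list(part$fractions))

    if (nrow(hnads) >= config$n_hnad_groups + 1) {
      hm <- stage("hnad-interactions", hnad_interaction_matrix(cm, hnads))
      grp <- stage("grouping",
                   cluster_hnads(hm, config$n_hnad_groups,
                                 centromeres = cen, lads = lads))
      utils::write.table(
        data.frame(hm$hnads, group = as.character(grp$assignment)),
        out("hnad_groups.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      report$hnad_groups <- grp$summary
    }

    ins <- stage("insulation",
                 suppressWarnings(
                   insulation_score(cmb, config$insulation_window)))
    bc <- stage("boundaries", call_boundaries(ins, config$boundary_delta))
    write_bedgraph(ins, out("insulation.bedgraph"))
    write_domains_bed(bc$tads, out("tads.bed"))
    write_domains_bed(bc$boundaries, out("boundaries.bed"))
    coin <- stage("boundary-coincidence",
                  boundary_coincidence(call, bc$boundaries, cm$binning,
                                       tolerance_bins = 1,
                                       insulation = ins))
    report$insulation <- list(n_boundaries = nrow(bc$boundaries),
                              n_tads = nrow(bc$tads),
                              nad_boundary_match_rate = coin$match_rate,
                              wilcox_p = coin$wilcox_p)

    if (has_rdna) {
      unit <- rdna_unit(chrom = config$rdna_chrom,
                        length_bp =
                          sizes_or(cm$binning, config$rdna_chrom),
                        bin_size =
                          cm$binning$bin_size_by_chrom[[config$rdna_chrom]])
      cnt <- stage("rdna", rdna_interaction_counts(cm, unit))
      um <- rdna_unit_matrix(cm, unit)
      report$rdna <- list(total = cnt$total, cis = cnt$cis_within_unit,
                          trans = cnt$trans_to_genome,
                          cis_fraction = cnt$cis_fraction,
                          tr_igs_contrast = um$contrast,
                          per_chromosome =
                            as.list(rdna_per_chromosome(cm, unit)))
    }
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "report.json"]
  report$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(sort(outputs))), basename(sort(outputs))))
  write_report_json(report, out("report.json"))
  invisible(report)
}

sizes_or <- function(binning, ch) as.numeric(binning$chrom_sizes[[ch]])

# sparse full-join of two contact matrices on (i, j); returns data.frame
join_entries <- function(cm_a, cm_b) {
  n <- cm_a$binning$n
  key_a <- (cm_a$i - 1) * n + cm_a$j
  key_b <- (cm_b$i - 1) * n + cm_b$j
  keys <- sort(unique(c(key_a, key_b)))
  data.frame(i = (keys - 1) %/% n + 1, j = (keys - 1) %% n + 1,
             xa = cm_a$x[match(keys, key_a)],
             xb = cm_b$x[match(keys, key_b)]) |>
    (\(d) { d$xa[is.na(d$xa)] <- 0; d$xb[is.na(d$xb)] <- 0; d })()
}

#' Differential report between two conditions
#'
#' Compares a control and a treated contact matrix (e.g. before/after
#' nucleolus disassembly by Actinomycin D) on the same binning: changes
#' in cis/trans compartment-pair interaction fractions, compartment
#' strength, inter-TAD interaction change stratified by hNAD boundaries,
#' and the share of increased trans B-B contact mass carried by hNAD bin
#' pairs.
#'
#' @param cm_ctrl,cm_treated Raw `ContactMatrix`es on the same binning.
#' @param compartments A `CompartmentTrack` (control assignment is used
#'   for both conditions).
#' @param tads `DomainSet` of TADs shared between conditions.
#' @param hnads `DomainSet` of hNADs.
#' @param tolerance_bins Boundary tolerance for stratification.
#' @return List: `fraction_change`, `strength_ctrl`, `strength_treated`,
#'   `strength_change`, `inter_tad` (from [inter_tad_change()]),
#'   `trans_bb_increase_hnad_fraction`.
#' @export
compare_conditions <- function(cm_ctrl, cm_treated, compartments, tads,
                               hnads, tolerance_bins = 1) {
  if (!same_binning(cm_ctrl$binning, cm_treated$binning))
    stop("conditions are on different binnings")
  part_c <- interaction_partition(cm_ctrl, compartments)
  part_t <- interaction_partition(cm_treated, compartments)
  b_ctrl <- ice_balance(cm_ctrl)
  b_trt <- ice_balance(cm_treated)
  s_c <- saddle_strength(b_ctrl, compartments)
  s_t <- saddle_strength(b_trt, compartments)
  itc <- inter_tad_change(b_ctrl, b_trt, tads, hnads, tolerance_bins)

  ## increased trans B-B mass: share carried by hNAD-hNAD bin pairs
  lab <- compartments$labels
  chrom <- bin_chrom(cm_ctrl$binning)
  in_hnad <- bins_in_domains(cm_ctrl$binning, hnads)
  je <- join_entries(cm_ctrl, cm_treated)
  rpm_a <- je$xa * 1e6 / cm_ctrl$total
  rpm_b <- je$xb * 1e6 / cm_treated$total
  bb_trans <- lab[je$i] %in% "B" & lab[je$j] %in% "B" &
    chrom[je$i] != chrom[je$j]
  inc <- pmax(rpm_b - rpm_a, 0)
  tot_inc <- sum(inc[bb_trans])
  # "related to hNADs": at least one end in an hNAD
  hnad_pair <- in_hnad[je$i] | in_hnad[je$j]
  hnad_frac <- if (tot_inc > 0)
    sum(inc[bb_trans & hnad_pair]) / tot_inc else NA_real_

  list(fraction_change = part_t$fractions - part_c$fractions,
       fractions_ctrl = part_c$fractions,
       fractions_treated = part_t$fractions,
       strength_ctrl = s_c$strength, strength_treated = s_t$strength,
       strength_change = log2(s_t$strength / s_c$strength),
       inter_tad = itc,
       trans_bb_increase_hnad_fraction = hnad_frac)
}
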