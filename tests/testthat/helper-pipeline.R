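# write a complete synthetic input bundle and return a RunConfig
pipeline_fixture <- function(dir, seed = 42) {
  cfg <- sim_config(seed = seed, n_chroms = 4, chrom_length_bp = 10e6,
                    bin_size = 100e3, nads_per_chrom = 2,
                    nad_length_bp = 1e6, tad_size_bins = 10,
                    centromere_d0_bp = 2e6, target_pairs = 2e5)
  tr <- simulate_depth_tracks(cfg)
  write_bedgraph(tr$treatment, file.path(dir, "t.bedgraph"))
  write_bedgraph(tr$control, file.path(dir, "c.bedgraph"))
  writeLines(paste(names(cfg$binning$chrom_sizes),
                   cfg$binning$chrom_sizes, sep = "\t"),
             file.path(dir, "chrom.sizes"))
  r <- simulate_rdna_contacts(cfg, simulate_contacts(cfg))
  write_contact_matrix(r$matrix, file.path(dir, "m.matrix"),
                       file.path(dir, "m.bed"))
  write_domains_bed(cfg$centromeres, file.path(dir, "cen.bed"))
  lads <- flags_to_domains(cfg$binning,
                           sim_compartment_profile(cfg) < 0, "LAD")
  write_domains_bed(lads, file.path(dir, "lads.bed"))
  list(cfg = cfg,
       rc = run_config(
         file.path(dir, "t.bedgraph"), file.path(dir, "c.bedgraph"),
         file.path(dir, "chrom.sizes"),
         out_dir = file.path(dir, "out"), nad_bin_size = 100e3,
         matrix_path = file.path(dir, "m.matrix"),
         bed_path = file.path(dir, "m.bed"),
         centromeres_bed = file.path(dir, "cen.bed"),
         lads_bed = file.path(dir, "lads.bed"),
         insulation_window = 5, seed = seed))
}
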