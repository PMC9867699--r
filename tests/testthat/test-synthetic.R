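test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_chroms = 2, chrom_length_bp = 3e6,
                    bin_size = 100e3, nads_per_chrom = 1,
                    target_pairs = 1e4,
                    image_dims = c(11L, 48L, 48L),
                    planted_distances_um = c(0, 0.5, 1))
  a1 <- simulate_depth_tracks(cfg); a2 <- simulate_depth_tracks(cfg)
  expect_identical(a1$treatment$values, a2$treatment$values)
  expect_identical(a1$control$values, a2$control$values)
  m1 <- simulate_contacts(cfg); m2 <- simulate_contacts(cfg)
  expect_identical(m1$x, m2$x)
  r1 <- simulate_rdna_contacts(cfg, m1); r2 <- simulate_rdna_contacts(cfg, m2)
  expect_identical(r1$matrix$x, r2$matrix$x)
  s1 <- simulate_image_stack(cfg); s2 <- simulate_image_stack(cfg)
  expect_identical(s1$fish$voxels, s2$fish$voxels)
})

test_that("depth fold plants the expected enrichment, null plants none", {
  cfg <- sim_config(seed = 2, n_chroms = 2, chrom_length_bp = 10e6,
                    bin_size = 10e3, nads_per_chrom = 2,
                    nad_length_bp = 1e6, nad_depth_fold = 4,
                    depth_noise_cv = 0)
  tr <- simulate_depth_tracks(cfg)
  fold <- mean(tr$treatment$values[tr$truth]) /
    mean(tr$treatment$values[!tr$truth])
  expect_equal(fold, 4, tolerance = 0.05)
  # fold = 1: treatment and control exchangeable
  cfg1 <- sim_config(seed = 2, n_chroms = 2, chrom_length_bp = 10e6,
                     bin_size = 10e3, nads_per_chrom = 2,
                     nad_length_bp = 1e6, nad_depth_fold = 1,
                     depth_noise_cv = 0)
  tr1 <- simulate_depth_tracks(cfg1)
  expect_equal(mean(tr1$treatment$values[tr1$truth]),
               mean(tr1$treatment$values[!tr1$truth]),
               tolerance = 0.03)
})

test_that("contact totals are conserved and decay limits to near-diagonal", {
  cfg <- sim_config(seed = 4, n_chroms = 2, chrom_length_bp = 3e6,
                    bin_size = 100e3, nads_per_chrom = 1,
                    target_pairs = 2e4)
  cm <- simulate_contacts(cfg)
  expect_equal(cm$total, sum(cm$x))
  expect_equal(cm$total, 2e4, tolerance = 0.05)
  # huge decay exponent and no trans-to-cis weight: mass hugs the diagonal
  cfg2 <- sim_config(seed = 4, n_chroms = 2, chrom_length_bp = 3e6,
                     bin_size = 100e3, nads_per_chrom = 1,
                     decay_exponent = 8, cis_weight = 1e6,
                     compartment_boost = 1, tad_intra_boost = 1,
                     target_pairs = 2e4)
  cm2 <- simulate_contacts(cfg2)
  chrom <- cm2$binning$bins$chrom
  cis <- chrom[cm2$i] == chrom[cm2$j]
  expect_gt(sum(cm2$x[cis & (cm2$j - cm2$i) <= 1]) / cm2$total, 0.99)
})

test_that("planted trans boost is recovered and attenuates monotonically", {
  ratio_at <- function(lam) {
    cfg <- sim_config(seed = 9, n_chroms = 4, chrom_length_bp = 10e6,
                      bin_size = 100e3, nads_per_chrom = 4,
                      hnad_trans_boost = 3, actd_mixing = lam,
                      actd_trans_release = 1, tad_intra_boost = 1,
                      target_pairs = 2e5)
    trans_hnad_enrichment(simulate_contacts(cfg), cfg$planted_nads)$ratio
  }
  r <- vapply(c(0, 0.4, 0.8), ratio_at, numeric(1))
  expect_equal(r[1], 3, tolerance = 0.15)
  expect_true(all(diff(r) < 0))
  # boost 1 is the null: ratio compatible with 1
  cfg0 <- sim_config(seed = 9, n_chroms = 4, chrom_length_bp = 10e6,
                     bin_size = 100e3, nads_per_chrom = 4,
                     hnad_trans_boost = 1, actd_trans_release = 1,
                     tad_intra_boost = 1, target_pairs = 2e5)
  r0 <- trans_hnad_enrichment(simulate_contacts(cfg0), cfg0$planted_nads)
  expect_equal(r0$ratio, 1, tolerance = 0.1)
})

test_that("rDNA unit simulation matches its block and cis-fraction model", {
  cfg <- sim_config(seed = 6, n_chroms = 2, chrom_length_bp = 5e6,
                    bin_size = 100e3, nads_per_chrom = 2,
                    target_pairs = 5e4, rdna_total_pairs = 3e4,
                    rdna_cis_fraction = 0.76, rdna_coupling = 0.2)
  cm <- simulate_contacts(cfg)
  r <- simulate_rdna_contacts(cfg, cm)
  rb <- which(r$matrix$binning$bins$chrom == "rDNA")
  expect_length(rb, 43L)
  cnt <- rdna_interaction_counts(r$matrix, r$unit)
  # binomial 95% CI of the planted cis fraction
  se <- sqrt(0.76 * 0.24 / cnt$total)
  expect_lt(abs(cnt$cis_fraction - 0.76), 1.96 * se + 0.01)
  # zero coupling: no TR-IGS contacts at all
  cfg0 <- sim_config(seed = 6, n_chroms = 2, chrom_length_bp = 5e6,
                     bin_size = 100e3, nads_per_chrom = 2,
                     target_pairs = 5e4, rdna_coupling = 0)
  r0 <- simulate_rdna_contacts(cfg0, simulate_contacts(cfg0))
  um0 <- rdna_unit_matrix(r0$matrix, r0$unit)
  expect_equal(um0$block_means[["TR_IGS"]], 0)
})

test_that("image truth geometry is self-consistent", {
  cfg <- sim_config(seed = 8, image_dims = c(21L, 96L, 96L),
                    planted_distances_um = c(0, 0.4, 1.2),
                    background_sd = 1e-6)
  im <- simulate_image_stack(cfg)
  expect_equal(im$truth$distances_um, c(0, 0.4, 1.2), tolerance = 1e-6)
  # a focus planted at distance 0 sits inside the noiseless mask
  cen <- im$truth$centroids_um[1, ]
  expect_equal(
    focus_nucleolus_distance(cen, im$truth$mask, cfg$voxel_size_um), 0)
  # near-noiseless stack: segmentation recovers the planted sphere mask
  mask <- segment_nucleolus(im$nucleolus)
  inter <- sum(mask$mask & im$truth$mask)
  jac <- inter / sum(mask$mask | im$truth$mask)
  expect_gt(jac, 0.9)
})
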