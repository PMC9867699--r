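arch_config <- function(seed, arch = rep(c("G1", "G2", "G3"),
                                         length.out = 24)) {
  sim_config(seed = seed, n_chroms = 6, chrom_length_bp = 10e6,
             bin_size = 100e3, nads_per_chrom = 4,
             hnad_archetype = arch, tad_intra_boost = 1,
             target_pairs = 2e5)
}

test_that("hNAD interaction matrix is RPM-normalized and boost-faithful", {
  cfg <- sim_config(seed = 21, n_chroms = 4, chrom_length_bp = 10e6,
                    bin_size = 100e3, nads_per_chrom = 2,
                    hnad_trans_boost = 3, tad_intra_boost = 1,
                    target_pairs = 2e5)
  cm <- simulate_contacts(cfg)
  hm <- hnad_interaction_matrix(cm, cfg$planted_nads)
  expect_true(isSymmetric(hm$matrix))
  expect_true(all(hm$matrix >= 0))
  # doubling all counts leaves entries unchanged (RPM scale invariance)
  cm2 <- contact_matrix(cm$binning, cm$i, cm$j, cm$x * 2)
  hm2 <- hnad_interaction_matrix(cm2, cfg$planted_nads)
  expect_equal(hm2$matrix, hm$matrix, tolerance = 1e-12)
  # trans entries reflect the planted pairwise boost vs background
  e <- trans_hnad_enrichment(cm, cfg$planted_nads)
  expect_equal(e$ratio, 3, tolerance = 0.15)
  # hNADs with no contacts between them would simply yield entry 0
  empty_pair <- hm$matrix[1, 2]
  expect_true(is.finite(empty_pair))
})

test_that("NOR-like chromosomes form the tightest cluster", {
  arch <- c(rep("G1", 12), rep("G3", 12))  # chr4-6 carry G3 hub hNADs
  cfg <- arch_config(22, arch)
  cm <- simulate_contacts(cfg)
  hm <- hnad_interaction_matrix(cm, cfg$planted_nads)
  cc <- cluster_chromosomes(hm)
  grp <- stats::cutree(cc$tree, 2)
  expect_equal(unname(grp[c("chr4", "chr5", "chr6")]),
               rep(grp[["chr4"]], 3))
  expect_equal(unname(grp[c("chr1", "chr2", "chr3")]),
               rep(grp[["chr1"]], 3))
  expect_true(grp[["chr1"]] != grp[["chr4"]])
  # permuting the hNAD input order leaves the topology unchanged
  perm <- sample(nrow(cfg$planted_nads))
  hn_p <- cfg$planted_nads[perm, , drop = FALSE]
  class(hn_p) <- c("DomainSet", "data.frame")
  cc2 <- cluster_chromosomes(hnad_interaction_matrix(cm, hn_p))
  expect_equal(stats::cophenetic(cc$tree), stats::cophenetic(cc2$tree),
               tolerance = 1e-12)
  expect_error(cluster_chromosomes(
    hnad_interaction_matrix(cm, cfg$planted_nads[1:4, ])), ">= 3")
})

test_that("G1/G2/G3 grouping recovers planted archetypes across seeds", {
  aris <- vapply(1:10, function(seed) {
    cfg <- arch_config(seed)
    hm <- hnad_interaction_matrix(simulate_contacts(cfg),
                                  cfg$planted_nads)
    grp <- cluster_hnads(hm, 3)
    # canonical ordering by construction of the relabelling
    s <- grp$summary
    expect_gte(s$mean_trans[s$group == "G3"],
               s$mean_trans[s$group == "G1"])
    expect_gte(s$mean_trans[s$group == "G1"],
               s$mean_trans[s$group == "G2"])
    adjusted_rand(as.character(grp$assignment), cfg$hnad_archetype)
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 1)
  cfg <- arch_config(1)
  hm <- hnad_interaction_matrix(simulate_contacts(cfg), cfg$planted_nads)
  expect_error(cluster_hnads(hm, k = 100), "exceeds")
})

test_that("centromere distances follow interval arithmetic", {
  cen <- domain_set(c("chr1", "chr1", "chr2"),
                    c(20e6, 40e6, 10e6), c(25e6, 45e6, 12e6),
                    label = "centromere")
  dom <- domain_set(c("chr1", "chr1", "chr1", "chr3"),
                    c(10e6, 21e6, 38e6, 0), c(11e6, 22e6, 39e6, 1e6),
                    label = "hNAD")
  d <- suppressWarnings(centromere_distance(dom, cen))
  expect_equal(d[1], 9e6)       # gap to nearest edge
  expect_equal(d[2], 0)         # overlapping
  expect_equal(d[3], 1e6)       # min over the two arms
  expect_true(is.na(d[4]))      # chromosome without a record
  expect_warning(centromere_distance(dom, cen), "chr3")
})

test_that("NAD trans contacts correlate negatively with centromere distance", {
  cfg <- sim_config(seed = 25, n_chroms = 4, chrom_length_bp = 10e6,
                    bin_size = 100e3, nads_per_chrom = 2,
                    centromere_d0_bp = 2e6, tad_intra_boost = 1,
                    target_pairs = 2e5)
  cm <- simulate_contacts(cfg)
  ct <- trans_centromere_correlation(cm, cfg$planted_nads,
                                     cfg$centromeres)
  expect_lt(ct$r, 0)
  expect_lt(ct$p, 0.05)
  # proximity factor disabled: no systematic correlation
  cfg0 <- sim_config(seed = 25, n_chroms = 4, chrom_length_bp = 10e6,
                     bin_size = 100e3, nads_per_chrom = 2,
                     tad_intra_boost = 1, target_pairs = 2e5)
  ct0 <- trans_centromere_correlation(simulate_contacts(cfg0),
                                      cfg0$planted_nads,
                                      cfg0$centromeres)
  expect_gt(abs(ct$r), abs(ct0$r))
  # constant input errors
  b <- toy_binning(6)
  cm1 <- contact_matrix(b, 1, 2, 5)
  expect_error(
    trans_centromere_correlation(
      cm1, domain_set("chrT", 0, 1000, "NAD"),
      domain_set("chrX", 0, 10, "centromere")),
    "fewer than 3|constant")
})

test_that("LAD overlap percentages follow base-pair arithmetic", {
  hn <- domain_set(c("chr1", "chr2"), c(0, 0), c(5e6, 5e6), "hNAD")
  grp <- structure(list(
    assignment = factor(c("G1", "G3"), levels = c("G1", "G2", "G3")),
    hnads = hn), class = "HnadGroups")
  # LADs covering the whole genome: 100% everywhere a group has members
  all_lads <- domain_set(c("chr1", "chr2"), c(0, 0), c(10e6, 10e6), "LAD")
  p <- lad_overlap_percent(grp, all_lads)
  expect_equal(unname(p[c("G1", "G3")]), c(100, 100))
  # 2 Mb of a 5 Mb hNAD -> 40%
  part <- domain_set("chr2", 1e6, 3e6, "LAD")
  p2 <- lad_overlap_percent(grp, part)
  expect_equal(unname(p2[["G3"]]), 40)
  expect_equal(unname(p2[["G1"]]), 0)
  # empty LAD set -> 0 everywhere
  expect_equal(unname(lad_overlap_percent(grp, domain_set())),
               c(0, 0, 0))
})
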