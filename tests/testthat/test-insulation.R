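# dense constructor: symmetric matrix on a single-chromosome binning
cm_from_dense <- function(m, bin = 20e3, chrom = "chrT") {
  n <- nrow(m)
  b <- genome_binning(stats::setNames(n * bin, chrom), bin)
  idx <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
  contact_matrix(b, idx[, 1], idx[, 2], m[idx])
}

test_that("insulation is flat on banded matrices and scale invariant", {
  n <- 40
  m <- abs(outer(1:n, 1:n, function(i, j) 10 / (abs(i - j) + 1)))
  cm <- cm_from_dense(m)
  ins <- insulation_score(cm, window_bins = 5)
  sc <- ins$values[!is.na(ins$values)]
  expect_lt(max(abs(sc)), 0.1)
  expect_true(all(is.na(ins$values[1:5])))
  # doubling counts leaves scores identical
  cm2 <- contact_matrix(cm$binning, cm$i, cm$j, cm$x * 2)
  expect_equal(insulation_score(cm2, window_bins = 5)$values,
               ins$values)
  # window larger than the chromosome: skipped with warning
  expect_warning(insulation_score(cm, window_bins = 30), "skipped")
})

test_that("a planted junction yields one deep boundary minimum", {
  n <- 40
  m <- matrix(0.2, n, n)
  m[1:20, 1:20] <- 10
  m[21:40, 21:40] <- 10
  cm <- cm_from_dense(m)
  ins <- insulation_score(cm, window_bins = 5)
  expect_equal(which.min(ins$values), 21L)
  bc <- call_boundaries(ins, delta_threshold = 0.5)
  expect_equal(nrow(bc$boundaries), 1L)
  expect_equal(bc$boundaries$start, 20 * 20e3)
  expect_equal(nrow(bc$tads), 2L)
  # threshold above every prominence: no boundaries, one TAD
  bc0 <- call_boundaries(ins, delta_threshold = 100)
  expect_equal(nrow(bc0$boundaries), 0L)
  expect_equal(nrow(bc0$tads), 1L)
})

test_that("planted TAD grid is recovered with high recall and precision", {
  rp <- vapply(1:3, function(seed) {
    cfg <- sim_config(seed = seed, n_chroms = 4, chrom_length_bp = 10e6,
                      bin_size = 100e3, tad_size_bins = 10,
                      tad_intra_boost = 3, compartment_boost = 1,
                      planted_nads = domain_set(), target_pairs = 3e5)
    cmb <- ice_balance(simulate_contacts(cfg))
    ins <- insulation_score(cmb, window_bins = 5)
    bc <- call_boundaries(ins, delta_threshold = 0.2)
    truth <- do.call(rbind, lapply(names(cfg$binning$chrom_sizes),
                                   function(ch) data.frame(
                                     chrom = ch,
                                     pos = seq(1e6, 9e6, by = 1e6))))
    boundary_recall_precision(bc$boundaries, truth, tol = 1e5)
  }, numeric(2))
  expect_true(all(rp["recall", ] >= 0.9))
  expect_true(all(rp["precision", ] >= 0.9))
})

test_that("NAD/TAD boundary matching behaves at tolerance extremes", {
  b <- genome_binning(c(chrT = 4e6), 20e3)
  nads <- domain_set("chrT", c(1e6, 3e6), c(2e6, 3.5e6), "NAD")
  # TAD boundaries exactly at the NAD edges
  tb <- domain_set("chrT", c(1e6, 2e6, 3e6, 3.5e6),
                   c(1e6, 2e6, 3e6, 3.5e6) + 20e3, "boundary")
  bcm <- boundary_coincidence(nads, tb, b, tolerance_bins = 0)
  expect_equal(bcm$match_rate, 1)
  # shifted beyond tolerance: no matches
  tb2 <- domain_set("chrT", c(1e6, 2e6, 3e6, 3.5e6) + 200e3,
                    c(1e6, 2e6, 3e6, 3.5e6) + 220e3, "boundary")
  expect_equal(boundary_coincidence(nads, tb2, b,
                                    tolerance_bins = 1)$match_rate, 0)
})

test_that("hNAD boundaries sit at deeper insulation minima than other NADs", {
  # construct insulation where hNAD edges are deep minima, others shallow
  set.seed(41)
  b <- genome_binning(c(chrT = 40e6), 20e3)
  vals <- rnorm(b$n, 0, 0.02)
  # alternating blocks: hNADs bounded by deep minima, other NADs by
  # shallow minima, all intervals disjoint
  k <- 0:3
  deep <- sort(c(200 + 400 * k, 300 + 400 * k))
  shallow <- sort(c(400 + 400 * k, 500 + 400 * k))
  vals[deep] <- -1.5 + rnorm(length(deep), 0, 0.05)
  vals[shallow] <- -0.3 + rnorm(length(shallow), 0, 0.05)
  ins <- binned_track(b, vals)
  class(ins) <- c("InsulationTrack", class(ins))
  edges <- function(bins) (bins - 1) * 20e3
  nads <- domain_set("chrT",
                     edges(c(200 + 400 * k, 400 + 400 * k)),
                     edges(c(300 + 400 * k, 500 + 400 * k)), "NAD")
  # domain_set sorts by start, interleaving hNADs and other NADs
  call <- structure(list(
    nads = nads, is_hnad = rep(c(TRUE, FALSE), times = 4)),
    class = "NADCall")
  tb <- domain_set("chrT", edges(c(deep, shallow)),
                   edges(c(deep, shallow)) + 20e3, "boundary")
  out <- boundary_coincidence(call, tb, b, tolerance_bins = 0,
                              insulation = ins)
  expect_equal(out$match_rate, 1)
  med <- tapply(abs(out$edges$insulation), out$edges$is_hnad, median)
  expect_gt(med[["TRUE"]], med[["FALSE"]])
  expect_lt(out$wilcox_p, 0.05)
})

test_that("inter-TAD change is zero for identical or rescaled conditions", {
  cfg <- sim_config(seed = 43, n_chroms = 2, chrom_length_bp = 10e6,
                    bin_size = 100e3, tad_size_bins = 10,
                    tad_intra_boost = 3, nads_per_chrom = 2,
                    target_pairs = 1e5)
  cm <- simulate_contacts(cfg)
  tads <- sim_tads(cfg)
  same <- inter_tad_change(cm, cm, tads, cfg$planted_nads)
  expect_true(all(abs(same$pairs$change) < 1e-12))
  cm2 <- contact_matrix(cm$binning, cm$i, cm$j, cm$x * 2)
  scaled <- inter_tad_change(cm, cm2, tads, cfg$planted_nads)
  expect_true(all(abs(scaled$pairs$change) < 1e-12))
})

test_that("ActD-style cross-boundary boost concentrates at hNAD boundaries", {
  mk <- function(lam) sim_config(
    seed = 44, n_chroms = 8, chrom_length_bp = 10e6, bin_size = 100e3,
    nads_per_chrom = 2, nad_length_bp = 1e6, tad_size_bins = 10,
    tad_intra_boost = 3, compartment_boost = 2,
    actd_boundary_boost = 3, actd_mixing = lam, target_pairs = 4e5)
  cfg <- mk(0)
  itc <- inter_tad_change(ice_balance(simulate_contacts(cfg)),
                          ice_balance(simulate_contacts(mk(0.8))),
                          sim_tads(cfg), cfg$planted_nads)
  strata <- split(itc$pairs$change, itc$pairs$at_hnad_boundary)
  expect_gt(mean(strata[["TRUE"]]), mean(strata[["FALSE"]]))
  expect_lt(itc$wilcox_p, 0.05)
})
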