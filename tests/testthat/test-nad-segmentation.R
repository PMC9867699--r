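test_that("enrichment ratio follows the RPM log-ratio formula", {
  b <- toy_binning(4)
  # equal normalized depths -> ER 0 everywhere
  t1 <- binned_track(b, c(10, 20, 30, 40))
  c1 <- binned_track(b, c(20, 40, 60, 80))  # same shape, double depth
  expect_equal(compute_er(t1, c1, pseudocount = 1)$values, rep(0, 4))
  # direct formula check, including the t = 0 case
  t2 <- binned_track(b, c(0, 10, 10, 20))
  c2 <- binned_track(b, c(8, 8, 8, 8))
  er <- compute_er(t2, c2, pseudocount = 1)
  rpm_t <- t2$values * 1e6 / sum(t2$values)
  rpm_c <- c2$values * 1e6 / sum(c2$values)
  expect_equal(er$values, log2((rpm_t + 1) / (rpm_c + 1)))
  # normalized t = 4c in one bin, vanishing pseudocount -> ER -> 2 there
  b2 <- toy_binning(2)
  t3 <- binned_track(b2, c(4, 0))
  c3 <- binned_track(b2, c(1, 3))
  expect_equal(compute_er(t3, c3, pseudocount = 1e-9)$values[1], 2,
               tolerance = 1e-6)
  # both-zero bins are NA; mismatched binning is an error
  t4 <- binned_track(b, c(0, 5, 5, 5)); c4 <- binned_track(b, c(0, 5, 5, 5))
  expect_true(is.na(compute_er(t4, c4)$values[1]))
  expect_error(compute_er(t1, binned_track(toy_binning(5), rep(1, 5))),
               "different binnings")
})

test_that("Viterbi equals exhaustive path enumeration on short tracks", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    model <- toy_model(mu = sort(rnorm(2, 0, 1.5)),
                       sd = runif(2, 0.3, 1),
                       diag = runif(1, 0.6, 0.95))
    x <- rnorm(n, sample(model$means, n, replace = TRUE), 0.8)
    expect_identical(nadscope:::viterbi_path(x, model),
                     brute_force_viterbi(x, model))
  }
})

test_that("EM recovers well-separated state means and is monotone", {
  set.seed(13)
  b <- genome_binning(c(chrT = 6e6), 10e3)
  # persistent two-state signal: alternating runs of 100 bins
  state <- rep(rep(c(1, 2), 3), each = 100)
  vals <- rnorm(600, c(-0.5, 1.5)[state], 0.1)
  er <- binned_track(b, vals)
  m <- fit_hmm(er)
  expect_equal(unname(m$means), c(-0.5, 1.5), tolerance = 0.05)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-12))
  # i.i.d. (shuffled) input: transition rows approach the state marginals
  er_shuf <- binned_track(b, sample(vals))
  ms <- fit_hmm(er_shuf)
  marg <- ms$initial  # close to the stationary mix (0.5/0.5 here)
  expect_equal(ms$transition[1, 2], ms$transition[2, 2], tolerance = 0.15)
  expect_equal(ms$transition[2, 2], 0.5, tolerance = 0.15)
  # constant ER is non-identifiable
  expect_error(fit_hmm(binned_track(b, rep(1, 600))), "non-identifiable")
})

test_that("segmentation finds the planted piece and respects NA gaps", {
  b <- genome_binning(c(chrT = 150e3), 1e3)
  vals <- c(rep(-1, 50), rep(1.5, 50), rep(-1, 50)) + rnorm(150, 0, 0.1)
  er <- binned_track(b, vals)
  model <- toy_model(mu = c(-1, 1.5), sd = c(0.1, 0.1), diag = 0.95)
  call <- viterbi_segment(er, model)
  expect_equal(nrow(call$nads), 1L)
  expect_equal(call$nads$start, 50e3)
  expect_equal(call$nads$end, 100e3)
  expect_true(all(call$posterior$values[60:90] > 0.99))
  # all bins at the inter mean: zero NAD intervals
  call0 <- viterbi_segment(binned_track(b, rep(-1, 150)), model)
  expect_equal(nrow(call0$nads), 0L)
  # an NA gap splits a NAD-state run into two intervals
  vals[75] <- NA
  call2 <- viterbi_segment(binned_track(b, vals), model)
  expect_equal(nrow(call2$nads), 2L)
})

test_that("negating ER yields the complementary segmentation", {
  set.seed(17)
  b <- genome_binning(c(chrT = 400e3), 1e3)
  state <- rep(rep(c(1, 2), 2), each = 100)
  vals <- rnorm(400, c(-0.8, 0.9)[state], 0.25)
  er <- binned_track(b, vals)
  m1 <- fit_hmm(er); m2 <- fit_hmm(binned_track(b, -vals))
  s1 <- viterbi_segment(er, m1)$state
  s2 <- viterbi_segment(binned_track(b, -vals), m2)$state
  expect_identical(s1, !s2)
})

test_that("hNAD filter applies the qualifying-bin rule", {
  b <- toy_binning(9)
  er <- binned_track(b, c(0.4, 1.2, 0.8, -1, -1, -1, 0.2, 0.9, 1.0))
  call <- structure(list(
    nads = domain_set(rep("chrT", 2), c(0, 6000), c(3000, 9000), "NAD"),
    is_hnad = c(FALSE, FALSE), max_er = c(NA, NA),
    posterior = binned_track(b, rep(NA_real_, 9)),
    state = rep(FALSE, 9)), class = "NADCall")
  out <- filter_hnads(call, er)  # default: >= 1 bin with ER > 1
  expect_identical(out$is_hnad, c(TRUE, FALSE))
  expect_equal(out$max_er, c(1.2, 1.0))
  # stricter rule: >= 2 qualifying bins
  out2 <- filter_hnads(call, er, min_bins = 2)
  expect_identical(out2$is_hnad, c(FALSE, FALSE))
  expect_equal(nrow(hnad_set(out)), 1L)
})

test_that("hNADs are a subset of NADs with max ER above threshold", {
  cfg <- sim_config(seed = 31, n_chroms = 3, chrom_length_bp = 10e6,
                    bin_size = 10e3, nads_per_chrom = 3,
                    nad_length_bp = 600e3, nad_depth_fold = 3,
                    depth_noise_cv = 0.3)
  tr <- simulate_depth_tracks(cfg)
  er <- compute_er(tr$treatment, tr$control)
  call <- filter_hnads(viterbi_segment(er, fit_hmm(er)), er)
  hn <- hnad_set(call)
  expect_true(all(hn$score > 1))
  ov <- overlap_stats(hn, call$nads, er$binning)
  expect_equal(ov$overlap_fraction, 1)
})

test_that("hypergeometric overlap p matches exact combinatorial tail", {
  b <- genome_binning(c(chrT = 1000e3), 1e3)  # 1000 bins
  mk <- function(bins) {
    s <- (bins - 1) * 1e3
    domain_set(rep("chrT", length(bins)), s, s + 1e3, "set")
  }
  # A == B: perfect overlap, tiny p
  a <- mk(1:100)
  st <- overlap_stats(a, a, b)
  expect_equal(st$overlap_fraction, 1)
  expect_equal(st$jaccard, 1)
  expect_lt(st$hypergeom_p, 1e-100)
  expect_equal(st$hypergeom_p, hypergeom_tail_exact(100, 100, 1000, 100),
               tolerance = 1e-10)
  # disjoint 10% sets: overlap 0, p ~ 1
  st2 <- overlap_stats(mk(1:100), mk(101:200), b)
  expect_equal(st2$overlap_fraction, 0)
  expect_equal(st2$hypergeom_p, hypergeom_tail_exact(0, 100, 1000, 100),
               tolerance = 1e-12)
  expect_gt(st2$hypergeom_p, 0.999999)
  # 50 of 100/100 shared out of 1000
  st3 <- overlap_stats(mk(1:100), mk(51:150), b)
  expect_equal(st3$hypergeom_p, hypergeom_tail_exact(50, 100, 1000, 100),
               tolerance = 1e-10)
  # empty set convention
  st4 <- overlap_stats(domain_set(), mk(1:10), b)
  expect_equal(st4$overlap_fraction, 0)
  expect_equal(st4$hypergeom_p, 1)
})
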