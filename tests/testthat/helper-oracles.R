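# Independent oracles and small fixture builders used across tests.

# Exhaustive most-probable-path search over all 2^n state paths of a
# two-state Gaussian HMM. Independent of the dynamic-programming
# implementation under test.
brute_force_viterbi <- function(x, model) {
  n <- length(x)
  best <- NULL; best_lp <- -Inf
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[seq_len(n)] + 1L
    lp <- log(model$initial[path[1]]) +
      stats::dnorm(x[1], model$means[path[1]],
                   sqrt(model$variances[path[1]]), log = TRUE)
    if (n > 1) for (t in 2:n) {
      lp <- lp + log(model$transition[path[t - 1], path[t]]) +
        stats::dnorm(x[t], model$means[path[t]],
                     sqrt(model$variances[path[t]]), log = TRUE)
    }
    if (lp > best_lp) { best_lp <- lp; best <- path }
  }
  best
}

# Upper-tail hypergeometric probability from the combinatorial definition
# (log-scale binomial coefficients), independent of stats::phyper.
hypergeom_tail_exact <- function(q, m, N, k) {
  qs <- q:min(m, k)
  sum(exp(lchoose(m, qs) + lchoose(N - m, k - qs) - lchoose(N, k)))
}

# Adjusted Rand index from the contingency table (closed form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  sa <- sum_comb(rowSums(tab)); sb <- sum_comb(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sa * sb / n2
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# bin-level F1 of a predicted logical vector against truth
f1_score <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  2 * tp / (2 * tp + fp + fn)
}

# tiny single-chromosome binning
toy_binning <- function(n = 10, bin = 1000, chrom = "chrT") {
  genome_binning(stats::setNames(n * bin, chrom), bin)
}

# two-state model with well-separated emissions
toy_model <- function(mu = c(-1, 1), sd = c(0.5, 0.5),
                      diag = 0.9, initial = c(0.5, 0.5)) {
  structure(list(means = mu, variances = sd^2,
                 transition = matrix(c(diag, 1 - diag, 1 - diag, diag),
                                     2, 2, byrow = TRUE),
                 initial = initial),
            class = "HMMModel")
}

# boundary recall/precision of called boundary positions vs true
# junction positions, matched within tol bp on the same chromosome
boundary_recall_precision <- function(boundaries, truth, tol) {
  hit <- vapply(seq_len(nrow(truth)), function(k) {
    b <- boundaries[boundaries$chrom == truth$chrom[k], , drop = FALSE]
    nrow(b) > 0 && min(abs(b$start - truth$pos[k])) <= tol
  }, logical(1))
  prec <- vapply(seq_len(nrow(boundaries)), function(k) {
    t <- truth[truth$chrom == boundaries$chrom[k], , drop = FALSE]
    nrow(t) > 0 && min(abs(t$pos - boundaries$start[k])) <= tol
  }, logical(1))
  c(recall = mean(hit), precision = mean(prec))
}
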