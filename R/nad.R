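#' Per-bin enrichment ratio of treatment over control depth
#'
#' Both tracks are first scaled to reads per million (RPM) so libraries of
#' different size are comparable, then
#' `ER = log2((treatment_rpm + pc) / (control_rpm + pc))`.
#' Bins where both raw depths are zero are flagged `NA` (unmappable) and
#' break the HMM chain downstream.
#'
#' @param treatment,control `BinnedTrack`s on the same binning (e.g.
#'   nucleolar vs whole-genome depth, or nucleolar Hi-C vs in situ Hi-C).
#' @param pseudocount Added to both RPM values before the log ratio.
#' @param source_pair Free-text label recording which library pair the
#'   ratio came from.
#' @return An `EnrichmentTrack` (a `BinnedTrack` whose values are ER).
#' @export
compute_er <- function(treatment, control, pseudocount = 1,
                       source_pair = "treatment/control") {
  stopifnot(inherits(treatment, "BinnedTrack"),
            inherits(control, "BinnedTrack"))
  if (!same_binning(treatment$binning, control$binning))
    stop("treatment and control are on different binnings")
  if (any(treatment$values < 0, na.rm = TRUE) ||
      any(control$values < 0, na.rm = TRUE))
    stop("negative depths")
  t_rpm <- treatment$values * 1e6 / sum(treatment$values, na.rm = TRUE)
  c_rpm <- control$values * 1e6 / sum(control$values, na.rm = TRUE)
  er <- log2((t_rpm + pseudocount) / (c_rpm + pseudocount))
  both0 <- !is.na(treatment$values) & !is.na(control$values) &
    treatment$values == 0 & control$values == 0
  er[both0 | is.na(treatment$values) | is.na(control$values)] <- NA_real_
  out <- binned_track(treatment$binning, er)
  out$source_pair <- source_pair
  out$pseudocount <- pseudocount
  class(out) <- c("EnrichmentTrack", class(out))
  out
}

# contiguous runs of finite values within one chromosome; NA bins break
# the chain so the HMM never bridges unmappable gaps
track_segments <- function(track) {
  ok <- is.finite(track$values)
  chrom <- track$binning$bins$chrom
  segs <- list()
  i <- 1; n <- length(ok)
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1] && chrom[j + 1] == chrom[i]) j <- j + 1
      segs[[length(segs) + 1]] <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  segs
}

gauss_dens <- function(x, mu, sigma2) {
  d <- cbind(stats::dnorm(x, mu[1], sqrt(sigma2[1])),
             stats::dnorm(x, mu[2], sqrt(sigma2[2])))
  d[d < 1e-300] <- 1e-300
  d
}

# scaled forward-backward for one segment; returns loglik, gamma (T x 2)
# and summed xi (2 x 2)
forward_backward <- function(x, model) {
  Tn <- length(x)
  B <- gauss_dens(x, model$means, model$variances)
  A <- model$transition
  a <- matrix(0, Tn, 2); b <- matrix(0, Tn, 2); cs <- numeric(Tn)
  a[1, ] <- model$initial * B[1, ]
  cs[1] <- sum(a[1, ]); a[1, ] <- a[1, ] / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a[t, ] <- (a[t - 1, ] %*% A) * B[t, ]
    cs[t] <- sum(a[t, ]); a[t, ] <- a[t, ] / cs[t]
  }
  b[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    b[t, ] <- (A %*% (B[t + 1, ] * b[t + 1, ])) / cs[t + 1]
  gamma <- a * b
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, 2, 2)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    m <- (a[t, ] %o% (B[t + 1, ] * b[t + 1, ])) * A / cs[t + 1]
    xi <- xi + m / sum(m)
  }
  list(loglik = sum(log(cs)), gamma = gamma, xi = xi)
}

#' Fit a two-state Gaussian HMM to an enrichment-ratio track
#'
#' Baum-Welch EM with Gaussian emissions, run jointly over all
#' chromosomes with shared parameters. `NA` bins split the observation
#' sequence; each run restarts from the initial state distribution. After
#' fitting, states are labelled so that state 2 ("NAD") has the larger
#' mean.
#'
#' @param er An `EnrichmentTrack` (or `BinnedTrack`) of ER values.
#' @param init_strategy `"quantile"` starts the state means at the
#'   25th/75th ER percentiles with equal variances; `"spread"` at the
#'   10th/90th.
#' @param max_iter,tol EM stops when the log-likelihood improves by less
#'   than `tol` or after `max_iter` iterations.
#' @return An `HMMModel`: `means`, `variances` (named `inter`, `nad`),
#'   row-stochastic `transition`, `initial`, `loglik`, `loglik_trace`,
#'   `n_iter`.
#' @export
fit_hmm <- function(er, init_strategy = c("quantile", "spread"),
                    max_iter = 500, tol = 1e-6) {
  init_strategy <- match.arg(init_strategy)
  segs <- track_segments(er)
  if (length(segs) == 0) stop("no finite ER values")
  vals <- er$values[unlist(segs)]
  if (length(unique(vals)) < 2)
    stop("non-identifiable: all ER values identical")
  model <- hmm_init(vals, init_strategy)
  fit <- baum_welch(er, segs, model, max_iter, tol)
  share <- fit$state_share
  if (min(share) < 0.01) {
    warning(sprintf(
      "degenerate fit (state occupancy %.2g); refitting from spread init",
      min(share)))
    alt <- baum_welch(er, segs, hmm_init(vals, "spread", diag = 0.8),
                     max_iter, tol)
    if (min(alt$state_share) > min(share)) fit <- alt
  }
  fit[c("means", "variances", "transition", "initial", "loglik",
        "loglik_trace", "n_iter")] |>
    structure(class = "HMMModel")
}

hmm_init <- function(vals, strategy, diag = 0.95) {
  probs <- if (strategy == "quantile") c(0.25, 0.75) else c(0.1, 0.9)
  mu <- unname(stats::quantile(vals, probs))
  if (diff(mu) < 1e-8) mu <- mu + c(-1, 1) * max(1e-3, stats::sd(vals) / 2)
  # per-state spread from the median split keeps the initial emissions
  # separated for bimodal input instead of maximally overlapping
  md <- stats::median(vals)
  v <- c(stats::var(vals[vals <= md]), stats::var(vals[vals > md]))
  v[!is.finite(v) | v <= 0] <- stats::var(vals)
  list(means = mu, variances = pmax(v, 1e-6),
       transition = matrix(c(diag, 1 - diag, 1 - diag, diag), 2, 2,
                           byrow = TRUE),
       initial = c(0.5, 0.5))
}

baum_welch <- function(er, segs, model, max_iter, tol) {
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g_sum <- c(0, 0); xi_sum <- matrix(0, 2, 2); init_sum <- c(0, 0)
    mu_num <- c(0, 0); s2_num <- c(0, 0)
    gam_list <- vector("list", length(segs))
    for (s in seq_along(segs)) {
      x <- er$values[segs[[s]]]
      fb <- forward_backward(x, model)
      ll <- ll + fb$loglik
      g <- fb$gamma
      gam_list[[s]] <- g
      g_sum <- g_sum + colSums(g)
      xi_sum <- xi_sum + fb$xi
      init_sum <- init_sum + g[1, ]
      mu_num <- mu_num + colSums(g * x)
    }
    mu_new <- mu_num / g_sum
    for (s in seq_along(segs)) {
      x <- er$values[segs[[s]]]
      g <- gam_list[[s]]
      s2_num <- s2_num + c(sum(g[, 1] * (x - mu_new[1])^2),
                           sum(g[, 2] * (x - mu_new[2])^2))
    }
    model$means <- mu_new
    model$variances <- pmax(s2_num / g_sum, 1e-8)
    rs <- rowSums(xi_sum)
    if (all(rs > 0)) model$transition <- xi_sum / rs
    model$initial <- init_sum / sum(init_sum)
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < tol) break
  }
  # canonical label order: state 2 = NAD = larger mean
  if (model$means[1] > model$means[2]) {
    model$means <- rev(model$means)
    model$variances <- rev(model$variances)
    model$initial <- rev(model$initial)
    model$transition <- model$transition[2:1, 2:1]
  }
  names(model$means) <- names(model$variances) <- c("inter", "nad")
  model$loglik <- trace[length(trace)]
  model$loglik_trace <- trace
  model$n_iter <- length(trace)
  model$state_share <- g_sum / sum(g_sum)
  model
}

#' @export
print.HMMModel <- function(x, ...) {
  cat(sprintf(
    "Two-state Gaussian HMM: inter mean %.3f (sd %.3f), NAD mean %.3f (sd %.3f)\n",
    x$means[1], sqrt(x$variances[1]), x$means[2], sqrt(x$variances[2])))
  cat(sprintf("  transition stay-probabilities: %.3f / %.3f; loglik %.2f (%d iterations)\n",
              x$transition[1, 1], x$transition[2, 2], x$loglik, x$n_iter))
  invisible(x)
}

#' Most probable NAD/inter-NAD segmentation of an ER track
#'
#' Runs the Viterbi algorithm per chromosome chain (NA bins break chains)
#' and merges contiguous NAD-state bins into intervals. Per-bin posterior
#' NAD probabilities from forward-backward are retained.
#'
#' @param er An `EnrichmentTrack`.
#' @param model A fitted `HMMModel`.
#' @return A `NADCall`: `nads` (`DomainSet`, label "NAD"), `is_hnad`
#'   (all `FALSE` until [filter_hnads()]), `max_er` per NAD, `posterior`
#'   (`BinnedTrack` of NAD-state probability), `state` (logical per bin).
#' @export
viterbi_segment <- function(er, model) {
  segs <- track_segments(er)
  n <- er$binning$n
  state <- rep(FALSE, n)
  post <- rep(NA_real_, n)
  for (seg in segs) {
    x <- er$values[seg]
    state[seg] <- viterbi_path(x, model) == 2
    post[seg] <- forward_backward(x, model)$gamma[, 2]
  }
  max_er_bins <- ifelse(state, er$values, NA_real_)
  nads <- flags_to_domains(er$binning, state, label = "NAD",
                           score = max_er_bins)
  structure(list(nads = nads, is_hnad = rep(FALSE, nrow(nads)),
                 max_er = nads$score,
                 posterior = binned_track(er$binning, post),
                 state = state, model = model),
            class = "NADCall")
}

# log-space Viterbi for one observation run; returns state path (1/2)
viterbi_path <- function(x, model) {
  Tn <- length(x)
  lB <- log(gauss_dens(x, model$means, model$variances))
  lA <- log(model$transition)
  lpi <- log(model$initial)
  v <- matrix(-Inf, Tn, 2); ptr <- matrix(1L, Tn, 2)
  v[1, ] <- lpi + lB[1, ]
  if (Tn > 1) for (t in 2:Tn) for (s in 1:2) {
    cand <- v[t - 1, ] + lA[, s]
    ptr[t, s] <- which.max(cand)
    v[t, s] <- cand[ptr[t, s]] + lB[t, s]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(v[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  path
}

#' @export
print.NADCall <- function(x, ...) {
  cat(sprintf("NADCall: %d NADs (%d hNADs), %.1f Mb total\n",
              nrow(x$nads), sum(x$is_hnad),
              sum(x$nads$end - x$nads$start) / 1e6))
  invisible(x)
}

#' Flag high-confidence NADs
#'
#' A NAD is a high-confidence NAD (hNAD) when at least `min_bins` of its
#' bins have ER above `threshold` (default: one bin with ER > 1, i.e. a
#' two-fold depth ratio). The stricter reading requiring two qualifying
#' bins is available via `min_bins = 2`.
#'
#' @param call A `NADCall` from [viterbi_segment()].
#' @param er The `EnrichmentTrack` the call was made from.
#' @param threshold ER cutoff a bin must exceed.
#' @param min_bins Number of qualifying bins required.
#' @return The `NADCall` with `is_hnad` and `max_er` filled in.
#' @export
filter_hnads <- function(call, er, threshold = 1, min_bins = 1) {
  stopifnot(inherits(call, "NADCall"))
  nads <- call$nads
  if (nrow(nads) == 0) return(call)
  b <- er$binning$bins
  qual <- integer(nrow(nads)); mx <- numeric(nrow(nads))
  bi_start <- bin_index(er$binning, nads$chrom, nads$start)
  bi_end <- bin_index(er$binning, nads$chrom, nads$end - 1)
  for (k in seq_len(nrow(nads))) {
    v <- er$values[bi_start[k]:bi_end[k]]
    qual[k] <- sum(v > threshold, na.rm = TRUE)
    mx[k] <- suppressWarnings(max(v, na.rm = TRUE))
  }
  call$is_hnad <- qual >= min_bins
  call$max_er <- mx
  call$nads$score <- mx
  call
}

#' Extract the hNAD intervals of a call
#'
#' @param call A `NADCall` after [filter_hnads()].
#' @return A `DomainSet` labelled "hNAD", score = max ER.
#' @export
hnad_set <- function(call) {
  d <- call$nads[call$is_hnad, , drop = FALSE]
  domain_set(d$chrom, d$start, d$end, label = "hNAD", score = d$score)
}

#' Overlap statistics between two interval sets
#'
#' Base-pair overlap fraction (of A covered by B), base-pair Jaccard, and
#' an upper-tail hypergeometric p-value on bin counts: with N mappable
#' bins, m bins touched by B and k by A, the p-value is the probability
#' of observing at least the seen number of shared bins when A's bins are
#' drawn without replacement.
#'
#' @param set_a,set_b `DomainSet`s on the same genome.
#' @param binning The `GenomeBinning` defining the bin population.
#' @param mappable Optional logical per bin restricting the population.
#' @return List with `overlap_fraction`, `jaccard`, `hypergeom_p`,
#'   `overlap_bp`, `bins` (the 2x2-style counts used).
#' @export
overlap_stats <- function(set_a, set_b, binning, mappable = NULL) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0)
    return(list(overlap_fraction = 0, jaccard = 0, hypergeom_p = 1,
                overlap_bp = 0,
                bins = c(N = binning$n, m = 0, k = 0, q = 0)))
  ga <- GenomicRanges::reduce(domains_to_granges(set_a))
  gb <- GenomicRanges::reduce(domains_to_granges(set_b))
  ov <- sum(IRanges::width(suppressWarnings(
    GenomicRanges::intersect(ga, gb))))
  wa <- sum(IRanges::width(ga)); wb <- sum(IRanges::width(gb))
  if (is.null(mappable)) mappable <- rep(TRUE, binning$n)
  in_a <- bins_in_domains(binning, set_a) & mappable
  in_b <- bins_in_domains(binning, set_b) & mappable
  N <- sum(mappable); m <- sum(in_b); k <- sum(in_a)
  q <- sum(in_a & in_b)
  p <- stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
  list(overlap_fraction = ov / wa, jaccard = ov / (wa + wb - ov),
       hypergeom_p = p, overlap_bp = ov,
       bins = c(N = N, m = m, k = k, q = q))
}
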