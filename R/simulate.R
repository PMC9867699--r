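#' Simulation configuration with planted ground truth
#'
#' Bundles every parameter of the synthetic genome, depth, contact and
#' imaging generators. Defaults describe a toy genome small enough to
#' simulate in seconds while retaining the statistical structure the
#' pipeline assumes: NADs with elevated depth ratio, a checkerboard A/B
#' compartment profile, TAD blocks, trans contacts enriched between hNAD
#' bins and near centromeres, an rDNA repeat-unit artificial chromosome
#' with TR/IGS sub-domains, and two-channel 3D FISH/nucleolus stacks.
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param n_chroms,chrom_length_bp,bin_size Toy genome geometry.
#' @param nads_per_chrom,nad_length_bp Number and length of planted NADs
#'   per chromosome (evenly spaced, aligned to the TAD grid).
#' @param planted_nads Optional explicit `DomainSet` overriding automatic
#'   placement; all planted NADs double as planted hNADs.
#' @param nad_depth_fold Ratio of mean depth inside vs outside NADs in the
#'   treatment channel (> 1).
#' @param depth_noise_cv Coefficient of variation of the lognormal per-bin
#'   multiplicative noise on expected depth.
#' @param depth_mean Mean control depth per bin (reads).
#' @param compartment_block_bins A/B checkerboard block size in bins.
#' @param compartment_boost Multiplier `c` on cis contacts between
#'   same-sign compartment bins (> 1 creates the checkerboard).
#' @param tad_size_bins TAD block size in bins; boundaries on this grid.
#' @param tad_intra_boost Multiplier on cis contacts within one TAD.
#' @param decay_exponent Cis distance-decay exponent alpha (expected count
#'   proportional to distance^-alpha).
#' @param cis_weight Relative weight of the cis vs trans background, sets
#'   the overall cis fraction of the matrix.
#' @param trans_background_rate Baseline trans expected weight.
#' @param hnad_trans_boost Multiplier on trans contacts when both bins lie
#'   in planted hNADs (uniform archetype).
#' @param hnad_archetype Optional character vector over planted NADs in
#'   `{"G1","G2","G3"}` giving each a trans-interaction archetype;
#'   `NULL` = uniform boost for every hNAD pair.
#' @param archetype_matrix Symmetric 3x3 matrix (dimnames G1/G2/G3) of
#'   pairwise trans boosts between archetypes: G2 is near-silent, G3 a
#'   high-frequency hub, G1 interacts moderately and mostly with G3.
#' @param centromere_halfwidth_bp Centromere interval half-width; the
#'   centromere sits at each chromosome midpoint.
#' @param centromere_d0_bp Length scale of the `exp(-d/d0)` trans
#'   proximity factor; `NULL` disables it.
#' @param actd_mixing Lambda in `[0, 1]`: attenuates hNAD-specific
#'   structure (compartment boost and hNAD trans boost shrink toward 1 by
#'   `1 - lambda`) and scales the ActD cross-boundary boost, emulating
#'   nucleolus disassembly.
#' @param actd_boundary_boost Cross-boundary cis boost applied, scaled by
#'   `actd_mixing`, to adjacent-TAD contacts at TAD boundaries coinciding
#'   with planted NAD edges.
#' @param actd_trans_release Trans boost, scaled by `actd_mixing`,
#'   applied to pairs with exactly one end in a planted hNAD: chromatin
#'   released from disassembling nucleoli makes new trans contacts with
#'   the rest of the genome while the specific hNAD-hNAD clustering
#'   dissolves.
#' @param target_pairs Total expected contact count of the genome matrix.
#' @param rdna_unit_length,rdna_bin_size rDNA repeat-unit length and its
#'   (finer) bin size.
#' @param tr_igs_split_bp Within-unit boundary between the transcribed
#'   region (TR) and the intergenic spacer (IGS).
#' @param rdna_cis_fraction Expected fraction of rDNA-associated contacts
#'   that are within-unit.
#' @param rdna_coupling TR-IGS block coupling relative to within-block
#'   mean (block contrast is its reciprocal).
#' @param rdna_nad_boost Affinity of rDNA trans contacts for planted NAD
#'   bins.
#' @param rdna_total_pairs Expected rDNA-associated contact count.
#' @param image_dims Stack dimensions (z frames, y, x).
#' @param voxel_size_um Voxel pitch in micrometres, named `(z, y, x)`.
#' @param n_nucleoli Number of spherical nucleolus blobs.
#' @param nucleolus_radius_um Nucleolus radius.
#' @param planted_distances_um Planted focus-to-nucleolus-surface
#'   distances (0 places the focus inside the nucleolus).
#' @param focus_amplitude Peak FISH focus intensity above background, in
#'   units of the background noise standard deviation (the focus SNR).
#' @param nucleolus_amplitude Nucleolus-channel blob intensity in the
#'   same units; immunofluorescence of nucleolar proteins is a strong
#'   signal, so its default is high and independent of the focus SNR.
#' @param focus_sigma_um Gaussian focus widths, named `(z, y, x)`.
#' @param background_mean,background_sd Gaussian background parameters.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length_bp = 10e6,
                       bin_size = 100e3,
                       nads_per_chrom = 4L,
                       nad_length_bp = NULL,
                       planted_nads = NULL,
                       nad_depth_fold = 4,
                       depth_noise_cv = 0.3,
                       depth_mean = 100,
                       compartment_block_bins = 10L,
                       compartment_boost = 2,
                       tad_size_bins = 10L,
                       tad_intra_boost = 2,
                       decay_exponent = 1.0,
                       cis_weight = 60,
                       trans_background_rate = 1.0,
                       hnad_trans_boost = 3,
                       hnad_archetype = NULL,
                       archetype_matrix = matrix(
                         c(1.5, 0.3, 5,
                           0.3, 0.15, 0.3,
                           5, 0.3, 9), 3, 3,
                         dimnames = list(c("G1", "G2", "G3"),
                                         c("G1", "G2", "G3"))),
                       centromere_halfwidth_bp = 250e3,
                       centromere_d0_bp = NULL,
                       actd_mixing = 0,
                       actd_boundary_boost = 1,
                       actd_trans_release = 2,
                       target_pairs = 1e5,
                       rdna_unit_length = 43000,
                       rdna_bin_size = 1000,
                       tr_igs_split_bp = 13300,
                       rdna_cis_fraction = 0.76,
                       rdna_coupling = 0.2,
                       rdna_nad_boost = 3,
                       rdna_total_pairs = 2e4,
                       image_dims = c(31L, 160L, 160L),
                       voxel_size_um = c(z = 0.1, y = 0.1, x = 0.1),
                       n_nucleoli = 2L,
                       nucleolus_radius_um = 1.0,
                       planted_distances_um = seq(0, 2, length.out = 20),
                       focus_amplitude = 10,
                       nucleolus_amplitude = 10,
                       focus_sigma_um = c(z = 0.2, y = 0.12, x = 0.12),
                       background_mean = 2,
                       background_sd = 1) {
  stopifnot(nad_depth_fold >= 1, decay_exponent > 0,
            actd_mixing >= 0, actd_mixing <= 1,
            depth_noise_cv >= 0, rdna_cis_fraction > 0,
            rdna_cis_fraction < 1)
  if (is.null(nad_length_bp)) nad_length_bp <- 5 * tad_size_bins * bin_size / 5
  cfg <- as.list(environment())
  cfg$binning <- genome_binning(
    stats::setNames(rep(chrom_length_bp, n_chroms),
                    paste0("chr", seq_len(n_chroms))),
    bin_size)
  if (is.null(planted_nads)) cfg$planted_nads <- plant_nads(cfg)
  bad <- !(cfg$planted_nads$chrom %in% names(cfg$binning$chrom_sizes)) |
    cfg$planted_nads$end > cfg$binning$chrom_sizes[cfg$planted_nads$chrom]
  if (any(bad)) stop("planted NAD outside simulated chromosomes")
  if (!is.null(hnad_archetype) &&
      length(hnad_archetype) != nrow(cfg$planted_nads))
    stop("hnad_archetype must have one entry per planted NAD")
  cfg$centromeres <- domain_set(
    chrom = names(cfg$binning$chrom_sizes),
    start = pmax(0, cfg$binning$chrom_sizes / 2 - centromere_halfwidth_bp),
    end = cfg$binning$chrom_sizes / 2 + centromere_halfwidth_bp,
    label = "centromere")
  structure(cfg, class = "SimConfig")
}

# Evenly spaced NADs aligned to the TAD grid, avoiding chromosome edges.
plant_nads <- function(cfg) {
  grid <- cfg$tad_size_bins * cfg$bin_size
  len <- max(grid, round(cfg$nad_length_bp / grid) * grid)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  starts_one <- function() {
    k <- cfg$nads_per_chrom
    anchors <- (seq_len(k) - 0.5) / k * cfg$chrom_length_bp
    round(anchors / grid) * grid
  }
  st <- starts_one()
  domain_set(chrom = rep(chroms, each = cfg$nads_per_chrom),
             start = rep(st, times = cfg$n_chroms),
             end = pmin(rep(st, times = cfg$n_chroms) + len,
                        cfg$chrom_length_bp),
             label = "hNAD")
}

#' Per-bin A/B compartment sign of the simulated genome
#'
#' Alternating blocks of `compartment_block_bins` bins, restarting at +1
#' (A) at each chromosome start; bins inside planted NADs are forced to
#' B (-1), since nucleolus-associated chromatin is part of the inactive
#' compartment.
#' @param config A `SimConfig`.
#' @return Numeric vector of +1/-1 over bins.
#' @export
sim_compartment_profile <- function(config) {
  b <- config$binning$bins
  block <- (b$start %/% config$bin_size) %/% config$compartment_block_bins
  sign <- ifelse(block %% 2 == 0, 1, -1)
  sign[bins_in_domains(config$binning, config$planted_nads)] <- -1
  sign
}

#' TAD boundary positions of the simulated genome
#'
#' @param config A `SimConfig`.
#' @return DomainSet of TAD intervals on the regular grid.
#' @export
sim_tads <- function(config) {
  sizes <- config$binning$chrom_sizes
  grid <- config$tad_size_bins * config$bin_size
  pieces <- lapply(names(sizes), function(ch) {
    st <- seq(0, sizes[[ch]] - 1, by = grid)
    data.frame(chrom = ch, start = st, end = pmin(st + grid, sizes[[ch]]))
  })
  d <- do.call(rbind, pieces)
  domain_set(d$chrom, d$start, d$end, label = "TAD")
}

# lognormal multiplicative noise with unit mean and given CV
lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate paired depth tracks with planted NADs
#'
#' Control depth is Poisson around a flat mean; treatment depth is boosted
#' by `nad_depth_fold` inside planted NADs. Both receive independent
#' lognormal per-bin multiplicative noise of the configured CV.
#'
#' @param config A `SimConfig`.
#' @return List with `treatment` and `control` (`BinnedTrack`s) and
#'   `truth` (logical per-bin NAD indicator).
#' @export
simulate_depth_tracks <- function(config) {
  set.seed(config$seed %% 2147483647L)
  binning <- config$binning
  in_nad <- bins_in_domains(binning, config$planted_nads)
  mu0 <- config$depth_mean
  mu_t <- mu0 * ifelse(in_nad, config$nad_depth_fold, 1)
  ctrl <- stats::rpois(binning$n,
                       mu0 * lognorm_noise(binning$n, config$depth_noise_cv))
  trt <- stats::rpois(binning$n,
                      mu_t * lognorm_noise(binning$n, config$depth_noise_cv))
  list(treatment = binned_track(binning, trt),
       control = binned_track(binning, ctrl),
       truth = in_nad)
}

# per-bin planted-NAD index (0 = background)
bin_nad_index <- function(config) {
  hnad_bin_assignment(config$binning, config$planted_nads)
}

# pairwise trans boost matrix over planted NADs
nad_pair_boost <- function(config) {
  n_nad <- nrow(config$planted_nads)
  if (is.null(config$hnad_archetype))
    return(matrix(config$hnad_trans_boost, n_nad, n_nad))
  K <- config$archetype_matrix
  K[config$hnad_archetype, config$hnad_archetype, drop = FALSE]
}

# distance of each bin midpoint to its chromosome's centromere interval (bp)
bin_centromere_distance <- function(config) {
  b <- config$binning$bins
  mid <- (b$start + b$end) / 2
  cen <- config$centromeres
  d <- numeric(nrow(b))
  for (ch in unique(b$chrom)) {
    sel <- b$chrom == ch
    ci <- cen[cen$chrom == ch, , drop = FALSE]
    d[sel] <- pmax(0, pmax(ci$start[1] - mid[sel], mid[sel] - ci$end[1]))
  }
  d
}

# shrink a multiplicative boost toward 1 by the ActD mixing parameter
attenuate <- function(boost, lambda) 1 + (1 - lambda) * (boost - 1)

#' Simulate a genome-wide contact matrix
#'
#' Cis expected counts decay as `distance^-alpha`, boosted for same-sign
#' compartment pairs (checkerboard), within-TAD pairs, and — under ActD
#' mixing — across TAD boundaries that coincide with planted NAD edges.
#' Trans expected counts are a flat background boosted between planted
#' hNAD bins and, optionally, by centromere proximity. Counts are Poisson
#' draws around expectations scaled to `target_pairs` total.
#'
#' @param config A `SimConfig`.
#' @return A `ContactMatrix`.
#' @export
simulate_contacts <- function(config) {
  set.seed((config$seed + 1000L) %% 2147483647L)
  binning <- config$binning
  n <- binning$n
  comp <- sim_compartment_profile(config)
  nad_idx <- bin_nad_index(config)
  pairK <- nad_pair_boost(config)
  lam <- config$actd_mixing
  c_eff <- attenuate(config$compartment_boost, lam)
  xb_eff <- attenuate(config$actd_boundary_boost, 1 - lam)
  chrom <- binning$bins$chrom
  tad_id <- cumsum(!duplicated(chrom)) * 1e6 +
    (binning$bins$start %/% (config$tad_size_bins * config$bin_size))
  nad_edge_tad <- nad_edge_tad_ids(config, tad_id)

  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_chrom <- chrom[i] == chrom[j]
  mu <- numeric(length(i))

  # cis: decay * compartment * TAD (+ ActD cross-boundary at NAD edges)
  ci <- which(same_chrom)
  d_bins <- j[ci] - i[ci]
  m <- config$cis_weight * (d_bins + 1)^(-config$decay_exponent)
  same_sign <- comp[i[ci]] * comp[j[ci]] > 0
  m[same_sign] <- m[same_sign] * c_eff
  same_tad <- tad_id[i[ci]] == tad_id[j[ci]]
  m[same_tad] <- m[same_tad] * config$tad_intra_boost
  if (xb_eff != 1 && length(nad_edge_tad)) {
    adj <- tad_id[j[ci]] == tad_id[i[ci]] + 1 &
      tad_id[j[ci]] %in% nad_edge_tad
    m[adj] <- m[adj] * xb_eff
  }
  mu[ci] <- m

  # trans: background, boosted when both ends lie in planted hNADs,
  # modulated by centromere proximity
  ti <- which(!same_chrom)
  boost <- rep(1, length(ti))
  both <- nad_idx[i[ti]] > 0 & nad_idx[j[ti]] > 0
  boost[both] <- pairK[cbind(nad_idx[i[ti]][both], nad_idx[j[ti]][both])]
  m <- config$trans_background_rate * attenuate(boost, lam)
  # nucleolus disassembly releases hNAD chromatin into new trans contacts
  one <- xor(nad_idx[i[ti]] > 0, nad_idx[j[ti]] > 0)
  m[one] <- m[one] * attenuate(config$actd_trans_release, 1 - lam)
  if (!is.null(config$centromere_d0_bp)) {
    cend <- bin_centromere_distance(config)
    f <- exp(-cend / config$centromere_d0_bp)
    m <- m * f[i[ti]] * f[j[ti]]
  }
  mu[ti] <- m

  mu <- mu * (config$target_pairs / sum(mu))
  x <- stats::rpois(length(mu), mu)
  keep <- x > 0
  contact_matrix(binning, i[keep], j[keep], x[keep])
}

# TAD ids whose left boundary coincides with a planted NAD start or end
nad_edge_tad_ids <- function(config, tad_id) {
  nads <- config$planted_nads
  if (nrow(nads) == 0) return(numeric())
  edges <- unique(data.frame(chrom = rep(nads$chrom, 2),
                             pos = c(nads$start, nads$end)))
  edges <- edges[edges$pos > 0 &
                   edges$pos < config$binning$chrom_sizes[edges$chrom], ]
  if (nrow(edges) == 0) return(numeric())
  bi <- bin_index(config$binning, edges$chrom, edges$pos)
  unique(tad_id[bi])
}

#' rDNA repeat-unit description
#'
#' @param chrom Name of the artificial chromosome carrying the unit.
#' @param length_bp Unit length (43 kb canonical human repeat).
#' @param bin_size Within-unit bin size.
#' @param tr_igs_split_bp 5' transcribed region / 3' intergenic spacer
#'   boundary within the unit.
#' @return An `RdnaUnit` list.
#' @export
rdna_unit <- function(chrom = "rDNA", length_bp = 43000, bin_size = 1000,
                      tr_igs_split_bp = 13300) {
  stopifnot(tr_igs_split_bp > 0, tr_igs_split_bp < length_bp)
  structure(list(chrom = chrom, length_bp = length_bp,
                 bin_size = bin_size, tr_igs_split_bp = tr_igs_split_bp),
            class = "RdnaUnit")
}

#' Append simulated rDNA repeat-unit contacts to a matrix
#'
#' Adds an artificial chromosome carrying one rDNA repeat unit, binned
#' finer than the genome. Within-unit contacts follow a two-block model
#' (TR block; IGS block with two sub-blocks; weak TR-IGS coupling) and
#' rDNA-genome trans contacts are enriched toward planted NAD bins. The
#' expected within-unit share of all rDNA contacts is
#' `config$rdna_cis_fraction`.
#'
#' @param config A `SimConfig`.
#' @param matrix A `ContactMatrix` from [simulate_contacts()].
#' @return List with `matrix` (extended `ContactMatrix`) and `unit` (the
#'   `RdnaUnit`).
#' @export
simulate_rdna_contacts <- function(config, matrix) {
  set.seed((config$seed + 2000L) %% 2147483647L)
  unit <- rdna_unit(length_bp = config$rdna_unit_length,
                    bin_size = config$rdna_bin_size,
                    tr_igs_split_bp = config$tr_igs_split_bp)
  old <- matrix$binning
  sizes <- c(old$chrom_sizes, stats::setNames(unit$length_bp, unit$chrom))
  binning <- genome_binning(sizes, old$bin_size,
                            bin_size_overrides =
                              stats::setNames(unit$bin_size, unit$chrom))
  n_gen <- old$n
  n_r <- binning$n - n_gen

  # within-unit block model
  starts <- binning$bins$start[(n_gen + 1):binning$n]
  tr <- starts < unit$tr_igs_split_bp
  igs_mid <- (unit$tr_igs_split_bp + unit$length_bp) / 2
  sub <- ifelse(tr, 0L, ifelse(starts < igs_mid, 1L, 2L))
  idx <- which(upper.tri(matrix(0, n_r, n_r), diag = TRUE), arr.ind = TRUE)
  ri <- idx[, 1]; rj <- idx[, 2]
  w <- numeric(length(ri))
  both_tr <- tr[ri] & tr[rj]
  both_igs <- !tr[ri] & !tr[rj]
  cross <- !both_tr & !both_igs
  w[both_tr] <- 1
  w[both_igs] <- ifelse(sub[ri[both_igs]] == sub[rj[both_igs]], 1.3, 0.7)
  w[cross] <- config$rdna_coupling
  # rebalance IGS so its block mean stays 1 (keeps contrast = 1/coupling)
  if (any(both_igs)) w[both_igs] <- w[both_igs] / mean(w[both_igs])
  mu_cis <- w * (config$rdna_cis_fraction * config$rdna_total_pairs / sum(w))

  # trans to genome, enriched toward planted NAD bins
  aff <- ifelse(bins_in_domains(old, config$planted_nads),
                config$rdna_nad_boost, 1)
  tg <- expand.grid(g = seq_len(n_gen), r = seq_len(n_r))
  wt <- aff[tg$g]
  mu_trans <- wt * ((1 - config$rdna_cis_fraction) *
                      config$rdna_total_pairs / sum(wt))

  x_cis <- stats::rpois(length(mu_cis), mu_cis)
  x_trans <- stats::rpois(length(mu_trans), mu_trans)
  keep_c <- x_cis > 0; keep_t <- x_trans > 0
  new_i <- c(matrix$i, n_gen + ri[keep_c], tg$g[keep_t])
  new_j <- c(matrix$j, n_gen + rj[keep_c], n_gen + tg$r[keep_t])
  new_x <- c(matrix$x, x_cis[keep_c], x_trans[keep_t])
  list(matrix = contact_matrix(binning, new_i, new_j, new_x), unit = unit)
}

#' Simulate a two-channel 3D FISH / nucleolus image stack
#'
#' The nucleolus channel holds spherical blobs with a soft intensity edge
#' plus Gaussian background noise; the FISH channel holds 3D Gaussian foci
#' placed at the planted surface distances around the nucleoli. Truth
#' records planted centroids, the noiseless nucleolus mask, and planted
#' distances.
#'
#' @param config A `SimConfig`.
#' @return List with `fish` and `nucleolus` (`ImageStack`s) and `truth`
#'   (list: `centroids_um`, `distances_um`, `mask` array, `centers_um`,
#'   `radius_um`).
#' @export
simulate_image_stack <- function(config) {
  set.seed((config$seed + 3000L) %% 2147483647L)
  dims <- config$image_dims  # (z, y, x)
  vs <- config$voxel_size_um # (z, y, x)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  ext <- c(nz * vs[1], ny * vs[2], nx * vs[3])
  r <- config$nucleolus_radius_um

  centers <- t(vapply(seq_len(config$n_nucleoli), function(k) {
    fy <- (k - 0.5) / config$n_nucleoli
    c(ext[1] / 2, ext[2] * fy, ext[3] * (0.3 + 0.4 * ((k - 1) %% 2)))
  }, numeric(3)))

  # physical coordinates of voxel centres
  zc <- (seq_len(nz) - 0.5) * vs[1]
  yc <- (seq_len(ny) - 0.5) * vs[2]
  xc <- (seq_len(nx) - 0.5) * vs[3]

  mask <- array(FALSE, dim = c(ny, nx, nz))
  nucl <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nrow(centers))) {
    cz <- centers[k, 1]; cy <- centers[k, 2]; cx <- centers[k, 3]
    for (z in seq_len(nz)) {
      dz2 <- (zc[z] - cz)^2
      dd <- sqrt(outer((yc - cy)^2, (xc - cx)^2, `+`) + dz2)
      mask[, , z] <- mask[, , z] | (dd <= r)
      # soft edge: 0.2 um ramp centred on the radius, so the
      # half-intensity surface coincides with the planted sphere
      nucl[, , z] <- pmax(nucl[, , z],
                          config$nucleolus_amplitude *
                            config$background_sd *
                            pmin(1, pmax(0, (r + 0.1 - dd) / 0.2)))
    }
  }

  # foci around alternating nucleoli at the planted surface distances
  nd <- length(config$planted_distances_um)
  theta <- 2 * pi * (seq_len(nd) - 1) / nd + 0.2
  cents <- matrix(0, nd, 3)
  for (k in seq_len(nd)) {
    host <- (k - 1) %% nrow(centers) + 1
    d <- config$planted_distances_um[k]
    rad <- if (d == 0) r * 0.4 else r + d
    cents[k, ] <- centers[host, ] +
      c(0, rad * sin(theta[k]), rad * cos(theta[k]))
  }
  cents[, 2] <- pmin(pmax(cents[, 2], 3 * vs[2]), ext[2] - 3 * vs[2])
  cents[, 3] <- pmin(pmax(cents[, 3], 3 * vs[3]), ext[3] - 3 * vs[3])

  fish <- array(0, dim = c(ny, nx, nz))
  sig <- config$focus_sigma_um
  amp <- config$focus_amplitude * config$background_sd
  for (k in seq_len(nd)) {
    gz <- exp(-(zc - cents[k, 1])^2 / (2 * sig[1]^2))
    gy <- exp(-(yc - cents[k, 2])^2 / (2 * sig[2]^2))
    gx <- exp(-(xc - cents[k, 3])^2 / (2 * sig[3]^2))
    for (z in which(gz > 1e-4))
      fish[, , z] <- fish[, , z] + amp * gz[z] * outer(gy, gx)
  }

  noise <- function() array(stats::rnorm(ny * nx * nz,
                                         config$background_mean,
                                         config$background_sd),
                            dim = c(ny, nx, nz))
  fish_stack <- image_stack(pmax(fish + noise(), 0), vs, channel = "FISH")
  nucl_stack <- image_stack(pmax(nucl + noise(), 0), vs,
                            channel = "nucleolus")

  # planted truth: exact sphere-surface distance in physical units
  dist_true <- vapply(seq_len(nd), function(k) {
    min(vapply(seq_len(nrow(centers)), function(h)
      max(0, sqrt(sum((cents[k, ] - centers[h, ])^2)) - r), numeric(1)))
  }, numeric(1))

  list(fish = fish_stack, nucleolus = nucl_stack,
       truth = list(centroids_um = cents, distances_um = dist_true,
                    mask = mask, centers_um = centers, radius_um = r))
}
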