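#' 3D single-channel image stack with physical voxel sizes
#'
#' @param voxels Numeric array `[y, x, z]` of intensities.
#' @param voxel_size_um Named numeric `(z, y, x)` voxel pitch in
#'   micrometres.
#' @param channel Channel label.
#' @return An `ImageStack`.
#' @export
image_stack <- function(voxels, voxel_size_um, channel = "") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            length(voxel_size_um) == 3, all(voxel_size_um > 0),
            all(is.finite(voxels)))
  structure(list(voxels = voxels,
                 voxel_size_um = stats::setNames(as.numeric(voxel_size_um),
                                                 c("z", "y", "x")),
                 channel = channel),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "ImageStack '%s': %d frames of %dx%d, voxel %.3g x %.3g x %.3g um (z,y,x)\n",
    x$channel, d[3], d[1], d[2],
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Segment nucleoli per frame
#'
#' Each frame is binarized with its Otsu threshold, connected components
#' smaller than `min_size` pixels are removed, the mask is closed with a
#' disk (dilation then erosion), and interior holes are filled. As a
#' guard against signal-free frames (whose per-frame Otsu threshold
#' merely splits the background noise), the effective threshold is never
#' allowed below the stack-wide Otsu threshold; frames with zero
#' variance yield an empty mask.
#'
#' @param stack Single-channel `ImageStack` (nucleolus channel).
#' @param min_size Minimum cluster size in pixels.
#' @param disk_radius Radius of the closing disk in pixels.
#' @return A `NucleolusMask`: `mask` (logical array `[y, x, z]`),
#'   `voxel_size_um`, per-frame region counts.
#' @export
segment_nucleolus <- function(stack, min_size = 4, disk_radius = 5) {
  arr <- stack$voxels
  nz <- dim(arr)[3]
  mask <- array(FALSE, dim(arr))
  brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
  rg_all <- range(arr)
  glob <- if (diff(rg_all) > 0)
    EBImage::otsu(EBImage::Image((arr - rg_all[1]) / diff(rg_all))) *
      diff(rg_all) + rg_all[1]
  else Inf
  for (z in seq_len(nz)) {
    fr <- arr[, , z]
    rg <- range(fr)
    if (diff(rg) == 0) next
    fr01 <- (fr - rg[1]) / diff(rg)
    th <- EBImage::otsu(EBImage::Image(fr01)) * diff(rg) + rg[1]
    bw <- fr > max(th, glob)
    if (sum(bw) < min_size) next
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab)
    small <- which(sizes < min_size)
    if (length(small)) bw[lab %in% small] <- FALSE
    bw <- EBImage::closing(EBImage::Image(bw * 1), brush)
    bw <- EBImage::fillHull(bw)
    mask[, , z] <- as.array(bw) > 0
  }
  structure(list(mask = mask, voxel_size_um = stack$voxel_size_um,
                 frame_area = apply(mask, 3, sum)),
            class = "NucleolusMask")
}

#' @export
print.NucleolusMask <- function(x, ...) {
  cat(sprintf("NucleolusMask: %d frames, %d mask voxels\n",
              dim(x$mask)[3], sum(x$mask)))
  invisible(x)
}

#' Detect FISH foci with z-persistence filtering
#'
#' Per frame, the foreground is where the raw image exceeds the
#' mean-filtered image by the relative margin `intensity_thresh`;
#' components smaller than `area_thresh` pixels are dropped. Components
#' are linked across consecutive frames by pixel overlap, and clusters
#' spanning more than `min_z_frames` consecutive frames are retained
#' (strict reading: a cluster must occupy at least `min_z_frames + 1`
#' frames). Centroids are intensity-weighted over the cluster's voxels.
#'
#' @param stack Single-channel `ImageStack` (FISH channel).
#' @param mean_filter_size Side of the square mean filter in pixels.
#' @param intensity_thresh Relative excess over the local mean required
#'   for foreground (0.5 = 50 percent above).
#' @param area_thresh Minimum per-frame component area in pixels.
#' @param min_z_frames Persistence: clusters must span more than this
#'   many frames.
#' @param min_total_intensity Optional cluster-level intensity threshold:
#'   clusters whose summed voxel intensity falls below it are discarded
#'   as non-specific signal (0 disables).
#' @return Data frame of foci: centroid voxel coordinates (`z`, `y`,
#'   `x`, fractional, 1-based), centroid in micrometres (`z_um`, `y_um`,
#'   `x_um`), `n_frames`, `total_intensity`.
#' @export
detect_fish_foci <- function(stack, mean_filter_size = 9,
                             intensity_thresh = 0.5, area_thresh = 4,
                             min_z_frames = 3, min_total_intensity = 0) {
  arr <- stack$voxels
  d <- dim(arr); nz <- d[3]
  kern <- matrix(1 / mean_filter_size^2, mean_filter_size,
                 mean_filter_size)
  vox <- list()   # per global component id: data.frame(y, x, z, val)
  frame_ids <- vector("list", nz)  # label matrix -> global id
  parent <- integer(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  next_id <- 0L
  prev_lab <- NULL; prev_map <- NULL
  for (z in seq_len(nz)) {
    fr <- arr[, , z]
    mf <- as.array(EBImage::filter2(EBImage::Image(fr), kern,
                                    boundary = "replicate"))
    fg <- fr > mf * (1 + intensity_thresh)
    lab <- as.array(EBImage::bwlabel(EBImage::Image(fg * 1)))
    sizes <- tabulate(lab)
    small <- which(sizes < area_thresh)
    if (length(small)) lab[lab %in% small] <- 0L
    labs_here <- setdiff(unique(as.integer(lab)), 0L)
    map <- integer(max(labs_here, 0L))
    for (l in labs_here) {
      next_id <- next_id + 1L
      parent[next_id] <- next_id
      map[l] <- next_id
      sel <- which(lab == l, arr.ind = TRUE)
      vox[[next_id]] <- data.frame(y = sel[, 1], x = sel[, 2], z = z,
                                   val = fr[sel])
    }
    if (!is.null(prev_lab) && length(labs_here)) {
      both <- prev_lab > 0 & lab > 0
      if (any(both)) {
        pairs <- unique(cbind(prev_lab[both], lab[both]))
        for (r in seq_len(nrow(pairs))) {
          a <- find(prev_map[pairs[r, 1]]); b <- find(map[pairs[r, 2]])
          if (a != b) parent[b] <- a
        }
      }
    }
    prev_lab <- lab; prev_map <- map
  }
  if (next_id == 0L)
    return(empty_foci())
  roots <- vapply(seq_len(next_id), find, integer(1))
  out <- list()
  vs <- stack$voxel_size_um
  for (r in unique(roots)) {
    vv <- do.call(rbind, vox[roots == r])
    nfr <- length(unique(vv$z))
    if (nfr <= min_z_frames) next
    if (sum(vv$val) < min_total_intensity) next
    w <- vv$val / sum(vv$val)
    cz <- sum(w * vv$z); cy <- sum(w * vv$y); cx <- sum(w * vv$x)
    out[[length(out) + 1]] <- data.frame(
      z = cz, y = cy, x = cx,
      z_um = (cz - 0.5) * vs["z"], y_um = (cy - 0.5) * vs["y"],
      x_um = (cx - 0.5) * vs["x"],
      n_frames = nfr, total_intensity = sum(vv$val))
  }
  if (length(out) == 0) return(empty_foci())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_foci <- function() {
  data.frame(z = numeric(), y = numeric(), x = numeric(),
             z_um = numeric(), y_um = numeric(), x_um = numeric(),
             n_frames = integer(), total_intensity = numeric())
}

#' Distance from a focus centroid to the nearest nucleolus voxel
#'
#' Anisotropy-corrected 3D Euclidean distance from the centroid to the
#' closest voxel centre of the mask; 0 when the centroid falls inside a
#' mask voxel.
#'
#' @param centroid_um Numeric `(z, y, x)` centroid in micrometres.
#' @param mask A `NucleolusMask` (or logical array `[y, x, z]`).
#' @param voxel_size_um Required when `mask` is a bare array.
#' @return Distance in micrometres; `NA` for an empty mask.
#' @export
focus_nucleolus_distance <- function(centroid_um, mask,
                                     voxel_size_um = NULL) {
  if (inherits(mask, "NucleolusMask")) {
    voxel_size_um <- mask$voxel_size_um
    mask <- mask$mask
  }
  stopifnot(!is.null(voxel_size_um))
  idx <- which(mask, arr.ind = TRUE)  # (y, x, z)
  if (nrow(idx) == 0) return(NA_real_)
  vz <- voxel_size_um[1]; vy <- voxel_size_um[2]; vx <- voxel_size_um[3]
  # voxel containing the centroid
  home <- c(floor(centroid_um[2] / vy), floor(centroid_um[3] / vx),
            floor(centroid_um[1] / vz)) + 1
  home <- pmax(home, 1)
  if (home[1] <= dim(mask)[1] && home[2] <= dim(mask)[2] &&
      home[3] <= dim(mask)[3] && mask[home[1], home[2], home[3]])
    return(0)
  dz <- (idx[, 3] - 0.5) * vz - centroid_um[1]
  dy <- (idx[, 1] - 0.5) * vy - centroid_um[2]
  dx <- (idx[, 2] - 0.5) * vx - centroid_um[3]
  min(sqrt(dz^2 + dy^2 + dx^2))
}

#' FISH focus to nucleolus distances for a two-channel acquisition
#'
#' Runs [segment_nucleolus()] on the nucleolus channel,
#' [detect_fish_foci()] on the FISH channel, and computes each focus'
#' distance to the nearest nucleolus voxel.
#'
#' @param fish,nucleolus `ImageStack`s of the two channels.
#' @param ... Passed on to [detect_fish_foci()].
#' @return Data frame: focus columns plus `distance_um`.
#' @export
fish_distances <- function(fish, nucleolus, ...) {
  mask <- segment_nucleolus(nucleolus)
  foci <- detect_fish_foci(fish, ...)
  foci$distance_um <- vapply(seq_len(nrow(foci)), function(k)
    focus_nucleolus_distance(c(foci$z_um[k], foci$y_um[k], foci$x_um[k]),
                             mask), numeric(1))
  foci
}
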