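#' Sparse symmetric contact matrix on a genome binning
#'
#' Stores the upper triangle only (i <= j, 1-based bin row indices).
#' Duplicate (i, j) entries are summed; (j, i) entries are mirrored into
#' canonical order on construction.
#'
#' @param binning A `GenomeBinning`.
#' @param i,j Integer bin indices of each contact entry.
#' @param x Non-negative contact counts.
#' @param weights Optional per-bin balancing weights (strictly positive
#'   where defined, `NA` for masked bins).
#' @return A `ContactMatrix`: list with `binning`, `i`, `j`, `x`,
#'   `weights`, `total` (sum of counts).
#' @export
contact_matrix <- function(binning, i, j, x, weights = NULL) {
  stopifnot(inherits(binning, "GenomeBinning"),
            length(i) == length(j), length(j) == length(x))
  i <- as.integer(i); j <- as.integer(j); x <- as.numeric(x)
  if (length(x) && (min(i, j) < 1 || max(i, j) > binning$n))
    stop("bin index out of range [1, ", binning$n, "]")
  if (any(x < 0)) stop("negative contact counts")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (length(x)) {
    key <- paste(i, j)
    if (anyDuplicated(key)) {
      agg <- rowsum(x, key, reorder = FALSE)
      ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
      x <- as.numeric(agg[, 1])
    }
    o <- order(i, j)
    i <- i[o]; j <- j[o]; x <- x[o]
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == binning$n)
    if (any(weights[!is.na(weights)] <= 0))
      stop("balancing weights must be strictly positive where defined")
  }
  structure(list(binning = binning, i = i, j = j, x = x,
                 weights = weights, total = sum(x)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf(
    "ContactMatrix: %d bins, %d non-zero entries, %.0f total counts%s\n",
    x$binning$n, length(x$x), x$total,
    if (is.null(x$weights)) "" else " (balanced)"))
  invisible(x)
}

#' Dense symmetric submatrix of a contact matrix
#'
#' @param cm A `ContactMatrix`.
#' @param bins Integer bin indices (default all).
#' @param balanced Apply balancing weights (`w_i * w_j * count`)? Requires
#'   `cm$weights`; masked bins yield `NA` rows/columns.
#' @return Dense numeric matrix over `bins`.
#' @export
dense_matrix <- function(cm, bins = seq_len(cm$binning$n),
                         balanced = FALSE) {
  n <- cm$binning$n
  sel <- cm$i %in% bins & cm$j %in% bins
  pos <- integer(n); pos[bins] <- seq_along(bins)
  m <- matrix(0, length(bins), length(bins))
  ii <- pos[cm$i[sel]]; jj <- pos[cm$j[sel]]; xx <- cm$x[sel]
  if (balanced) {
    if (is.null(cm$weights)) stop("matrix has no balancing weights")
    xx <- xx * cm$weights[cm$i[sel]] * cm$weights[cm$j[sel]]
  }
  m[cbind(ii, jj)] <- xx
  m[cbind(jj, ii)] <- xx
  if (balanced) {
    bad <- which(is.na(cm$weights[bins]))
    m[bad, ] <- NA_real_
    m[, bad] <- NA_real_
  }
  m
}

#' Per-bin marginal counts (row sums of the full symmetric matrix)
#'
#' Diagonal entries count once.
#' @param cm A `ContactMatrix`.
#' @param balanced Apply balancing weights?
#' @return Numeric vector over all bins.
#' @export
bin_coverage <- function(cm, balanced = FALSE) {
  x <- cm$x
  if (balanced) {
    if (is.null(cm$weights)) stop("matrix has no balancing weights")
    x <- x * cm$weights[cm$i] * cm$weights[cm$j]
    x[is.na(x)] <- 0  # entries touching masked bins are excluded
  }
  cov <- numeric(cm$binning$n)
  off <- cm$i != cm$j
  cov <- cov + unname(tapply_add(cm$i, x, cm$binning$n))
  cov + unname(tapply_add(cm$j[off], x[off], cm$binning$n))
}

tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Chromosome of each bin index
#' @keywords internal
bin_chrom <- function(binning) binning$bins$chrom
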