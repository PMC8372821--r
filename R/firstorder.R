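#' First-order intensity features
#'
#' The 17 first-order features summarize the ROI's intensity distribution
#' without regard to spatial arrangement. Entropy and uniformity are computed
#' over the `N_g`-bin discretized level histogram (base-2 entropy); all other
#' features use the raw intensities. Variance is the population variance;
#' kurtosis is the uncorrected fourth standardized moment (3 for a Gaussian);
#' skewness and kurtosis of a constant ROI are defined as 0 so degenerate
#' ROIs never produce NaN.
#'
#' @param voxels Numeric vector of ROI intensities (>= 1 value).
#' @param disc A `disc_roi` from [discretize()] for the same ROI; used only
#'   for the entropy/uniformity histogram.
#' @return Named numeric vector of length 17 (names `Mean`, `Median`,
#'   `Minimum`, `Maximum`, `Range`, `Variance`, `StandardDeviation`,
#'   `Skewness`, `Kurtosis`, `Energy`, `RootMeanSquare`,
#'   `MeanAbsoluteDeviation`, `Entropy`, `Uniformity`, `P10`, `P90`,
#'   `InterquartileRange`).
#' @examples
#' d <- discretize(array(1:4, c(4, 1, 1)), array(TRUE, c(4, 1, 1)))
#' firstorder_features(1:4, d)[c("Mean", "Variance", "Range")]
#' @export
firstorder_features <- function(voxels, disc) {
  if (!length(voxels))
    stop("firstorder_features: empty voxel set", call. = FALSE)
  stopifnot(inherits(disc, "disc_roi"))
  x <- as.numeric(voxels)
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)                       # population variance
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 else 0
  lv <- disc$levels[disc$mask]
  p <- tabulate(lv, nbins = disc$n_levels) / length(lv)
  p <- p[p > 0]
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  c(Mean = m,
    Median = stats::median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = v,
    StandardDeviation = s,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    RootMeanSquare = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    P10 = qs[1],
    P90 = qs[4],
    InterquartileRange = qs[3] - qs[2])
}

#' Morphological (shape) features of an ROI mask
#'
#' Seven descriptors of the binary mask geometry, computed on the voxel
#' grid: volume as voxel count times voxel volume; surface area by counting
#' exposed voxel faces (the boxy face-count surface, not a fitted mesh);
#' surface-to-volume ratio; sphericity `pi^(1/3) (6V)^(2/3) / A`;
#' compactness `V / (sqrt(pi) A^(3/2))`; spherical disproportion `A /
#' (4 pi r^2)` with `r` the radius of the equal-volume sphere; and the
#' maximum 3D diameter (largest pairwise distance between voxel centers).
#'
#' @param mask Logical 3D array.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return Named numeric vector of length 7 (`VoxelVolume`, `SurfaceArea`,
#'   `SurfaceVolumeRatio`, `Sphericity`, `Compactness`,
#'   `SphericalDisproportion`, `Maximum3DDiameter`).
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("shape_features: mask must be a logical 3D array", call. = FALSE)
  if (!any(mask))
    stop("shape_features: empty mask", call. = FALSE)
  sp <- as.numeric(spacing)
  d <- dim(mask)
  nv <- sum(mask)
  vol <- nv * prod(sp)
  # exposed faces along each axis: neighbour outside mask or outside grid
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  shift_out <- function(axis, step) {
    # TRUE where the neighbour at +step along axis is OUTSIDE the mask
    idx <- vector("list", 3); for (k in 1:3) idx[[k]] <- seq_len(d[k])
    nb <- array(FALSE, d)
    src <- idx; dst <- idx
    if (step == 1L) { dst[[axis]] <- seq_len(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
    else            { dst[[axis]] <- 2:d[axis]; src[[axis]] <- seq_len(d[axis] - 1L) }
    if (d[axis] > 1L)
      nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    sum(mask & !nb)
  }
  area <- 0
  for (axis in 1:3)
    area <- area + face_area[axis] * (shift_out(axis, 1L) + shift_out(axis, -1L))
  # maximum pairwise distance between voxel centers (exact over boundary voxels)
  bnd <- boundary_voxels(mask)
  pts <- which(bnd, arr.ind = TRUE)
  if (nrow(pts) < 2L) {
    maxd <- 0
  } else {
    P <- sweep(pts - 1, 2, sp, `*`)
    maxd <- sqrt(max_pairwise_sq(P))
  }
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  c(VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    Compactness = vol / (sqrt(pi) * area^(3 / 2)),
    SphericalDisproportion = area / (4 * pi * r_eq^2),
    Maximum3DDiameter = maxd)
}

# voxels of the mask with at least one 6-neighbour outside (or on the grid edge)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- array(TRUE, d)
  for (axis in 1:3) {
    idx <- lapply(d, seq_len)
    for (step in c(1L, -1L)) {
      nb <- array(FALSE, d)
      dst <- idx; src <- idx
      if (step == 1L) { dst[[axis]] <- seq_len(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
      else            { dst[[axis]] <- 2:d[axis]; src[[axis]] <- seq_len(d[axis] - 1L) }
      if (d[axis] > 1L)
        nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      inner <- inner & nb
    }
  }
  mask & !inner
}

# max squared Euclidean distance between rows of P, blockwise to bound memory
max_pairwise_sq <- function(P, block = 512L) {
  n <- nrow(P)
  sq <- rowSums(P^2)
  best <- 0
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(n, i0 + block - 1L)
    G <- P[i0:i1, , drop = FALSE] %*% t(P)
    D <- outer(sq[i0:i1], sq, `+`) - 2 * G
    best <- max(best, max(D))
  }
  max(best, 0)
}
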