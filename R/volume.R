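#' Construct a 3D volume
#'
#' A `rad_volume` is the image substrate for every stage of the pipeline: a
#' 3D numeric grid plus the voxel spacing (mm) and world origin needed to
#' reason about physical extent. Label maps use the same container with
#' non-negative integer values (see [as_labelmap()]).
#'
#' @param values Numeric 3D array. All values must be finite.
#' @param spacing Numeric vector of length 3, per-axis voxel size in mm
#'   (all > 0).
#' @param origin Numeric vector of length 3, world coordinate of the center
#'   of voxel (1,1,1).
#' @return An object of class `rad_volume`.
#' @examples
#' v <- rad_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(2, 2, 2))
#' dim(v$values)
#' @export
rad_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("rad_volume: 'values' must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("rad_volume: grid must have at least one voxel per axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("rad_volume: spacing must be 3 positive numbers", call. = FALSE)
  if (any(!is.finite(values)))
    stop("rad_volume: all values must be finite", call. = FALSE)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "rad_volume")
}

#' @exportS3Method print rad_volume
print.rad_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rad_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Mark a volume as an integer label map
#'
#' Validates that values are non-negative integers (0 = background) and tags
#' the object so resampling defaults to nearest-neighbour interpolation.
#'
#' @param v A `rad_volume` whose values are whole numbers >= 0.
#' @return The volume with class `rad_labelmap` prepended.
#' @export
as_labelmap <- function(v) {
  stopifnot(inherits(v, "rad_volume"))
  if (any(v$values < 0) || any(v$values != round(v$values)))
    stop("as_labelmap: labels must be non-negative integers", call. = FALSE)
  v$values <- array(as.integer(round(v$values)), dim(v$values))
  class(v) <- unique(c("rad_labelmap", class(v)))
  v
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file, taking voxel spacing and origin from the
#' header. Label maps should be passed through [as_labelmap()] after reading.
#'
#' @param path Path to a NIfTI-1 file containing a 3D image.
#' @return A [rad_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: '%s'", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("read_volume: unreadable header in '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("read_volume: non-3D data (%d dimensions) in '%s'",
                 length(d), path), call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[seq_len(3), 4])
  rad_volume(array(as.numeric(img), d), spacing = spacing, origin = origin)
}

#' Write a volume to NIfTI
#'
#' @param v A [rad_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "rad_volume"))
  img <- RNifti::asNifti(v$values)
  aff <- diag(c(v$spacing, 1))
  aff[seq_len(3), 4] <- v$origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' Voxel centers sit at `origin + (index - 1) * spacing`; the output grid
#' keeps the origin and covers the full physical extent of the input
#' (`ceil(extent / target)` voxels per axis), so tissue is never cropped.
#' Intensities are interpolated trilinearly; label maps must use
#' nearest-neighbour so the output value set is a subset of the input labels.
#'
#' @param v A [rad_volume()] (or label map).
#' @param target_mm Positive target voxel size in mm (applied to all axes).
#' @param mode `"linear"` (trilinear, for intensities) or `"nearest"`
#'   (for label maps). Defaults to `"nearest"` for `rad_labelmap` input.
#' @return A resampled [rad_volume()] with spacing `rep(target_mm, 3)`.
#' @examples
#' v <- rad_volume(array(1, c(8, 8, 8)), spacing = c(2, 2, 2))
#' r <- resample_isotropic(v, 1)
#' dim(r$values)   # 16 x 16 x 16
#' @export
resample_isotropic <- function(v, target_mm = 1,
                               mode = c("linear", "nearest")) {
  stopifnot(inherits(v, "rad_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("resample_isotropic: target_mm must be a positive number", call. = FALSE)
  if (missing(mode) && inherits(v, "rad_labelmap")) mode <- "nearest"
  mode <- match.arg(mode)
  if (all(abs(v$spacing - target_mm) < 1e-12)) return(v)  # already on target
  din <- dim(v$values)
  extent <- din * v$spacing
  dout <- pmax(1L, as.integer(ceiling(extent / target_mm - 1e-9)))
  # output voxel center i (1-based) lies at (i-1)*target world offset from origin;
  # its fractional input index is (i-1)*target/spacing + 1
  co <- lapply(seq_len(3), function(a)
    (seq_len(dout[a]) - 1) * target_mm / v$spacing[a] + 1)
  out <- if (mode == "nearest") {
    idx <- lapply(seq_len(3), function(a)
      pmin(din[a], pmax(1L, as.integer(round(co[[a]])))))
    array(v$values[as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))], dout)
  } else {
    trilinear_sample(v$values, co[[1]], co[[2]], co[[3]])
  }
  res <- rad_volume(out, spacing = rep(target_mm, 3), origin = v$origin)
  if (inherits(v, "rad_labelmap")) res <- as_labelmap(res)
  res
}

# Trilinear interpolation of `arr` on the tensor grid cx x cy x cz of
# fractional 1-based indices, clamped to the array edges.
trilinear_sample <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  clamp <- function(x, n) pmin(n, pmax(1, x))
  cx <- clamp(cx, d[1]); cy <- clamp(cy, d[2]); cz <- clamp(cz, d[3])
  x0 <- pmin(d[1] - 1L, pmax(1L, floor(cx))); x1 <- pmin(d[1], x0 + 1L)
  y0 <- pmin(d[2] - 1L, pmax(1L, floor(cy))); y1 <- pmin(d[2], y0 + 1L)
  z0 <- pmin(d[3] - 1L, pmax(1L, floor(cz))); z1 <- pmin(d[3], z0 + 1L)
  if (d[1] == 1L) { x0 <- x1 <- rep(1L, length(cx)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1L, length(cy)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1L, length(cz)) }
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  # expand per-axis weights/indices to the full output grid
  AX0 <- array(rep.int(x0, ny * nz), c(nx, ny, nz))
  AX1 <- array(rep.int(x1, ny * nz), c(nx, ny, nz))
  FX  <- array(rep.int(fx, ny * nz), c(nx, ny, nz))
  AY0 <- array(rep(rep.int(y0, rep.int(nx, ny)), nz), c(nx, ny, nz))
  AY1 <- array(rep(rep.int(y1, rep.int(nx, ny)), nz), c(nx, ny, nz))
  FY  <- array(rep(rep.int(fy, rep.int(nx, ny)), nz), c(nx, ny, nz))
  AZ0 <- array(rep.int(z0, rep.int(nx * ny, nz)), c(nx, ny, nz))
  AZ1 <- array(rep.int(z1, rep.int(nx * ny, nz)), c(nx, ny, nz))
  FZ  <- array(rep.int(fz, rep.int(nx * ny, nz)), c(nx, ny, nz))
  lin <- function(ix, iy, iz) arr[cbind(as.vector(ix), as.vector(iy), as.vector(iz))]
  v000 <- lin(AX0, AY0, AZ0); v100 <- lin(AX1, AY0, AZ0)
  v010 <- lin(AX0, AY1, AZ0); v110 <- lin(AX1, AY1, AZ0)
  v001 <- lin(AX0, AY0, AZ1); v101 <- lin(AX1, AY0, AZ1)
  v011 <- lin(AX0, AY1, AZ1); v111 <- lin(AX1, AY1, AZ1)
  fx <- as.vector(FX); fy <- as.vector(FY); fz <- as.vector(FZ)
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                       fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
            fy * ((1 - fx) * v011 + fx * v111))
  array(out, c(nx, ny, nz))
}
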