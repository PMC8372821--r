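#' Wavelet configuration
#'
#' Single-level undecimated (stationary) 3D wavelet decomposition. The
#' transform is separable: the low-pass (L) or high-pass (H) analysis filter
#' is applied along each axis with periodic boundary handling and no
#' downsampling, so every sub-band keeps the input grid and ROI masks apply
#' unchanged. Sub-bands are named by axis order (z, y, x): `LLH` is low-pass
#' along z and y, high-pass along x.
#'
#' @param family Wavelet family; currently `"coif1"` (coiflet-1, the common
#'   radiomics default) and `"haar"`.
#' @return A list of class `wavelet_config` with analysis filters `lo`, `hi`.
#' @export
wavelet_config <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  f <- wavelet_filters(family)
  structure(list(family = family, lo = f$lo, hi = f$hi, boundary = "periodic"),
            class = "wavelet_config")
}

# Orthonormal analysis filter banks (quadrature mirror pairs).
wavelet_filters <- function(family) {
  lo <- switch(family,
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645),
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet family: ", family, call. = FALSE))
  n <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(n)  # quadrature mirror of the low-pass
  list(lo = lo, hi = hi)
}

SUBBAND_NAMES <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Single-level undecimated 3D wavelet transform
#'
#' @param v A [rad_volume()] or numeric 3D array.
#' @param cfg A [wavelet_config()].
#' @return A named list of 8 numeric arrays (`LLL` ... `HHH`), each the
#'   shape of the input. Letter order is (z, y, x).
#' @examples
#' sb <- dwt3(array(rnorm(64), c(4, 4, 4)))
#' names(sb)
#' @export
dwt3 <- function(v, cfg = wavelet_config()) {
  x <- if (inherits(v, "rad_volume")) v$values else v
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("dwt3: input must be a 3D array", call. = FALSE)
  if (any(dim(x) < 1L)) stop("dwt3: degenerate axis", call. = FALSE)
  d <- dim(x)
  filt <- function(a, h, axis)
    array(cpp_filter_axis(as.numeric(a), d, h, axis), d)
  out <- vector("list", 8)
  names(out) <- SUBBAND_NAMES
  # letters name (z, y, x); axis indices: x = 1, y = 2, z = 3
  for (nm in SUBBAND_NAMES) {
    letters3 <- strsplit(nm, "")[[1]]
    a <- x
    a <- filt(a, if (letters3[3] == "L") cfg$lo else cfg$hi, 0L)  # x axis
    a <- filt(a, if (letters3[2] == "L") cfg$lo else cfg$hi, 1L)  # y axis
    a <- filt(a, if (letters3[1] == "L") cfg$lo else cfg$hi, 2L)  # z axis
    out[[nm]] <- a
  }
  out
}

#' Wavelet-domain radiomic features
#'
#' Re-extracts the 17 first-order and 162 texture features on each of the 8
#' sub-bands of the undecimated transform, restricted to the original ROI
#' mask (each sub-band is re-discretized over its own range): 8 x 179 =
#' 1,432 features, named `wavelet-<band>_<family>_<feature>`.
#'
#' @param values Numeric 3D array (normalized, resampled image).
#' @param mask Logical ROI mask.
#' @param wav_cfg A [wavelet_config()].
#' @param tex_cfg A [texture_config()].
#' @param disc_cfg A [disc_config()].
#' @return Named numeric vector of length 1,432.
#' @export
wavelet_features <- function(values, mask, wav_cfg = wavelet_config(),
                             tex_cfg = texture_config(),
                             disc_cfg = disc_config()) {
  if (inherits(values, "rad_volume")) values <- values$values
  bands <- dwt3(values, wav_cfg)
  out <- vector("list", length(bands))
  for (k in seq_along(bands)) {
    band <- bands[[k]]
    disc <- discretize(band, mask, disc_cfg)
    fo <- firstorder_features(band[mask], disc)
    names(fo) <- paste0("firstorder_", names(fo))
    tx <- texture_features(band, mask, tex_cfg, disc_cfg)
    f <- c(fo, tx)
    names(f) <- paste0("wavelet-", names(bands)[k], "_", names(f))
    out[[k]] <- f
  }
  unlist(out)
}
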