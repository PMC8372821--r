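#' Gray-level discretization of an ROI
#'
#' Texture matrices and the histogram-based first-order features (entropy,
#' uniformity) need integer gray levels. Intensities inside the mask are
#' quantized to a fixed number of bins over the ROI's own `[min, max]`:
#' `level(x) = min(N_g, floor(N_g * (I(x) - min) / (max - min)) + 1)`.
#' A constant ROI maps every voxel to level 1.
#'
#' @param n_bins Integer number of gray levels `N_g` (>= 2). Default 32,
#'   a common radiomics choice for z-scaled inputs.
#' @return For `disc_config`, a list of class `disc_config`.
#' @name discretization
NULL

#' @rdname discretization
#' @export
disc_config <- function(n_bins = 32L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("disc_config: n_bins must be an integer >= 2", call. = FALSE)
  structure(list(n_bins = n_bins, strategy = "fixed_bin_number"),
            class = "disc_config")
}

#' @param values Numeric 3D array (or any array) of intensities.
#' @param mask Logical array, same shape; must contain at least one voxel.
#' @param cfg A [disc_config()].
#' @return For `discretize`, an object of class `disc_roi` with `levels`
#'   (integer array, 0 outside the mask, 1..N_g inside), `mask`, `n_levels`
#'   (= N_g) and `spacing` copied from the input when available.
#' @rdname discretization
#' @export
discretize <- function(values, mask, cfg = disc_config()) {
  if (inherits(values, "rad_volume")) values <- values$values
  stopifnot(inherits(cfg, "disc_config"))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("discretize: mask must be a logical array matching the values",
         call. = FALSE)
  if (!any(mask))
    stop("discretize: empty mask", call. = FALSE)
  ng <- cfg$n_bins
  x <- values[mask]
  lo <- min(x); hi <- max(x)
  lv <- if (hi == lo) rep(1L, length(x))
        else pmin(ng, as.integer(floor(ng * (x - lo) / (hi - lo))) + 1L)
  levels <- array(0L, dim(values))
  levels[mask] <- lv
  structure(list(levels = levels, mask = mask, n_levels = ng),
            class = "disc_roi")
}
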