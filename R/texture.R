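#' Texture configuration
#'
#' The texture family comprises 162 features: 23 gray-level co-occurrence
#' (GLCM) features at distances 1, 2 and 3 voxels, and 12 gray-level
#' run-length (GLRLM) features, each reported under two aggregations —
#' the mean over the 13 unique 3D directions (`avg`) and the feature of the
#' direction-merged matrix (`mrg`): 23 x 2 x 3 + 12 x 2 = 162.
#'
#' @param distances Integer GLCM distances in voxels (default 1:3).
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(distances = 1:3) {
  distances <- as.integer(distances)
  if (any(distances < 1L)) stop("distances must be >= 1", call. = FALSE)
  structure(list(distances = distances, directions = directions_3d()),
            class = "texture_config")
}

#' The 13 unique 3D neighbour directions
#'
#' One representative per +/- pair of the 26-connected neighbourhood offsets,
#' so the set is closed under negation once GLCM symmetrization is applied.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
directions_3d <- function() {
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(d) <- "integer"
  d
}

# Crop a disc_roi to the mask bounding box; pairs and runs never leave it.
crop_disc <- function(disc) {
  idx <- which(disc$mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  list(levels = disc$levels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       n_levels = disc$n_levels)
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask voxel pairs separated by `distance * direction`, both ways
#' (symmetric), and normalizes to probabilities. When the mask admits no
#' pair at this offset the matrix is flagged empty (`attr(, "n_pairs") == 0`).
#'
#' @param disc A `disc_roi` from [discretize()].
#' @param distance Integer offset multiplier (voxels).
#' @param direction Integer length-3 direction, one row of [directions_3d()].
#' @return `n_levels` x `n_levels` probability matrix with attribute
#'   `n_pairs` (number of symmetrized pairs counted).
#' @export
compute_glcm <- function(disc, distance, direction) {
  stopifnot(inherits(disc, "disc_roi"))
  cr <- crop_disc(disc)
  glcm_from_levels(cr$levels, cr$n_levels, as.integer(distance),
                   as.integer(direction))
}

glcm_from_levels <- function(levels, ng, distance, direction) {
  counts <- cpp_glcm_counts(as.integer(levels), dim(levels), ng,
                            as.integer(distance * direction))
  tot <- sum(counts)
  P <- if (tot > 0) counts / tot else counts
  attr(P, "n_pairs") <- tot
  P
}

#' Gray-level run-length matrix
#'
#' Entry (g, l) counts the maximal runs of level `g` with length `l` along
#' the direction; runs lie wholly inside the mask.
#'
#' @inheritParams compute_glcm
#' @return `n_levels` x `R_max` count matrix with attribute `n_voxels`
#'   (mask voxel count, needed for run percentage).
#' @export
compute_glrlm <- function(disc, direction) {
  stopifnot(inherits(disc, "disc_roi"))
  cr <- crop_disc(disc)
  glrlm_from_levels(cr$levels, cr$n_levels, as.integer(direction))
}

glrlm_from_levels <- function(levels, ng, direction) {
  max_len <- max(dim(levels)) * 2L  # safe bound for diagonal paths
  M <- cpp_glrlm_counts(as.integer(levels), dim(levels), ng,
                        as.integer(direction), max_len)
  keep <- max(1L, max(which(colSums(M) > 0), 1L))
  M <- M[, seq_len(keep), drop = FALSE]
  attr(M, "n_voxels") <- sum(levels > 0L)
  M
}

GLCM_FEATURES <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                   "ClusterTendency", "Contrast", "Correlation",
                   "DifferenceAverage", "DifferenceEntropy",
                   "DifferenceVariance", "JointAverage", "JointEnergy",
                   "JointEntropy", "Imc1", "Imc2", "Id", "Idn", "Idm",
                   "Idmn", "InverseVariance", "MaximumProbability",
                   "SumAverage", "SumEntropy", "SumOfSquares")

# Values every GLCM feature takes on a point-mass (single-level) matrix;
# also used as the defined fallback for flagged-empty matrices.
glcm_fallbacks <- function() {
  c(Autocorrelation = 1, ClusterProminence = 0, ClusterShade = 0,
    ClusterTendency = 0, Contrast = 0, Correlation = 1,
    DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
    JointAverage = 1, JointEnergy = 1, JointEntropy = 0, Imc1 = 0, Imc2 = 0,
    Id = 1, Idn = 1, Idm = 1, Idmn = 1, InverseVariance = 0,
    MaximumProbability = 1, SumAverage = 2, SumEntropy = 0, SumOfSquares = 0)
}

# The 23 co-occurrence features of one normalized symmetric matrix.
glcm_feature_vec <- function(P) {
  if (is.null(attr(P, "n_pairs")) || attr(P, "n_pairs") == 0)
    return(glcm_fallbacks())
  ng <- nrow(P)
  i <- seq_len(ng)
  px <- rowSums(P)                  # == colSums by symmetry
  mux <- sum(i * px)
  sx2 <- sum((i - mux)^2 * px)
  sx <- sqrt(sx2)
  I <- matrix(i, ng, ng)
  J <- t(I)
  # sum and difference distributions (grouped sums over the diagonals)
  ks <- 2:(2 * ng)
  psum <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  if (length(psum) < length(ks)) {  # some diagonals absent: fill by match
    grp <- sort(unique(as.vector(I + J)))
    full <- numeric(length(ks)); full[match(grp, ks)] <- psum; psum <- full
  }
  kd <- 0:(ng - 1)
  pdif <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))
  if (length(pdif) < length(kd)) {
    grp <- sort(unique(as.vector(abs(I - J))))
    full <- numeric(length(kd)); full[match(grp, kd)] <- pdif; pdif <- full
  }
  pos <- P > 0
  hxy <- -sum(P[pos] * log2(P[pos]))
  pxpy <- outer(px, px)
  ok <- pos & pxpy > 0
  hxy1 <- -sum(P[ok] * log2(pxpy[ok]))
  okk <- pxpy > 0
  hxy2 <- -sum(pxpy[okk] * log2(pxpy[okk]))
  hx <- { q <- px[px > 0]; -sum(q * log2(q)) }
  da <- sum(kd * pdif)
  dpos <- pdif > 0
  corr <- if (sx2 > 0) (sum(I * J * P) - mux^2) / sx2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  offd <- abs(I - J) > 0
  spos <- psum > 0
  c(Autocorrelation = sum(I * J * P),
    ClusterProminence = sum((I + J - 2 * mux)^4 * P),
    ClusterShade = sum((I + J - 2 * mux)^3 * P),
    ClusterTendency = sum((I + J - 2 * mux)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdif[dpos] * log2(pdif[dpos])),
    DifferenceVariance = sum((kd - da)^2 * pdif),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Id = sum(P / (1 + abs(I - J))),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + (I - J)^2 / ng^2)),
    InverseVariance = sum(P[offd] / (I - J)[offd]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum[spos] * log2(psum[spos])),
    SumOfSquares = sx2)
}

#' GLCM features for one distance under both aggregations
#'
#' Computes the 23 co-occurrence features either as the mean over the 13
#' directional matrices (`avg`, empty matrices excluded) or from the single
#' direction-merged matrix (`mrg`, counts summed then renormalized),
#' yielding 46 named values.
#'
#' @param glcms List of 13 directional GLCMs from [compute_glcm()] at one
#'   distance.
#' @return Named numeric vector of length 46 (`avg_*`, `mrg_*`).
#' @export
glcm_features <- function(glcms) {
  pairs <- vapply(glcms, function(g) attr(g, "n_pairs"), numeric(1))
  nonempty <- which(pairs > 0)
  if (length(nonempty)) {
    per_dir <- vapply(glcms[nonempty], glcm_feature_vec,
                      numeric(length(GLCM_FEATURES)))
    avg <- rowMeans(per_dir)
    merged <- Reduce(`+`, lapply(glcms[nonempty],
                                 function(g) g * attr(g, "n_pairs")))
    merged <- merged / sum(pairs)
    attr(merged, "n_pairs") <- sum(pairs)
    mrg <- glcm_feature_vec(merged)
  } else {
    avg <- mrg <- glcm_fallbacks()
  }
  stats::setNames(c(avg, mrg),
                  c(paste0("avg_", GLCM_FEATURES), paste0("mrg_", GLCM_FEATURES)))
}

GLRLM_FEATURES <- c("ShortRunEmphasis", "LongRunEmphasis",
                    "GrayLevelNonUniformity", "RunLengthNonUniformity",
                    "RunPercentage", "LowGrayLevelRunEmphasis",
                    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                    "ShortRunHighGrayLevelEmphasis",
                    "LongRunLowGrayLevelEmphasis",
                    "LongRunHighGrayLevelEmphasis", "GrayLevelVariance")

# The 12 run-length features of one count matrix; np = voxels for RunPercentage
# (np is multiplied by the direction count for merged matrices).
glrlm_feature_vec <- function(M, np) {
  nr <- sum(M)
  g <- seq_len(nrow(M))
  l <- seq_len(ncol(M))
  rg <- rowSums(M)
  rl <- colSums(M)
  p <- M / nr
  mug <- sum(g * rowSums(p))
  c(ShortRunEmphasis = sum(t(M) / l^2) / nr,
    LongRunEmphasis = sum(t(M) * l^2) / nr,
    GrayLevelNonUniformity = sum(rg^2) / nr,
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunPercentage = nr / np,
    LowGrayLevelRunEmphasis = sum(M / g^2) / nr,
    HighGrayLevelRunEmphasis = sum(M * g^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum((M / g^2) %*% diag(1 / l^2, length(l))) / nr,
    ShortRunHighGrayLevelEmphasis = sum((M * g^2) %*% diag(1 / l^2, length(l))) / nr,
    LongRunLowGrayLevelEmphasis = sum((M / g^2) %*% diag(l^2, length(l))) / nr,
    LongRunHighGrayLevelEmphasis = sum((M * g^2) %*% diag(l^2, length(l))) / nr,
    GrayLevelVariance = sum(rowSums(p) * (g - mug)^2))
}

#' GLRLM features under both aggregations
#'
#' 12 run-length features as the mean over 13 directional matrices (`avg`)
#' and from the direction-merged count matrix (`mrg`; run percentage then
#' divides by `13 * n_voxels`), yielding 24 named values.
#'
#' @param glrlms List of 13 directional GLRLMs from [compute_glrlm()].
#' @return Named numeric vector of length 24.
#' @export
glrlm_features <- function(glrlms) {
  np <- attr(glrlms[[1]], "n_voxels")
  per_dir <- vapply(glrlms, glrlm_feature_vec, numeric(length(GLRLM_FEATURES)),
                    np = np)
  avg <- rowMeans(per_dir)
  lmax <- max(vapply(glrlms, ncol, integer(1)))
  merged <- matrix(0, nrow(glrlms[[1]]), lmax)
  for (M in glrlms) merged[, seq_len(ncol(M))] <- merged[, seq_len(ncol(M))] + M
  mrg <- glrlm_feature_vec(merged, np * length(glrlms))
  stats::setNames(c(avg, mrg),
                  c(paste0("avg_", GLRLM_FEATURES), paste0("mrg_", GLRLM_FEATURES)))
}

#' All 162 texture features of one image/mask pair
#'
#' @param values Numeric 3D array (image on the analysis grid).
#' @param mask Logical array of the ROI.
#' @param cfg A [texture_config()].
#' @param disc_cfg A [disc_config()].
#' @return Named numeric vector of length 162 with names
#'   `glcm_d<dist>_<agg>_<feature>` and `glrlm_<agg>_<feature>`.
#' @export
texture_features <- function(values, mask, cfg = texture_config(),
                             disc_cfg = disc_config()) {
  disc <- discretize(values, mask, disc_cfg)
  cr <- crop_disc(disc)
  dirs <- cfg$directions
  out <- numeric(0)
  for (d in cfg$distances) {
    glcms <- lapply(seq_len(nrow(dirs)), function(k)
      glcm_from_levels(cr$levels, cr$n_levels, d, dirs[k, ]))
    f <- glcm_features(glcms)
    names(f) <- paste0("glcm_d", d, "_", names(f))
    out <- c(out, f)
  }
  glrlms <- lapply(seq_len(nrow(dirs)), function(k)
    glrlm_from_levels(cr$levels, cr$n_levels, dirs[k, ]))
  f <- glrlm_features(glrlms)
  names(f) <- paste0("glrlm_", names(f))
  c(out, f)
}
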