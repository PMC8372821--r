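#' Phantom cohort specification
#'
#' Parameters of the synthetic FLAIR-like cohort that stands in for clinical
#' data. Each subject is a smooth base intensity inside an ellipsoidal
#' "brain", textured by a Gaussian random field (smoothed white noise with
#' kernel SD `l_null` voxels) plus independent voxel noise. Patients carry,
#' inside the ROIs of one hemisphere (the affected side), an additive
#' intensity shift of `delta` total-noise SDs and a random field with
#' correlation length `l_affected` instead of `l_null` — i.e. altered
#' voxel-level heterogeneity, the signal the entropy-type features respond
#' to. Hippocampi are mirrored ellipsoids; the extrahippocampal temporal
#' regions are mirrored ellipsoidal shells around them.
#'
#' @param n_patients,n_controls Cohort sizes. Defaults 36 and 50, matching
#'   the clinical training cohort this simulator emulates.
#' @param grid Integer grid dimensions (default `c(64, 64, 48)`).
#' @param spacing Voxel size in mm (default 1 mm isotropic).
#' @param delta Affected-side intensity shift in units of the total noise SD
#'   (default 2, a strong effect).
#' @param l_null Correlation length (Gaussian kernel SD, voxels) of the
#'   background texture field (default 2).
#' @param l_ratio `l_affected / l_null` (default 3; 1 = no texture effect).
#' @param base Base in-brain intensity (default 100 a.u.).
#' @param field_sd SD of the texture field contribution (default 6).
#' @param noise_sd SD of the white voxel noise (default 8).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 36L, n_controls = 50L,
                         grid = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                         delta = 2, l_null = 2, l_ratio = 3,
                         base = 100, field_sd = 6, noise_sd = 8,
                         seed = 1L) {
  grid <- as.integer(grid)
  if (n_patients < 1L || n_controls < 1L)
    stop("phantom_spec: counts must be >= 1", call. = FALSE)
  if (delta < 0) stop("phantom_spec: delta must be >= 0", call. = FALSE)
  if (any(grid < 24L))
    stop("phantom_spec: grid too small for the ROI geometry", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls), grid = grid,
                 spacing = as.numeric(spacing), delta = delta,
                 l_null = l_null, l_ratio = l_ratio, base = base,
                 field_sd = field_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipsoid mask from 1-based indices
ellipsoid_mask <- function(grid, center, semi) {
  x <- seq_len(grid[1]); y <- seq_len(grid[2]); z <- seq_len(grid[3])
  X2 <- ((x - center[1]) / semi[1])^2
  Y2 <- ((y - center[2]) / semi[2])^2
  Z2 <- ((z - center[3]) / semi[3])^2
  outer(outer(X2, Y2, `+`), Z2, `+`) <= 1
}

# left-hemisphere masks + exact mirror images (flip along x)
phantom_geometry <- function(grid) {
  cx <- (grid[1] + 1) / 2; cy <- (grid[2] + 1) / 2; cz <- (grid[3] + 1) / 2
  off <- round(0.22 * grid[1])
  hc <- c(cx - off, cy, cz)
  scale <- grid / c(64, 64, 48)
  hip_semi <- pmax(2.5, c(5, 7, 4) * scale)
  out_semi <- pmax(4, c(10, 13, 8) * scale)
  in_semi <- pmax(3, c(7, 10, 6) * scale)
  hipL <- ellipsoid_mask(grid, hc, hip_semi)
  shellL <- ellipsoid_mask(grid, hc, out_semi) &
    !ellipsoid_mask(grid, hc, in_semi) & !hipL
  flipx <- function(m) m[rev(seq_len(grid[1])), , , drop = FALSE]
  brain <- ellipsoid_mask(grid, c(cx, cy, cz),
                          c(0.47 * grid[1], 0.47 * grid[2], 0.47 * grid[3]))
  list(left_hippocampal = hipL, right_hippocampal = flipx(hipL),
       left_temporal = shellL, right_temporal = flipx(shellL),
       brain = brain | hipL | flipx(hipL) | shellL | flipx(shellL))
}

# unit-SD Gaussian random field: the given white-noise array smoothed by a
# separable periodic Gaussian kernel with SD `l` voxels
smooth_field <- function(w, l) {
  if (l <= 0) return(w / stats::sd(w))
  grid <- dim(w)
  half <- max(1L, ceiling(3 * l))
  k <- stats::dnorm(seq(-half, half), sd = l)
  k <- k / sum(k)
  for (axis in 0:2)
    w <- array(cpp_filter_axis(as.numeric(w), grid, k, axis), grid)
  w / stats::sd(w)
}

# labels used by the phantom; all present in the shipped grouping table
PHANTOM_LABELS <- c(left_hippocampal = 17L, right_hippocampal = 53L,
                    left_temporal = 1015L, right_temporal = 2015L)

#' Generate a phantom cohort
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `rad_cohort`: `subjects` (each a list with
#'   `volume`, `labelmap`, `group`, `affected_side`), `ids`, `grouping`
#'   (label table matching the phantom's label map) and the `spec`.
#' @examples
#' ph <- make_cohort(phantom_spec(n_patients = 1, n_controls = 1,
#'                                grid = c(32, 32, 24), seed = 1))
#' ph$subjects[[1]]$group
#' @export
make_cohort <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec$grid)
  labels <- array(0L, spec$grid)
  labels[geom$brain] <- 3L   # surrounding cerebral tissue: in the brain mask,
                             # mapped to no ROI by the grouping
  for (nm in names(PHANTOM_LABELS)) labels[geom[[nm]]] <- PHANTOM_LABELS[[nm]]
  rng <- local_rng(spec$seed)
  n <- spec$n_patients + spec$n_controls
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  subjects <- vector("list", n)
  sd_tot <- sqrt(spec$field_sd^2 + spec$noise_sd^2)
  for (i in seq_len(n)) {
    # one white-noise field per subject drives both texture fields, so a
    # zero-effect patient (delta 0, l_ratio 1) is voxel-identical to a
    # control and the null cohort is exactly exchangeable
    w <- array(stats::qnorm(rng$runif(prod(spec$grid))), spec$grid)
    fnull <- smooth_field(w, spec$l_null)
    wn <- array(stats::qnorm(rng$runif(prod(spec$grid))), spec$grid)
    vol <- array(0, spec$grid)
    vol[geom$brain] <- spec$base
    vol <- vol + spec$field_sd * fnull + spec$noise_sd * wn
    affected <- NA_character_
    side_draw <- rng$runif(1)  # drawn for every subject: the image stream
                               # does not depend on the group sequence
    if (groups[i] == "patient") {
      affected <- if (side_draw < 0.5) "left" else "right"
      amask <- geom[[paste0(affected, "_hippocampal")]] |
        geom[[paste0(affected, "_temporal")]]
      if (spec$l_ratio != 1) {
        faff <- smooth_field(w, spec$l_null * spec$l_ratio)
        vol[amask] <- spec$base + spec$field_sd * faff[amask] +
          spec$noise_sd * wn[amask]
      }
      vol[amask] <- vol[amask] + spec$delta * sd_tot
    }
    subjects[[i]] <- list(
      volume = rad_volume(vol, spacing = spec$spacing),
      labelmap = as_labelmap(rad_volume(labels * 1.0, spacing = spec$spacing)),
      group = groups[i],
      affected_side = if (groups[i] == "patient") affected else NA_character_)
  }
  grouping <- data.frame(label_id = unname(PHANTOM_LABELS),
                         roi_name = names(PHANTOM_LABELS),
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects,
                 ids = sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                               as.integer(stats::ave(seq_len(n), groups,
                                                     FUN = seq_along))),
                 grouping = grouping, spec = spec),
            class = "rad_cohort")
}

#' @exportS3Method print rad_cohort
print.rad_cohort <- function(x, ...) {
  cat(sprintf("<rad_cohort> %d patients + %d controls, grid %s, seed %d\n",
              x$spec$n_patients, x$spec$n_controls,
              paste(x$spec$grid, collapse = "x"), x$spec$seed))
  invisible(x)
}

#' Write / read a phantom cohort as NIfTI + manifest
#'
#' Writes `<id>_flair.nii.gz` and `<id>_labels.nii.gz` per subject, the ROI
#' grouping table, and `manifest.csv` (subject_id, group, affected_side,
#' file names), so downstream stages consume phantoms exactly as they would
#' clinical inputs.
#'
#' @param cohort A `rad_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly (write); a `rad_cohort`
#'   (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(subject_id = cohort$ids,
                    group = vapply(cohort$subjects, `[[`, "", "group"),
                    affected_side = vapply(cohort$subjects, function(s)
                      if (is.na(s$affected_side)) "" else s$affected_side, ""),
                    volume_file = paste0(cohort$ids, "_flair.nii.gz"),
                    label_file = paste0(cohort$ids, "_labels.nii.gz"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(cohort$subjects)) {
    write_volume(cohort$subjects[[i]]$volume,
                 file.path(dir, man$volume_file[i]))
    write_volume(cohort$subjects[[i]]$labelmap,
                 file.path(dir, man$label_file[i]))
  }
  utils::write.table(cohort$grouping, file.path(dir, "roi_grouping.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  grouping <- utils::read.table(file.path(dir, "roi_grouping.tsv"),
                                header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    lm <- read_volume(file.path(dir, man$label_file[i]))
    list(volume = read_volume(file.path(dir, man$volume_file[i])),
         labelmap = as_labelmap(lm),
         group = man$group[i],
         affected_side = if (nzchar(man$affected_side[i]))
           man$affected_side[i] else NA_character_)
  })
  structure(list(subjects = subjects, ids = man$subject_id,
                 grouping = grouping, spec = NULL),
            class = "rad_cohort")
}

#' Deterministic toy fixtures for the texture oracles
#'
#' Small arrays with known texture structure: a constant 4x4x4 block, a
#' two-level 4x4x4 checkerboard, the 1D strip `c(1, 1, 1, 2, 2)`, and a
#' seeded random 5x5x5 level array (levels 1..4).
#'
#' @param seed Seed for the random fixture.
#' @return Named list of integer arrays (`constant`, `checkerboard`,
#'   `strip`, `random`).
#' @export
make_toy_fixtures <- function(seed = 42L) {
  rng <- local_rng(seed)
  chk <- array(0L, c(4, 4, 4))
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  chk[idx] <- 1L + (rowSums(idx) %% 2L)
  list(constant = array(1L, c(4, 4, 4)),
       checkerboard = chk,
       strip = array(c(1L, 1L, 1L, 2L, 2L), c(5, 1, 1)),
       random = array(floor(rng$runif(125) * 4) + 1L, c(5, 5, 5)))
}
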