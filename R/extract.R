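#' Extract the full radiomic feature vector of one ROI
#'
#' The default configuration emits exactly 1,618 named features:
#' 17 first-order + 162 texture + 7 shape on the original image (186), plus
#' 179 (17 first-order + 162 texture) on each of the 8 undecimated wavelet
#' sub-bands (1,432). Shape is geometric and therefore computed only once,
#' on the original grid. Names follow
#' `<image>_<family>[_<dist>][_<agg>]_<feature>` with image `original` or
#' `wavelet-<band>`.
#'
#' @param values Numeric 3D array or [rad_volume()]; expected to be the
#'   resampled, white-stripe-normalized image.
#' @param mask Logical ROI mask on the same grid.
#' @param spacing Voxel spacing in mm (taken from the volume if given one).
#' @param tex_cfg,disc_cfg,wav_cfg Family configurations.
#' @return Named numeric vector, length 1,618 under the defaults; all values
#'   finite.
#' @export
extract_features <- function(values, mask, spacing = c(1, 1, 1),
                             tex_cfg = texture_config(),
                             disc_cfg = disc_config(),
                             wav_cfg = wavelet_config()) {
  if (inherits(values, "rad_volume")) {
    spacing <- values$spacing
    values <- values$values
  }
  sh <- shape_features(mask, spacing)
  names(sh) <- paste0("original_shape_", names(sh))
  # crop to the mask bounding box plus the wavelet filter support, so the
  # in-mask sub-band values are unchanged but the transform is cheap
  margin <- length(wav_cfg$lo) + 2L
  d <- dim(values)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(d, apply(idx, 2, max) + margin)
  values <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  disc <- discretize(values, mask, disc_cfg)
  fo <- firstorder_features(values[mask], disc)
  names(fo) <- paste0("original_firstorder_", names(fo))
  tx <- texture_features(values, mask, tex_cfg, disc_cfg)
  names(tx) <- paste0("original_", names(tx))
  wv <- wavelet_features(values, mask, wav_cfg, tex_cfg, disc_cfg)
  out <- c(fo, tx, sh, wv)
  stopifnot(!anyDuplicated(names(out)), all(is.finite(out)))
  out
}

#' Extract a feature table from a phantom or clinical cohort
#'
#' Runs the full per-subject chain — resample to the isotropic analysis
#' grid, white-stripe normalize, assemble the four ROIs — then extracts the
#' feature vector of each requested ROI, producing one row per
#' (subject, side, roi).
#'
#' @param cohort A `rad_cohort` from [make_cohort()], or a list with
#'   elements `subjects` (list of `list(volume, labelmap, group,
#'   affected_side)`) and `ids`.
#' @param grouping ROI grouping data.frame (default: shipped
#'   Desikan/Killiany table via [read_roi_grouping()], or the cohort's own
#'   grouping when it carries one).
#' @param rois Which ROI types to extract (default both).
#' @param target_mm Isotropic analysis resolution (default 1 mm).
#' @param ws_cfg,tex_cfg,disc_cfg,wav_cfg Stage configurations.
#' @param verbose Print per-subject progress.
#' @return A data.frame of class `rad_features`: metadata columns
#'   `subject_id`, `group`, `side`, `roi`, `affected` followed by the
#'   feature columns.
#' @export
extract_cohort <- function(cohort, grouping = NULL,
                           rois = c("hippocampal", "temporal"),
                           target_mm = 1,
                           ws_cfg = ws_config(),
                           tex_cfg = texture_config(),
                           disc_cfg = disc_config(),
                           wav_cfg = wavelet_config(),
                           verbose = FALSE) {
  rois <- match.arg(rois, several.ok = TRUE)
  if (is.null(grouping))
    grouping <- if (!is.null(cohort$grouping)) cohort$grouping
                else read_roi_grouping()
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    v <- resample_isotropic(s$volume, target_mm, mode = "linear")
    lm <- resample_isotropic(s$labelmap, target_mm, mode = "nearest")
    brain <- lm$values > 0L
    stats <- estimate_stripe(v, brain, ws_cfg)
    vn <- ws_normalize(v, stats)
    masks <- build_rois(lm, grouping)
    for (side in c("left", "right")) {
      for (roi in rois) {
        m <- masks[[paste0(side, "_", roi)]]
        if (!any(m)) next
        fv <- extract_features(vn$values, m, spacing = vn$spacing,
                               tex_cfg = tex_cfg, disc_cfg = disc_cfg,
                               wav_cfg = wav_cfg)
        aff <- if (identical(s$group, "patient"))
          as.integer(identical(s$affected_side, side)) else 0L
        rows[[length(rows) + 1L]] <- c(
          list(subject_id = cohort$ids[i], group = s$group, side = side,
               roi = roi, affected = aff),
          as.list(fv))
      }
    }
    if (verbose)
      message(sprintf("extracted subject %s (%d/%d)",
                      cohort$ids[i], i, length(cohort$subjects)))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  class(df) <- c("rad_features", class(df))
  df
}

#' Names of the metadata (non-feature) columns of a feature table
#' @return Character vector.
#' @export
meta_columns <- function() c("subject_id", "group", "side", "roi", "affected")

#' Feature column names of a feature table
#' @param table A feature table from [extract_cohort()].
#' @return Character vector of feature names.
#' @export
feature_columns <- function(table) setdiff(names(table), meta_columns())

#' Write / read a feature table as CSV
#' @param table Feature table.
#' @param path CSV path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("rad_features", class(df))
  df
}
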