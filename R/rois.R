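#' @title ROI groupings and mask assembly
#' @description Tools to collapse an anatomical parcellation into the four
#'   study regions: left/right hippocampus and left/right extrahippocampal
#'   temporal lobe.
#' @name rois
NULL

ROI_NAMES <- c("left_hippocampal", "right_hippocampal",
               "left_temporal", "right_temporal")

#' Read an ROI grouping table
#'
#' The grouping maps parcellation label IDs to one of the four study ROI
#' names. The shipped default (`system.file("extdata",
#' "dk_temporal_grouping.tsv", package = "radlat")`) lists the
#' Desikan/Killiany temporal-lobe cortical labels plus the subcortical
#' hippocampus labels (17 left, 53 right).
#'
#' @param path Path to a two-column tab/whitespace-separated table with
#'   header `label_id roi_name`. If missing, the shipped default is used.
#' @return A data.frame with integer `label_id` and character `roi_name`.
#' @export
read_roi_grouping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dk_temporal_grouping.tsv",
                        package = "radlat", mustWork = TRUE)
  g <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  validate_roi_grouping(g)
}

validate_roi_grouping <- function(g) {
  stopifnot(is.data.frame(g))
  if (!all(c("label_id", "roi_name") %in% names(g)))
    stop("ROI grouping needs columns 'label_id' and 'roi_name'", call. = FALSE)
  g$label_id <- as.integer(g$label_id)
  if (anyDuplicated(g$label_id))
    stop("ROI grouping: each label may map to at most one ROI", call. = FALSE)
  bad <- setdiff(unique(g$roi_name), ROI_NAMES)
  if (length(bad))
    stop(sprintf("ROI grouping: unknown ROI name(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  missing <- setdiff(ROI_NAMES, unique(g$roi_name))
  if (length(missing))
    stop(sprintf("ROI grouping: missing ROI name(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g[, c("label_id", "roi_name")]
}

#' Assemble the four study ROI masks from a parcellation
#'
#' A voxel enters ROI `r` iff its parcellation label maps to `r` under the
#' grouping; labels absent from the grouping (including background 0) enter
#' no mask. The four masks are pairwise disjoint by construction.
#'
#' @param lm A label map ([as_labelmap()]) on the analysis grid.
#' @param grouping A grouping data.frame as from [read_roi_grouping()].
#' @return An object of class `rad_roiset`: a named list of four logical
#'   arrays (`left_hippocampal`, `right_hippocampal`, `left_temporal`,
#'   `right_temporal`) with attributes `spacing` and `dim`.
#' @export
build_rois <- function(lm, grouping) {
  stopifnot(inherits(lm, "rad_labelmap"))
  grouping <- validate_roi_grouping(grouping)
  lv <- lm$values
  masks <- lapply(ROI_NAMES, function(r) {
    ids <- grouping$label_id[grouping$roi_name == r]
    array(lv %in% ids, dim(lv))
  })
  names(masks) <- ROI_NAMES
  structure(masks, spacing = lm$spacing, grid_dim = dim(lv),
            class = "rad_roiset")
}

#' @exportS3Method print rad_roiset
print.rad_roiset <- function(x, ...) {
  cat("<rad_roiset>\n")
  for (r in names(x))
    cat(sprintf("  %-18s %d voxels\n", r, sum(x[[r]])))
  invisible(x)
}
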