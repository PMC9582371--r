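#' Region masks
#'
#' A `region_mask` is a logical 3D array on the dataset grid with a label
#' and a provenance tag (how the mask was obtained).
#'
#' @param mask logical 3D array (must be nonempty).
#' @param label character label.
#' @param provenance one of `"functional"`, `"meta_analytic"`,
#'   `"anatomical"`, `"white_matter"`, `"sphere"`.
#' @param affine voxel-to-world matrix.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(mask, label, provenance = c(
  "functional", "meta_analytic", "anatomical", "white_matter", "sphere"),
  affine = grid_affine(dim(mask))) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop(sprintf("mask '%s' is empty", label))
  structure(list(mask = mask, label = label, provenance = provenance,
                 affine = affine),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s' (%s)> %d voxels\n", x$label, x$provenance,
              sum(x$mask)))
  invisible(x)
}

#' Extract one region from a label array
#'
#' @param labels integer label array from [region_labels()].
#' @param label region name (one of the array's `levels`).
#' @param affine voxel-to-world matrix.
#' @return a [region_mask()].
#' @export
region_mask_from_labels <- function(labels, label,
                                    affine = grid_affine(dim(labels))) {
  lv <- attr(labels, "levels")
  code <- match(label, lv)
  if (is.na(code)) stop(sprintf("unknown region label '%s'", label))
  prov <- if (label == "white_matter") "white_matter" else "anatomical"
  region_mask(array(labels == code, dim(labels)), label, prov, affine)
}

#' Spherical mask around a world coordinate
#'
#' Includes every voxel whose centre lies within `radius_mm` of
#' `center_mm`.
#'
#' @param center_mm length-3 world coordinate (mm).
#' @param radius_mm sphere radius (mm).
#' @param grid_shape voxel counts.
#' @param affine voxel-to-world matrix.
#' @return a [region_mask()] with provenance `"sphere"`.
#' @export
make_sphere_mask <- function(center_mm, radius_mm, grid_shape,
                             affine = grid_affine(grid_shape)) {
  idx <- seq_len(prod(grid_shape))
  xyz <- voxel_to_world(index_to_ijk(idx, grid_shape), affine)
  d2 <- rowSums(sweep(xyz, 2, center_mm)^2)
  m <- array(d2 <= radius_mm^2, grid_shape)
  if (!any(m))
    stop("sphere contains no voxel centres (is the centre inside the grid?)")
  region_mask(m, sprintf("sphere_r%g", radius_mm), "sphere", affine)
}

#' Intersection of two masks
#'
#' @param a,b `region_mask`s on the same grid.
#' @return a [region_mask()] with the voxelwise AND.
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "region_mask"), inherits(b, "region_mask"))
  if (!all(dim(a$mask) == dim(b$mask))) stop("masks are on different grids")
  m <- a$mask & b$mask
  if (!any(m))
    stop(sprintf("empty intersection (|%s| = %d, |%s| = %d)", a$label,
                 sum(a$mask), b$label, sum(b$mask)))
  region_mask(m, paste(a$label, b$label, sep = "&"), a$provenance, a$affine)
}

#' Select the per-subject peak voxel within a mask
#'
#' Argmax (or argmin) of the selection statistic within the mask; ties are
#' broken by the smallest linear index, for determinism.
#'
#' @param subject_map [vol_map()] or full 3D array of the selection
#'   statistic.
#' @param mask a [region_mask()] or logical array.
#' @param direction `"max"` or `"min"`.
#' @return list with `index` (linear), `ijk` (0-based), `mm` (world) and
#'   `value`.
#' @export
select_peak_voxel <- function(subject_map, mask, direction = c("max", "min")) {
  direction <- match.arg(direction)
  vals <- if (inherits(subject_map, "vol_map")) subject_map$values
          else subject_map
  affine <- if (inherits(subject_map, "vol_map")) subject_map$affine
            else if (inherits(mask, "region_mask")) mask$affine
            else grid_affine(dim(vals))
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  idx <- which(m)
  v <- vals[idx]
  if (all(is.na(v))) stop("selection statistic is NA on the whole mask")
  if (direction == "min") v <- -v
  pick <- idx[which.max(replace(v, is.na(v), -Inf))]
  list(index = pick, ijk = index_to_ijk(pick, dim(m))[1, ],
       mm = as.numeric(voxel_to_world(index_to_ijk(pick, dim(m)), affine)),
       value = vals[pick])
}

#' Extract ROI signal per subject: peak voxel vs. mask mean
#'
#' Peak strategy: for each subject, find the voxel in the mask maximizing
#' the selection contrast's effect, then read each test contrast's effect
#' at that voxel (non-independent selection: see
#' [selection_bias_experiment()]). Mean strategy: average each test
#' contrast's effect over the whole mask. Selection and test statistics are
#' subject-level betas.
#'
#' @param fits list of [fit_first_level()] results, one per subject.
#' @param mask a [region_mask()].
#' @param strategy `"peak"` or `"mean"`.
#' @param selection_contrast named contrast weights for peak selection
#'   (required for `strategy = "peak"`).
#' @param test_contrasts named list of contrast weight vectors to extract.
#' @return data.frame: `subject`, `strategy`, `contrast`, `value`,
#'   `peak_x/y/z` (mm, peak only).
#' @export
extract_roi_signal <- function(fits, mask, strategy = c("peak", "mean"),
                               selection_contrast = NULL, test_contrasts) {
  strategy <- match.arg(strategy)
  if (strategy == "peak" && is.null(selection_contrast))
    stop("peak strategy needs a selection contrast")
  stopifnot(inherits(mask, "region_mask"))
  if (is.null(names(test_contrasts)))
    stop("test_contrasts must be a named list")
  rows <- list()
  for (s in seq_along(fits)) {
    fit <- fits[[s]]
    if (is.null(fit$mask))
      stop("fits must carry a mask to locate voxels on the grid")
    get_map <- function(w) contrast_map(fit, w)$effect_map
    if (strategy == "peak") {
      sel <- get_map(selection_contrast)
      pk <- select_peak_voxel(sel, mask)
      for (cn in names(test_contrasts)) {
        tm <- get_map(test_contrasts[[cn]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, strategy = "peak", contrast = cn,
          value = tm$values[pk$index], peak_x = pk$mm[1], peak_y = pk$mm[2],
          peak_z = pk$mm[3], stringsAsFactors = FALSE)
      }
    } else {
      for (cn in names(test_contrasts)) {
        tm <- get_map(test_contrasts[[cn]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, strategy = "mean", contrast = cn,
          value = mean(tm$values[mask$mask], na.rm = TRUE),
          peak_x = NA_real_, peak_y = NA_real_, peak_z = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
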