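#' Define a circular ROI
#'
#' Circular single-slice region of interest, specified in voxel coordinates
#' with a physical diameter (mm). Mirrors the clinical workflow: a 20 mm
#' circle in frontoparietal white matter and a 10 mm circle in ventricular
#' CSF, drawn on the b = 1000 image and transferred unchanged (same voxel
#' indices) to the ADC map.
#'
#' @param label ROI label.
#' @param slice Slice index (1-based).
#' @param row,col Centre in voxel coordinates (may be fractional).
#' @param diameter_mm Circle diameter in mm (> 0).
#' @param tissue Optional tissue/vial tag.
#' @return A one-row tibble of class `roi_spec`.
#' @export
roi_spec <- function(label, slice, row, col, diameter_mm, tissue = NA_character_) {
  check_number(diameter_mm, "diameter_mm", 0, strict = TRUE)
  out <- tibble::tibble(label = as.character(label), slice = as.integer(slice),
                        row = as.numeric(row), col = as.numeric(col),
                        diameter_mm = diameter_mm, tissue = tissue)
  class(out) <- c("roi_spec", class(out))
  out
}

#' Rasterize a circular ROI onto a voxel grid
#'
#' A voxel belongs to the mask iff its centre lies strictly inside the
#' circle of radius `diameter_mm / 2` around the ROI centre. Voxel centres
#' sit at integer coordinates; distances are scaled by `voxel_size_mm`.
#'
#' @param roi A [roi_spec()] row.
#' @param voxel_size_mm In-plane voxel size, mm.
#' @param grid_shape Length-2 integer `(n_rows, n_cols)`.
#' @return Logical `n_rows x n_cols` matrix; errors if the mask is empty or
#'   the ROI centre falls outside the grid.
#' @export
#' @examples
#' roi <- roi_spec("wm", 1, 16.5, 16.5, diameter_mm = 10)
#' sum(rasterize_roi(roi, 1, c(32, 32))) # ~ pi * 5^2
rasterize_roi <- function(roi, voxel_size_mm, grid_shape) {
  stopifnot(length(grid_shape) == 2)
  if (roi$row < 1 || roi$row > grid_shape[1] ||
      roi$col < 1 || roi$col > grid_shape[2]) {
    abort(sprintf("ROI '%s' centre (%.1f, %.1f) lies outside the grid.",
                  roi$label, roi$row, roi$col))
  }
  r_vox <- roi$diameter_mm / 2 / voxel_size_mm
  rows <- seq_len(grid_shape[1]) - roi$row
  cols <- seq_len(grid_shape[2]) - roi$col
  mask <- outer(rows^2, cols^2, `+`) < r_vox^2
  if (!any(mask)) {
    abort(sprintf(
      "ROI '%s' rasterizes to an empty mask (diameter %.2f mm < voxel grid).",
      roi$label, roi$diameter_mm))
  }
  mask
}

#' Compute VOI statistics under a mask
#'
#' Sample mean, SD (n - 1 denominator), range and histogram of the finite
#' in-mask voxels of a 2-D or 3-D image (an ADC map's `values` or one
#' b-volume of a DWI series). NaN voxels (unfittable) are excluded and do
#' not count toward `n_voxels`.
#'
#' @param x Numeric array (2-D or 3-D), or an `adc_map` (its `values` are
#'   used).
#' @param mask Logical array of the same shape.
#' @param label ROI label recorded in the output.
#' @param n_bins Histogram bin count.
#' @return One-row tibble: `label`, `n_voxels`, `mean`, `sd`, `min`, `max`,
#'   and list-columns `hist_breaks`, `hist_counts` covering `[min, max]`.
#' @export
voi_statistics <- function(x, mask, label = "roi", n_bins = 32) {
  if (inherits(x, "adc_map")) x <- x$values
  if (!identical(dim(x), dim(mask))) abort("`x` and `mask` shapes differ.")
  if (!any(mask)) abort(sprintf("Mask for '%s' is empty.", label))
  vals <- x[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    abort(sprintf("All voxels under mask '%s' are NaN; nothing to summarise.",
                  label))
  }
  breaks <- seq(min(vals), max(vals), length.out = n_bins + 1)
  if (min(vals) == max(vals)) breaks <- c(min(vals) - 0.5, max(vals) + 0.5)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  tibble::tibble(
    label = label, n_voxels = length(vals), mean = mean(vals),
    sd = if (length(vals) > 1) sd(vals) else 0,
    min = min(vals), max = max(vals),
    hist_breaks = list(h$breaks), hist_counts = list(h$counts)
  )
}
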