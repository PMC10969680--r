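#' Describe one phantom vial
#'
#' A vial is a cylinder spanning all slices of the phantom grid, filled with
#' a polyvinylpyrrolidone (PVP) solution whose concentration sets its true
#' diffusivity. The 0% PVP vial is pure water with a ground-truth ADC of
#' 1100 um^2/s at the phantom's controlled temperature; it anchors the bias
#' and repeatability claims.
#'
#' @param label Unique vial label.
#' @param row,col Vial centre in voxel coordinates (1-based, may be fractional).
#' @param radius_mm Vial radius in mm (> 0).
#' @param true_adc Ground-truth ADC in um^2/s (> 0).
#' @param s0 Noiseless signal at b = 0, arbitrary units (> 0).
#' @param pvp_concentration PVP concentration, % w/w (informational).
#' @param central Logical; is this the central 0% PVP reference vial?
#' @return A one-row tibble.
#' @export
vial_spec <- function(label, row, col, radius_mm, true_adc, s0 = 1000,
                      pvp_concentration = NA_real_, central = FALSE) {
  check_number(radius_mm, "radius_mm", 0, strict = TRUE)
  check_number(true_adc, "true_adc", 0, strict = TRUE)
  check_number(s0, "s0", 0, strict = TRUE)
  tibble::tibble(
    label = as.character(label), row = as.numeric(row), col = as.numeric(col),
    radius_mm = radius_mm, true_adc = true_adc, s0 = s0,
    pvp_concentration = pvp_concentration, central = isTRUE(central)
  )
}

# synthetic monotone-decreasing diffusivity ladder; only the 0% PVP value is
# a measured reference, the rest emulate increasing PVP concentration
default_vial_ladder <- function() {
  pvp <- c(0, 10, 20, 30, 40, 50)
  tibble::tibble(
    pvp_concentration = pvp,
    true_adc = 1100 * exp(-0.025 * pvp)
  )
}

#' Build a multi-vial diffusion phantom layout
#'
#' Constructs the geometry and ground truth of a QIBA-style diffusion
#' phantom: one central vial of pure water (0% PVP, true ADC `dc_true`) and a
#' ring of vials with a monotone-decreasing diffusivity ladder emulating
#' increasing PVP concentration. All vials are cylinders through every slice.
#'
#' @param n_ring Number of ring vials (default 12, giving 13 vials total).
#' @param grid_shape Integer vector `(n_slices, n_rows, n_cols)`.
#' @param voxel_size_mm In-plane voxel size in mm.
#' @param vial_radius_mm Vial radius in mm.
#' @param ring_radius_mm Distance from grid centre to ring-vial centres, mm.
#' @param dc_true Ground-truth ADC of the central 0% PVP vial, um^2/s.
#' @param s0 Baseline b = 0 signal for every vial, arbitrary units.
#' @param background Background signal level outside all vials.
#' @param vials Optional tibble of vials (as from [vial_spec()]) overriding
#'   the generated ring; must contain exactly one `central` vial.
#' @return An object of class `phantom_layout`: a list with `vials` (tibble),
#'   `grid_shape`, `voxel_size_mm` and `background`.
#' @export
#' @examples
#' layout <- make_phantom_layout()
#' layout$vials$true_adc[layout$vials$central] # 1100
make_phantom_layout <- function(n_ring = 12,
                                grid_shape = c(5, 96, 96),
                                voxel_size_mm = 1.72,
                                vial_radius_mm = 9,
                                ring_radius_mm = 52,
                                dc_true = 1100,
                                s0 = 1000,
                                background = 0,
                                vials = NULL) {
  check_number(dc_true, "dc_true", 0, strict = TRUE)
  check_number(voxel_size_mm, "voxel_size_mm", 0, strict = TRUE)
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("`grid_shape` must be (n_slices, n_rows, n_cols), all >= 1.")
  }
  grid_shape <- as.integer(grid_shape)

  if (is.null(vials)) {
    check_number(vial_radius_mm, "vial_radius_mm", 0, strict = TRUE)
    centre <- (grid_shape[2:3] + 1) / 2
    ladder <- default_vial_ladder()
    central <- vial_spec("vial_00", centre[1], centre[2], vial_radius_mm,
                         true_adc = dc_true, s0 = s0,
                         pvp_concentration = 0, central = TRUE)
    ring <- NULL
    if (n_ring > 0) {
      theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
      r_vox <- ring_radius_mm / voxel_size_mm
      # ring vials cycle through the nonzero-PVP ladder
      lad <- ladder[-1, ]
      idx <- ((seq_len(n_ring) - 1) %% nrow(lad)) + 1
      ring <- purrr::map_dfr(seq_len(n_ring), function(i) {
        vial_spec(sprintf("vial_%02d", i),
                  row = centre[1] + r_vox * sin(theta[i]),
                  col = centre[2] + r_vox * cos(theta[i]),
                  radius_mm = vial_radius_mm,
                  true_adc = lad$true_adc[idx[i]], s0 = s0,
                  pvp_concentration = lad$pvp_concentration[idx[i]])
      })
    }
    vials <- dplyr::bind_rows(central, ring)
  } else {
    vials <- dplyr::bind_rows(vials)
  }

  if (anyDuplicated(vials$label)) abort("Vial labels must be unique.")
  if (sum(vials$central) != 1L) {
    abort("Exactly one vial must be flagged `central` (the 0% PVP reference).")
  }
  if (any(vials$true_adc <= 0) || any(vials$radius_mm <= 0) || any(vials$s0 <= 0)) {
    abort("All vials need true_adc > 0, radius_mm > 0 and s0 > 0.")
  }

  r_vox <- vials$radius_mm / voxel_size_mm
  if (any(vials$row - r_vox < 0.5) || any(vials$row + r_vox > grid_shape[2] + 0.5) ||
      any(vials$col - r_vox < 0.5) || any(vials$col + r_vox > grid_shape[3] + 0.5)) {
    abort("Vial footprint extends outside the image grid.")
  }
  if (nrow(vials) > 1) {
    d <- as.matrix(stats::dist(vials[, c("row", "col")])) * voxel_size_mm
    lim <- outer(vials$radius_mm, vials$radius_mm, `+`)
    diag(d) <- Inf
    if (any(d < lim)) abort("Vials overlap; shrink radii or move centres.")
  }

  structure(
    list(vials = vials, grid_shape = grid_shape,
         voxel_size_mm = voxel_size_mm, background = background),
    class = "phantom_layout"
  )
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %d vials on a %s grid (%.2f mm in-plane)\n",
              nrow(x$vials), paste(x$grid_shape, collapse = " x "),
              x$voxel_size_mm))
  print(x$vials)
  invisible(x)
}

# logical (slice, row, col) mask of a vial's cylindrical footprint
vial_mask <- function(layout, label, slices = NULL) {
  v <- layout$vials[layout$vials$label == label, ]
  if (nrow(v) != 1L) abort(sprintf("Unknown vial label '%s'.", label))
  slices <- slices %||% seq_len(layout$grid_shape[1])
  roi <- roi_spec(v$label, slice = slices[1], row = v$row, col = v$col,
                  diameter_mm = 2 * v$radius_mm)
  disc <- rasterize_roi(roi, layout$voxel_size_mm, layout$grid_shape[2:3])
  mask <- array(FALSE, layout$grid_shape)
  for (s in slices) mask[s, , ] <- disc
  mask
}
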