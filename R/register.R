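#' Register a low-dose scan to an AEC scan (backward-forward projection)
#'
#' Compensates inter-scan subject motion so that low-dose projections can
#' be combined with the AEC projections:
#' \enumerate{
#'   \item the projected markers are removed from the low-dose projections
#'     by [inpaint_markers()] (no metal artifacts downstream);
#'   \item the low-dose stack is FDK-filtered and backprojected with a
#'     moving-least-squares deformation built from the paired 3D marker
#'     positions, yielding a reconstruction deformed into the AEC pose.
#'     Each output voxel (an AEC-pose position) is mapped through the
#'     AEC-to-low-dose marker deformation to the position where the same
#'     material sat during the low-dose scan, projected onto the detector
#'     there, and the readout is accumulated at the original voxel;
#'   \item the deformed volume is reduced to its object support before
#'     reprojection: voxels outside the reconstructible field-of-view
#'     cylinder are zeroed, and attenuation values ramp smoothly to zero
#'     below \code{support_threshold} (full suppression below half of it —
#'     air cannot attenuate, while partial-volume skin voxels survive).
#'     This suppresses the diffuse halo that photon-starvation-inconsistent
#'     data and lateral truncation leave around the object, which would
#'     otherwise contaminate the synthesized background;
#'   \item the cleaned volume is forward-projected with the same system
#'     geometry, synthesizing low-dose projections aligned to the AEC scan
#'     (negative line integrals are clamped to zero);
#'   \item each synthesized view receives a global least-squares gain
#'     against the original low-dose projection, computed over pixels that
#'     are neither starved nor near zero, fixing the amplitude loss of the
#'     backward-forward process.
#' }
#'
#' @param lowdose Low-dose [projection_stack()] (or a \code{sim_scan}).
#' @param aec_markers,ld_markers \code{marker_set}s (or n x 3 matrices) of
#'   the AEC and low-dose scans; matched internally with
#'   [match_markers()].
#' The reconstruction for this backward-forward process uses its own grid
#' (see [registration_grid()]): detector-matched in-plane resolution over
#' the full lateral field of view and an axial extent covering the whole
#' illuminated cone, so that the synthesized projections miss as little of
#' the object as the scan geometry permits.  Laterally truncated parts of
#' the object remain invisible to the reconstruction; the per-view gain
#' and the row-wise scaling of the downstream combination absorb the
#' resulting global amplitude deficit.
#'
#' @param geometry A [cone_beam_geometry()] (default: the stack's).
#' @param grid [volume_grid()] used only to default the axial spacing of
#'   the registration grid; pass \code{reg_grid} to control the
#'   backward-forward grid fully.
#' @param reg_grid Optional [volume_grid()] for the backward-forward
#'   reconstruction (default [registration_grid()]).
#' @param alpha MLS weight exponent (default 1).
#' @param inpaint_radius Marker inpainting radius in pixels (default 2).
#' @param gain_floor Pixels with line integrals at or below this value are
#'   excluded from the per-view gain fit (default 0.1).
#' @param support_threshold Attenuation (1/mm) below which a voxel of the
#'   registration volume is treated as air (default 0.009, about half the
#'   fat attenuation at the high-dose effective energy); 0 disables.
#' @return List of class \code{registered_scan}: \code{stack} (the
#'   registered [projection_stack()]), \code{volume} (the deformed
#'   low-dose reconstruction), \code{deformation}, \code{gains} (per view)
#'   and \code{marker_permutation}.
#' @export
register_lowdose_scan <- function(lowdose, aec_markers, ld_markers,
                                  geometry = NULL, grid = NULL,
                                  reg_grid = NULL, alpha = 1,
                                  inpaint_radius = 2, gain_floor = 0.1,
                                  support_threshold = 0.009) {
  if (inherits(lowdose, "sim_scan")) lowdose <- lowdose$stack
  data <- stack_data(lowdose)
  if (is.null(geometry)) {
    stopifnot(inherits(lowdose, "projection_stack"))
    geometry <- lowdose$geometry
  }
  if (is.null(reg_grid))
    reg_grid <- registration_grid(geometry,
                                  z_spacing = if (!is.null(grid))
                                    grid$spacing[3] else NULL)
  A <- if (inherits(aec_markers, "marker_set")) aec_markers$positions
       else as.matrix(aec_markers)
  B <- if (inherits(ld_markers, "marker_set")) ld_markers$positions
       else as.matrix(ld_markers)
  perm <- match_markers(A, B)
  B <- B[perm, , drop = FALSE]
  cleaned <- inpaint_markers(data, B, radius = inpaint_radius,
                             geometry = geometry)
  # forward map (diagnostics): low-dose pose -> AEC pose; the deformed
  # backprojection needs the inverse map (AEC-pose voxel -> low-dose-pose
  # read position)
  def <- mls_deformation(p = B, q = A, alpha = alpha)
  def_inv <- mls_deformation(p = A, q = B, alpha = alpha)
  vol <- fdk_reconstruct(cleaned, geometry, reg_grid,
                         deformation = def_inv)
  support <- vol
  ctr <- voxel_centers(reg_grid)
  r_fov <- geometry$detector_cols / 2 * geometry$pixel_spacing *
    geometry$source_isocenter_distance / geometry$source_detector_distance
  outside <- sqrt(ctr[, 1]^2 + ctr[, 2]^2) > r_fov
  support[array(outside, reg_grid$size)] <- 0
  if (support_threshold > 0) {
    st <- support_threshold
    support <- support * pmin(pmax((support - st / 2) / (st / 2), 0), 1)
  }
  synth <- forward_project(support, reg_grid, geometry)
  synth[synth < 0] <- 0
  gains <- vapply(seq_len(dim(data)[3]), function(k) {
    s <- synth[, , k]; o <- cleaned[, , k]
    sel <- s > gain_floor & o > gain_floor
    if (!any(sel)) return(1)
    sum(s[sel] * o[sel]) / sum(s[sel]^2)
  }, 0)
  for (k in seq_len(dim(synth)[3]))
    synth[, , k] <- synth[, , k] * gains[k]
  structure(list(stack = projection_stack(synth, geometry), volume = vol,
                 deformation = def, gains = gains,
                 marker_permutation = perm),
            class = "registered_scan")
}

#' Default grid of the backward-forward registration reconstruction
#'
#' In-plane: the full lateral field of view at detector-matched resolution
#' (pixel spacing scaled to the isocenter plane).  Axially: the whole
#' illuminated cone at the lateral FOV edge, so rays to the top and bottom
#' detector rows traverse reconstructed material wherever the scan
#' actually measured it.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param z_spacing Axial voxel spacing (default: the in-plane spacing).
#' @return A [volume_grid()].
#' @export
registration_grid <- function(geometry, z_spacing = NULL) {
  sid <- geometry$source_isocenter_distance
  sdd <- geometry$source_detector_distance
  ps_iso <- geometry$pixel_spacing * sid / sdd
  r_fov <- geometry$detector_cols / 2 * ps_iso
  v_max <- geometry$detector_rows / 2 * geometry$pixel_spacing
  z_half <- v_max * (sid + r_fov) / sdd
  if (is.null(z_spacing)) z_spacing <- ps_iso
  n_xy <- 2 * ceiling(r_fov / ps_iso / 2) * 2
  n_z <- 2 * ceiling(z_half / z_spacing)
  volume_grid(c(n_xy, n_xy, n_z), c(ps_iso, ps_iso, z_spacing))
}

#' @export
print.registered_scan <- function(x, ...) {
  cat(sprintf(
    "Registered low-dose scan: %d control points, view gains %.3f-%.3f\n",
    nrow(x$deformation$p), min(x$gains), max(x$gains)))
  invisible(x)
}
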