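#' Ray-driven forward projection
#'
#' Computes cone-beam line integrals of a sampled volume: each detector pixel
#' receives the integral of the (trilinearly interpolated) volume along the
#' ray from the source to the pixel center, sampled with a fixed step of
#' \code{step_fraction} times the smallest voxel spacing.  The operator is
#' linear in the volume; rays missing the grid integrate to zero and rays
#' leaving the grid laterally are integrated over the intersected segment
#' only.
#'
#' @param volume 3D numeric array matching \code{grid$size}.
#' @param grid A [volume_grid()].
#' @param geometry A [cone_beam_geometry()].
#' @param step_fraction Ray sampling step as a fraction of the minimum voxel
#'   spacing (default 0.5).
#' @return A \code{rows x cols x views} array of line integrals.
#' @export
forward_project <- function(volume, grid, geometry, step_fraction = 0.5) {
  stopifnot(identical(dim(volume), as.integer(grid$size)),
            all(is.finite(volume)))
  cpp_forward_project(as.numeric(volume), grid$size, grid$spacing,
                      grid$origin, view_angles(geometry),
                      geometry$source_isocenter_distance,
                      geometry$source_detector_distance,
                      geometry$detector_rows, geometry$detector_cols,
                      geometry$pixel_spacing,
                      geometry$detector_offset[1],
                      geometry$detector_offset[2],
                      step_fraction * min(grid$spacing))
}

#' Voxel-driven (optionally deformed) backprojection
#'
#' For every voxel center v and every view, the voxel is projected onto the
#' detector, the projection image is read bilinearly, and the value is
#' accumulated at the voxel.  With \code{weight = "fdk"} the standard FDK
#' distance weight \eqn{(SID/s)^2} and the angular increment are applied, so
#' that backprojecting a filtered stack yields the FDK reconstruction; with
#' \code{weight = "simple"} a plain mean over views is returned (used e.g.
#' for marker blob localization).
#'
#' When a \code{deformation} is supplied (an [mls_deformation()] or a
#' precomputed N x 3 matrix of deformed voxel positions), each voxel's 3D
#' position is transformed *before* it is projected onto the detector, but
#' the readout is still accumulated at the original voxel — this is the
#' deformed backprojection used for inter-scan non-rigid alignment.
#' An identity deformation reproduces the plain backprojection exactly.
#'
#' @param stack Projection array (rows, cols, views) or [projection_stack()].
#' @param geometry A [cone_beam_geometry()].
#' @param grid Output [volume_grid()].
#' With \code{weight = "adjoint"} the distance weights and global scale are
#' chosen so that the operator is the (approximate, up to interpolation
#' differences) adjoint of [forward_project()]:
#' \eqn{\langle F x, y\rangle \approx \langle x, B y\rangle}.
#'
#' @param deformation Optional [mls_deformation()] or N x 3 coordinate matrix.
#' @param weight `"fdk"`, `"simple"` or `"adjoint"`.
#' @return 3D numeric array of size \code{grid$size}.
#' @export
back_project <- function(stack, geometry, grid, deformation = NULL,
                         weight = c("fdk", "simple", "adjoint")) {
  weight <- match.arg(weight)
  data <- stack_data(stack)
  stopifnot(dim(data)[1] == geometry$detector_rows,
            dim(data)[2] == geometry$detector_cols,
            dim(data)[3] == geometry$num_views)
  coords <- NULL
  if (!is.null(deformation)) {
    if (inherits(deformation, "mls_deformation")) {
      coords <- mls_transform(voxel_centers(grid), deformation)
    } else {
      coords <- as.matrix(deformation)
      stopifnot(ncol(coords) == 3,
                nrow(coords) == prod(grid$size))
    }
  }
  sid <- geometry$source_isocenter_distance
  sdd <- geometry$source_detector_distance
  ps <- geometry$pixel_spacing
  scale <- switch(weight,
    fdk = geometry$angular_increment * pi / 180,
    adjoint = prod(grid$spacing) * (sdd / (ps * sid))^2,
    simple = 0)
  cpp_back_project(data, dim(data), view_angles(geometry),
                   sid, sdd, ps,
                   geometry$detector_offset[1], geometry$detector_offset[2],
                   grid$size, grid$spacing, grid$origin,
                   coords,
                   if (weight == "simple") 1L else 0L,
                   scale)
}
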