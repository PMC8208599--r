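#' Circular-trajectory cone-beam acquisition geometry
#'
#' Describes a flat-panel cone-beam CT acquisition on a circular source
#' trajectory around a fixed vertical rotation axis (the world z axis)
#' through the isocenter.  The same object is shared by the simulator, the
#' projection operators and the FDK reconstruction.
#'
#' Coordinate conventions: right-handed world frame with the rotation axis
#' along z and the isocenter at the origin.  At view angle \eqn{\theta} the
#' source sits at \eqn{SID\,(\cos\theta, \sin\theta, 0)} and the detector
#' u axis runs along \eqn{(-\sin\theta, \cos\theta, 0)} (detector columns),
#' the v axis along +z (detector rows).  Detector pixel indices are 1-based
#' and refer to pixel centers; the principal ray hits the detector center
#' pixel position \code{(detector_rows+1)/2, (detector_cols+1)/2} when the
#' offsets are zero.
#'
#' @param source_isocenter_distance Source-to-rotation-axis distance in mm.
#' @param source_detector_distance Source-to-detector distance in mm; must
#'   exceed \code{source_isocenter_distance}.
#' @param detector_rows,detector_cols Detector size in pixels (rows run along
#'   the rotation axis).
#' @param pixel_spacing Isotropic detector pixel spacing in mm.
#' @param num_views Number of projections.
#' @param start_angle Source angle of the first view, degrees.
#' @param angular_increment Rotation between consecutive views, degrees.
#' @param detector_offset Detector shift \code{c(u, v)} in mm (default none).
#' @return An object of class \code{cone_beam_geometry}.
#' @seealso [projection_matrix()], [forward_project()], [fdk_reconstruct()]
#' @export
cone_beam_geometry <- function(source_isocenter_distance,
                               source_detector_distance,
                               detector_rows, detector_cols,
                               pixel_spacing, num_views,
                               start_angle = 0, angular_increment = 0.8,
                               detector_offset = c(0, 0)) {
  stopifnot(source_detector_distance > source_isocenter_distance,
            source_isocenter_distance > 0,
            pixel_spacing > 0, num_views >= 1,
            detector_rows >= 1, detector_cols >= 1,
            length(detector_offset) == 2)
  g <- list(
    source_isocenter_distance = as.numeric(source_isocenter_distance),
    source_detector_distance = as.numeric(source_detector_distance),
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    pixel_spacing = as.numeric(pixel_spacing),
    num_views = as.integer(num_views),
    start_angle = as.numeric(start_angle),
    angular_increment = as.numeric(angular_increment),
    detector_offset = as.numeric(detector_offset)
  )
  class(g) <- "cone_beam_geometry"
  g
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat("Cone-beam geometry\n")
  cat(sprintf("  SID %.1f mm, SDD %.1f mm (magnification %.3f)\n",
              x$source_isocenter_distance, x$source_detector_distance,
              x$source_detector_distance / x$source_isocenter_distance))
  cat(sprintf("  detector %d x %d px @ %.4g mm\n",
              x$detector_rows, x$detector_cols, x$pixel_spacing))
  cat(sprintf("  %d views from %.2f deg, increment %.2f deg (span %.1f deg)\n",
              x$num_views, x$start_angle, x$angular_increment,
              x$num_views * x$angular_increment))
  invisible(x)
}

#' View angles of a geometry
#'
#' @param geometry A [cone_beam_geometry()].
#' @param units `"radians"` (default) or `"degrees"`.
#' @return Numeric vector of length `num_views`.
#' @export
view_angles <- function(geometry, units = c("radians", "degrees")) {
  units <- match.arg(units)
  a <- geometry$start_angle +
    (seq_len(geometry$num_views) - 1) * geometry$angular_increment
  if (units == "radians") a * pi / 180 else a
}

#' Reconstruction volume grid
#'
#' Regular voxel grid with anisotropic spacing.  \code{origin} is the world
#' position of the center of voxel (1,1,1); by default the grid is centered
#' on the isocenter.
#'
#' @param size Integer vector \code{c(nx, ny, nz)}.
#' @param spacing Voxel spacing in mm, scalar or length-3.
#' @param origin World coordinates of the first voxel center, or NULL to
#'   center the grid on the isocenter.
#' @return An object of class \code{volume_grid}.
#' @export
volume_grid <- function(size, spacing, origin = NULL) {
  size <- as.integer(size)
  stopifnot(length(size) == 3, all(size >= 1), all(spacing > 0))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(origin)) origin <- -(size - 1) / 2 * spacing
  stopifnot(length(origin) == 3)
  structure(list(size = size, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("Volume grid %d x %d x %d @ (%.3g, %.3g, %.3g) mm\n",
              x$size[1], x$size[2], x$size[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' World coordinates of all voxel centers
#'
#' @param grid A [volume_grid()].
#' @return An N x 3 matrix in voxel storage order (x index fastest).
#' @export
voxel_centers <- function(grid) {
  ix <- (seq_len(grid$size[1]) - 1) * grid$spacing[1] + grid$origin[1]
  iy <- (seq_len(grid$size[2]) - 1) * grid$spacing[2] + grid$origin[2]
  iz <- (seq_len(grid$size[3]) - 1) * grid$spacing[3] + grid$origin[3]
  cbind(rep(ix, times = grid$size[2] * grid$size[3]),
        rep(rep(iy, each = grid$size[1]), times = grid$size[3]),
        rep(iz, each = grid$size[1] * grid$size[2]))
}

#' Projection matrix of one view
#'
#' Returns the 3 x 4 homogeneous matrix mapping a world point
#' \code{c(x, y, z, 1)} to detector pixel coordinates: for
#' \code{h = P \%*\% c(x,y,z,1)}, the (1-based, fractional) pixel column is
#' \code{h[1]/h[3]} and the pixel row \code{h[2]/h[3]}.  The third row holds
#' the FDK depth \eqn{s = SID - x\cdot\hat e(\theta)} scaled so that the
#' perspective division yields the pixel position.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param view_index View number in \code{1..num_views}.
#' @return A 3 x 4 numeric matrix.
#' @export
projection_matrix <- function(geometry, view_index) {
  if (view_index < 1 || view_index > geometry$num_views)
    stop("view_index out of range [1, ", geometry$num_views, "]")
  th <- view_angles(geometry)[view_index]
  sid <- geometry$source_isocenter_distance
  sdd <- geometry$source_detector_distance
  ps <- geometry$pixel_spacing
  e_s <- c(cos(th), sin(th), 0)     # isocenter -> source direction
  e_u <- c(-sin(th), cos(th), 0)
  e_v <- c(0, 0, 1)
  cu <- (geometry$detector_cols + 1) / 2 - geometry$detector_offset[1] / ps
  cv <- (geometry$detector_rows + 1) / 2 - geometry$detector_offset[2] / ps
  row3 <- c(-e_s, sid)
  rbind((sdd / ps) * c(e_u, 0) + cu * row3,
        (sdd / ps) * c(e_v, 0) + cv * row3,
        row3)
}

#' Project world points to detector pixels for one view
#'
#' Convenience wrapper around [projection_matrix()] for an n x 3 matrix of
#' world points; returns an n x 2 matrix of (row, col) pixel coordinates.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param geometry A [cone_beam_geometry()].
#' @param view_index View number.
#' @export
project_points <- function(points, geometry, view_index) {
  points <- rbind(points)
  P <- projection_matrix(geometry, view_index)
  h <- cbind(points, 1) %*% t(P)
  cbind(row = h[, 2] / h[, 3], col = h[, 1] / h[, 3])
}

#' Per-view stack of line-integral projection images
#'
#' Container pairing a \code{detector_rows x detector_cols x num_views}
#' array of line integrals (\eqn{-\ln I/I_0}, unitless) with its acquisition
#' geometry.  Background (air) pixels are approximately zero except in
#' saturated scans, where clipping maps them to the saturation value.
#'
#' @param data 3D numeric array (rows, cols, views).
#' @param geometry Matching [cone_beam_geometry()].
#' @export
projection_stack <- function(data, geometry) {
  d <- dim(data)
  stopifnot(length(d) == 3,
            d[1] == geometry$detector_rows,
            d[2] == geometry$detector_cols,
            d[3] == geometry$num_views,
            all(is.finite(data)))
  structure(list(data = data, geometry = geometry),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("Projection stack: %d views of %d x %d px, range [%.4g, %.4g]\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2],
              min(x$data), max(x$data)))
  invisible(x)
}

# accept either a projection_stack or a bare array
stack_data <- function(x) {
  if (inherits(x, "projection_stack")) x$data else x
}
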