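#' Parametric two-leg knee phantom
#'
#' Analytic stand-in for a numerical knee model: two legs, each consisting of
#' femur, tibia, patella and fibula (cortical bone) with bone marrow cores,
#' a muscle-like soft-tissue bulk and a surrounding fat envelope, plus
#' optional 1 mm metal fiducial markers on the anterior skin surface near
#' the joint.  All structures are convex quadric primitives (ellipsoids and
#' capped elliptic cylinders) so that projections can be computed by exact
#' ray intersection.  Overlapping primitives are resolved by priority:
#' innermost material wins (marker > marrow > bone > muscle > fat).
#'
#' The default dimensions describe an adult lying with the knees pressed
#' together: fat envelopes of lateral half-width 69 mm and anterior-posterior
#' half-depth 73 mm centered \code{2 * leg_half_separation} apart, slightly
#' overlapping at the midline.  The legs are deliberately wide enough that
#' in anterior-posterior-ish views their silhouette extends beyond the
#' reconstructable field of view of the default scan geometries: overexposure
#' at the thin skin border then occurs only in lateral-ish views, which is
#' the premise of correcting only the lateral view range.  The anterior
#' direction is -y; markers sit on the anterior surface, non-overlapping in
#' projection.
#'
#' @param leg_half_separation Half the distance between the two leg centers
#'   in mm (default 64; envelopes overlap by 10 mm at the midline).
#' @param include_markers If TRUE (default), place 11 metal markers of
#'   `marker_diameter` mm on the anterior surfaces (6 left, 5 right).
#' @param marker_diameter Marker diameter in mm (default 1).
#' @return An object of class \code{knee_phantom}: list with
#'   \code{primitives}, a \code{markers} matrix (n x 3 world mm, NULL when
#'   disabled) and the two leg centers.
#' @export
knee_phantom <- function(leg_half_separation = 64, include_markers = TRUE,
                         marker_diameter = 1) {
  prims <- list()
  add <- function(shape, center, material, priority, leg,
                  semi = NULL, radii = NULL, half_length = NULL) {
    prims[[length(prims) + 1]] <<- list(
      shape = shape, center = center, semi = semi, radii = radii,
      half_length = half_length, rotation = diag(3),
      material = material, priority = priority, leg = leg)
  }
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    cx <- sgn * leg_half_separation
    # local anterior = -y; local lateral (away from midline) = sgn * x
    lp <- function(x, y, z) c(cx + sgn * x, y, z)
    add("cylinder", lp(0, 0, 0), "fat", 1, side,
        radii = c(69, 73), half_length = 170)
    add("cylinder", lp(0, 1, 0), "soft_tissue", 2, side,
        radii = c(54, 58), half_length = 170)
    add("cylinder", lp(0, 6, 89), "cortical_bone", 3, side,   # femur shaft
        radii = c(16, 16), half_length = 81)
    add("ellipsoid", lp(0, 6, 14), "cortical_bone", 3, side,  # condyles
        semi = c(24, 20, 16))
    add("cylinder", lp(0, 6, 93), "bone_marrow", 4, side,
        radii = c(9, 9), half_length = 77)
    add("cylinder", lp(0, 9, -91), "cortical_bone", 3, side,  # tibia shaft
        radii = c(15, 15), half_length = 79)
    add("ellipsoid", lp(0, 9, -16), "cortical_bone", 3, side, # plateau
        semi = c(23, 19, 12))
    add("cylinder", lp(0, 9, -95), "bone_marrow", 4, side,
        radii = c(8, 8), half_length = 75)
    add("cylinder", lp(26, 22, -94), "cortical_bone", 3, side, # fibula
        radii = c(5, 5), half_length = 76)
    add("cylinder", lp(26, 22, -94), "bone_marrow", 4, side,
        radii = c(2, 2), half_length = 74)
    add("ellipsoid", lp(0, -46, 12), "cortical_bone", 3, side, # patella
        semi = c(16, 9, 18))
  }
  # soft-tissue contact region where the pressed knees touch: thickens the
  # inter-knee notch so that near-anterior-posterior rays through the
  # midline stay well above the saturation threshold (no overexposure
  # outside the lateral view range); stays inside the pair silhouette
  add("cylinder", c(0, 0, 0), "fat", 1, "none",
      radii = c(20, 50), half_length = 170)
  markers <- NULL
  if (include_markers) {
    # (leg, angle from anterior in deg, z mm); on the fat surface, spaced
    # so that projections do not overlap (distinct detector rows)
    spec <- rbind(
      c(-1, -18, -45), c(-1, -6, -18), c(-1, 6, 8), c(-1, 18, 34),
      c(-1, -12, 52), c(-1, 10, -55),
      c(1, -15, -35), c(1, -3, -8), c(1, 9, 18), c(1, 16, 44), c(1, -8, -62))
    markers <- t(apply(spec, 1, function(m) {
      sgn <- m[1]
      phi <- m[2] * pi / 180
      scl <- 1 - (marker_diameter / 2 + 0.1) / 69  # just inside the surface
      c(sgn * leg_half_separation + sgn * 69 * scl * sin(phi),
        -73 * scl * cos(phi), m[3])
    }))
    for (i in seq_len(nrow(markers))) {
      side <- if (spec[i, 1] < 0) "left" else "right"
      prims[[length(prims) + 1]] <- list(
        shape = "ellipsoid", center = markers[i, ],
        semi = rep(marker_diameter / 2, 3), radii = NULL, half_length = NULL,
        rotation = diag(3), material = "marker_metal", priority = 6,
        leg = side)
    }
  }
  structure(list(primitives = prims, markers = markers,
                 leg_centers = list(left = c(-leg_half_separation, 0, 0),
                                    right = c(leg_half_separation, 0, 0))),
            class = "knee_phantom")
}

#' @export
print.knee_phantom <- function(x, ...) {
  cat(sprintf("Knee phantom: %d primitives, %d markers\n",
              length(x$primitives),
              if (is.null(x$markers)) 0L else nrow(x$markers)))
  invisible(x)
}

#' Build a phantom from an explicit primitive list
#'
#' Lower-level companion of [knee_phantom()] for simple test objects
#' (cylinders, spheres) or custom phantoms.  Each primitive is a list with
#' \code{shape} ("ellipsoid" or "cylinder"), \code{center}, \code{material}
#' (see [material_names()]), \code{priority}, and either \code{semi}
#' (ellipsoid semi-axes) or \code{radii} (two cross-section radii) plus
#' \code{half_length}; optional \code{rotation} (3 x 3) and \code{leg}.
#'
#' @param primitives List of primitive descriptions.
#' @param markers Optional n x 3 matrix of marker positions.
#' @return An object of class \code{knee_phantom}.
#' @export
analytic_phantom <- function(primitives, markers = NULL) {
  primitives <- lapply(primitives, function(p) {
    p$rotation <- p$rotation %||% diag(3)
    p$leg <- p$leg %||% "none"
    p$semi <- p$semi %||% NULL
    p$radii <- p$radii %||% NULL
    p$half_length <- p$half_length %||% NULL
    stopifnot(p$shape %in% c("ellipsoid", "cylinder"))
    p
  })
  structure(list(primitives = primitives, markers = markers,
                 leg_centers = list(left = c(0, 0, 0), right = c(0, 0, 0))),
            class = "knee_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rigid motion of one leg
#'
#' A rotation about an axis through a center point followed by a
#' translation.  The default center NULL means the moving leg's own center,
#' so a pure `rotation_deg` models a leg rotating in or out about its axis.
#'
#' @param translation Length-3 translation (mm).
#' @param rotation_deg Rotation angle in degrees.
#' @param axis Rotation axis direction (default the leg axis, z).
#' @param center Rotation center, or NULL for the leg center.
#' @return An object of class \code{rigid_motion}.
#' @export
rigid_motion <- function(translation = c(0, 0, 0), rotation_deg = 0,
                         axis = c(0, 0, 1), center = NULL) {
  stopifnot(length(translation) == 3, length(axis) == 3,
            sum(axis^2) > 0)
  structure(list(translation = as.numeric(translation),
                 rotation_deg = as.numeric(rotation_deg),
                 axis = axis / sqrt(sum(axis^2)), center = center),
            class = "rigid_motion")
}

# Rodrigues rotation matrix
rotation_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply per-leg rigid motion to a phantom
#'
#' Moves each leg group (all its primitives and markers) rigidly; models
#' inter-scan subject motion such as a change of the leg opening angle or a
#' leg rotated slightly further in or out.  The input phantom is untouched.
#'
#' @param phantom A [knee_phantom()].
#' @param left,right [rigid_motion()] for each leg (identity by default).
#' @return A new \code{knee_phantom}.
#' @export
apply_motion <- function(phantom, left = rigid_motion(),
                         right = rigid_motion()) {
  motions <- list(left = left, right = right)
  out <- phantom
  for (side in c("left", "right")) {
    m <- motions[[side]]
    ctr <- if (is.null(m$center)) phantom$leg_centers[[side]] else m$center
    R <- rotation_matrix(m$axis, m$rotation_deg)
    move <- function(p) as.numeric(R %*% (p - ctr)) + ctr + m$translation
    for (i in seq_along(out$primitives)) {
      pr <- out$primitives[[i]]
      if (!identical(pr$leg, side)) next
      pr$center <- move(pr$center)
      pr$rotation <- R %*% pr$rotation
      out$primitives[[i]] <- pr
    }
    if (!is.null(out$markers)) {
      sel <- marker_leg(phantom) == side
      out$markers[sel, ] <- t(apply(out$markers[sel, , drop = FALSE], 1, move))
    }
    out$leg_centers[[side]] <- move(phantom$leg_centers[[side]])
  }
  lim <- 300  # primitives must stay inside the scannable region
  ctrs <- vapply(out$primitives, function(p) max(abs(p$center[1:2])), 0)
  if (any(ctrs > lim))
    stop("motion pushes the phantom outside the reconstructable field of view")
  out
}

# leg assignment of each marker row (by x sign of the construction)
marker_leg <- function(phantom) {
  legs <- vapply(phantom$primitives, function(p) {
    if (identical(p$material, "marker_metal")) p$leg else NA_character_
  }, "")
  legs[!is.na(legs)]
}

# Encode the primitive list for the C++ tracer:
# columns 1 type (0 ellipsoid / 1 cylinder), 2:4 center,
# 5:7 (a,b,c) = ellipsoid semi-axes or (rx, half_length, ry), 8:16 rotation.
encode_phantom <- function(phantom) {
  mats <- unique(vapply(phantom$primitives, `[[`, "", "material"))
  tab <- t(vapply(phantom$primitives, function(p) {
    abc <- if (p$shape == "ellipsoid") p$semi
           else c(p$radii[1], p$half_length, p$radii[2])
    c(if (p$shape == "ellipsoid") 0 else 1, p$center, abc, as.numeric(p$rotation))
  }, numeric(16)))
  # rotation stored row-major in C++: transpose the column-major 3x3
  tab[, 8:16] <- tab[, c(8, 11, 14, 9, 12, 15, 10, 13, 16)]
  list(prims = tab,
       mat = match(vapply(phantom$primitives, `[[`, "", "material"),
                   mats) - 1L,
       prio = vapply(phantom$primitives, function(p) as.integer(p$priority),
                     1L),
       materials = mats)
}

#' Exact per-material path lengths of a single ray
#'
#' Intersects one ray with the phantom analytically and returns the total
#' intersected length per material, resolving overlaps by priority.  Mostly
#' a diagnostic / testing aid for the projection simulator.
#'
#' @param phantom A [knee_phantom()].
#' @param origin,direction Ray origin and direction (world mm).
#' @return Named numeric vector of lengths (mm) per material.
#' @export
trace_ray <- function(phantom, origin, direction) {
  enc <- encode_phantom(phantom)
  L <- cpp_trace_ray(enc$prims, enc$mat, enc$prio, length(enc$materials),
                     as.numeric(origin), as.numeric(direction))
  names(L) <- enc$materials
  L
}
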