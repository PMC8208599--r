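#' Localize fiducial markers in 3D from a projection stack
#'
#' The circular projections of the metal markers are detected in every view
#' with the fast radial symmetry transform; the response stack is then
#' backprojected with the system geometry, producing a blurry 3D blob at
#' each marker position.  The blob volume is binarized, labeled by
#' 26-connected component analysis, and candidate blobs yield
#' response-weighted centroids in world coordinates.
#'
#' Three measures make the detection robust on projections dominated by
#' other high-contrast structure (saturation borders, bone edges,
#' photon-starved plateaus): (i) each view is background-suppressed by
#' subtracting a 3 x 3 median before the FRST, which preserves the compact
#' (sub-pixel to few-pixel) marker spots and removes extended edges;
#' (ii) marker candidates are the local maxima of the binarized blob
#' volume rather than whole connected components — a single component may
#' fuse several markers with nearby surface response, but each marker
#' still carries its own sharp peak; (iii) candidates are ranked by
#' reprojection consistency (the median, over all views, of the response
#' at the candidate's projected position) — a physical marker has response
#' in essentially every view, whereas streak-intersection ghosts and
#' diffuse surface response do not — and, after suppression of candidates
#' closer than \code{min_separation} to a better one, the
#' \code{expected_n} most consistent candidates are kept.
#'
#' @param stack [projection_stack()] (or array plus geometry) of the scan
#'   containing the markers.
#' @param geometry A [cone_beam_geometry()] (taken from the stack when
#'   omitted).
#' @param grid [volume_grid()] for the blob volume.
#' @param expected_n Number of markers to find (default 11).
#' @param radii FRST radii in pixels (default \code{c(1, 2)}, matching a
#'   1 mm marker magnified onto coarse detector pixels).
#' @param min_separation Minimum distance between two accepted markers in
#'   mm (default 8; of two close candidates the more consistent one wins).
#' @param ... Passed to [frst_response()].
#' @param exclude Optional logical array (same shape as the stack): pixels
#'   to ignore, e.g. photon-starved pixels of a low-dose scan.
#' @param min_score Minimum reprojection-consistency score (median
#'   response at the projected candidate position, line-integral gradient
#'   units) for a candidate to count as a marker (default 3e-4): genuine
#'   metal markers in simulated scans score around 3e-3, while residual
#'   clutter in marker-free scans stays below 1e-4, so the floor rejects
#'   "detections" on markerless data with a wide margin on both sides.
#' @return Object of class \code{marker_set}: \code{positions}
#'   (\code{expected_n} x 3 world mm, ordered by decreasing consistency
#'   score), \code{sizes} (voxels per blob) and \code{scores}.
#' @export
localize_markers_3d <- function(stack, geometry = NULL, grid,
                                expected_n = 11, radii = c(1, 2),
                                min_separation = 8,
                                exclude = NULL, min_score = 3e-4, ...) {
  data <- stack_data(stack)
  if (is.null(geometry)) {
    stopifnot(inherits(stack, "projection_stack"))
    geometry <- stack$geometry
  }
  nv <- dim(data)[3]
  resp <- array(0, dim(data))
  for (k in seq_len(nv)) {
    dot <- data[, , k] - cpp_median3(data[, , k])
    dot[dot < 0] <- 0
    if (!is.null(exclude)) dot[exclude[, , k]] <- 0
    resp[, , k] <- frst_response(dot, radii = radii, ...)
  }
  blob <- back_project(resp, geometry, grid, weight = "simple")
  blob[blob < 0] <- 0
  thr <- otsu_threshold(blob)
  lab <- cpp_label3d(blob > thr, grid$size)
  peaks <- which(cpp_local_max3d(blob, grid$size) & lab > 0)
  if (!length(peaks))
    stop(sprintf("0 of %d markers found", expected_n))
  # refine each peak to a response-weighted centroid of its neighborhood
  ctr <- voxel_centers(grid)
  pos <- t(vapply(peaks, function(i)
    refine_peak(blob, grid, ctr, i), numeric(3)))
  # reprojection consistency of each candidate
  vals <- matrix(0, nrow(pos), nv)
  for (k in seq_len(nv)) {
    pj <- project_points(pos, geometry, k)
    vals[, k] <- bilinear_read(resp[, , k], pj[, 1], pj[, 2])
  }
  score <- apply(vals, 1, median)
  # greedy non-maximum suppression by score
  ord <- order(score, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (score[i] < min_score) break
    if (length(kept) &&
        min(sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2))) <
          min_separation) next
    kept <- c(kept, i)
    if (length(kept) == expected_n) break
  }
  if (length(kept) < expected_n)
    stop(sprintf("%d of %d markers found", length(kept), expected_n))
  structure(list(positions = pos[kept, , drop = FALSE],
                 sizes = tabulate(lab)[lab[peaks[kept]]],
                 scores = score[kept]),
            class = "marker_set")
}

# response-weighted centroid of the 5x5x5 neighborhood of a peak voxel
refine_peak <- function(blob, grid, ctr, idx) {
  d <- grid$size
  iz <- (idx - 1) %/% (d[1] * d[2])
  rem <- (idx - 1) %% (d[1] * d[2])
  iy <- rem %/% d[1]
  ix <- rem %% d[1]
  xs <- max(0, ix - 2):min(d[1] - 1, ix + 2)
  ys <- max(0, iy - 2):min(d[2] - 1, iy + 2)
  zs <- max(0, iz - 2):min(d[3] - 1, iz + 2)
  sel <- as.vector(outer(outer(xs + 1, ys * d[1], `+`),
                         zs * d[1] * d[2], `+`))
  w <- blob[sel]^2
  colSums(ctr[sel, , drop = FALSE] * w) / sum(w)
}

# vectorized bilinear image read, zero outside
bilinear_read <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- pmin(pmax(r[ok], 1), nr); c <- pmin(pmax(c[ok], 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  out[ok] <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set: %d markers, blob sizes %s voxels\n",
              nrow(x$positions), paste(range(x$sizes), collapse = "-")))
  invisible(x)
}

#' Establish marker correspondence between two scans
#'
#' The physical markers are identical in both scans but the localization
#' order is arbitrary.  Correspondence is established by a rigid Procrustes
#' pre-alignment (centroid shift + Kabsch rotation, iterated with a
#' globally greedy bijective assignment) followed by a
#' mutual-nearest-neighbor validation.  When no single rigid motion
#' explains the matching — the two legs move independently, and a large
#' inter-scan motion can displace markers further than their spacing —
#' each set is split into its two leg groups (largest gap along the
#' principal axis) and the groups are matched separately.  An ambiguous
#' (non-bijective) matching is an error.
#'
#' @param a,b \code{marker_set}s or n x 3 matrices with equal marker count.
#' @return Integer permutation \code{perm} such that \code{b[perm, ]}
#'   corresponds row-by-row to \code{a}.
#' @export
match_markers <- function(a, b) {
  A <- if (inherits(a, "marker_set")) a$positions else as.matrix(a)
  B <- if (inherits(b, "marker_set")) b$positions else as.matrix(b)
  if (nrow(A) != nrow(B))
    stop(sprintf("marker count mismatch: %d vs %d", nrow(A), nrow(B)))
  direct <- tryCatch(match_rigid_group(A, B), error = function(e) NULL)
  if (!is.null(direct)) return(direct)
  # two-group (per-leg) fallback
  ga <- split_largest_gap(A)
  gb <- split_largest_gap(B)
  sizes_a <- tabulate(ga, 2)
  sizes_b <- tabulate(gb, 2)
  if (!setequal(sizes_a, sizes_b))
    stop("ambiguous marker correspondence (group sizes differ)")
  if (sizes_a[1] != sizes_b[1]) gb <- 3L - gb
  if (sizes_a[1] == sizes_a[2]) {
    # equal groups: align group centroids after overall centroid shift
    ca <- rowsum(A, ga) / sizes_a
    cb <- rowsum(sweep(B, 2, colMeans(B) - colMeans(A)), gb) / sizes_b
    if (sum((ca[1, ] - cb[1, ])^2) > sum((ca[1, ] - cb[2, ])^2))
      gb <- 3L - gb
  }
  perm <- integer(nrow(A))
  for (gr in 1:2) {
    ia <- which(ga == gr); ib <- which(gb == gr)
    perm[ia] <- ib[match_rigid_group(A[ia, , drop = FALSE],
                                     B[ib, , drop = FALSE])]
  }
  perm
}

# split a point set into the two-group partition minimizing the total
# within-group squared scatter, among all cuts of the orderings along the
# coordinate and principal axes (deterministic 2-means over 1D cuts)
split_largest_gap <- function(X) {
  dirs <- cbind(diag(3), prcomp(X, center = TRUE, scale. = FALSE)$rotation)
  n <- nrow(X)
  best <- NULL
  best_w <- Inf
  for (j in seq_len(ncol(dirs))) {
    o <- order(as.numeric(X %*% dirs[, j]))
    for (cut in seq_len(n - 1)) {
      g1 <- o[seq_len(cut)]
      g2 <- o[-seq_len(cut)]
      w <- sum(scale(X[g1, , drop = FALSE], scale = FALSE)^2) +
        sum(scale(X[g2, , drop = FALSE], scale = FALSE)^2)
      if (w < best_w) {
        best_w <- w
        best <- list(g1 = g1)
      }
    }
  }
  grp <- rep(2L, n)
  grp[best$g1] <- 1L
  grp
}

# single-rigid-motion correspondence (iterated greedy assignment +
# Procrustes); errors when the result is not mutually nearest
match_rigid_group <- function(A, B) {
  n <- nrow(A)
  if (n == 1) return(1L)
  Bt <- sweep(B, 2, colMeans(B) - colMeans(A))  # centroid pre-alignment
  perm <- integer(n)
  for (it in 1:10) {
    # globally greedy bijective assignment on the distance matrix
    d2 <- outer(rowSums(A^2), rowSums(Bt^2), `+`) - 2 * A %*% t(Bt)
    perm_new <- integer(n)
    dd <- d2
    for (step in seq_len(n)) {
      ij <- arrayInd(which.min(dd), dim(dd))
      perm_new[ij[1]] <- ij[2]
      dd[ij[1], ] <- Inf
      dd[, ij[2]] <- Inf
    }
    converged <- identical(perm_new, perm)
    perm <- perm_new
    # rigid Procrustes refinement on the current matching
    Am <- sweep(A, 2, colMeans(A))
    Bp <- B[perm, , drop = FALSE]
    Bm <- sweep(Bp, 2, colMeans(Bp))
    sv <- svd(t(Bm) %*% Am)
    R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
    Bt <- sweep(sweep(B, 2, colMeans(B)) %*% R, 2, -colMeans(A))
    if (converged) break
  }
  # validate: after alignment the matching must be mutually nearest
  d2 <- outer(rowSums(A^2), rowSums(Bt^2), `+`) - 2 * A %*% t(Bt)
  fwd <- apply(d2, 1, which.min)
  back <- apply(d2, 2, which.min)
  if (any(fwd != perm) || any(back[perm] != seq_len(n)))
    stop("ambiguous marker correspondence (matching not bijective)")
  perm
}

#' Remove projected markers from a stack by harmonic inpainting
#'
#' Replaces a disk around each projected marker position with the solution
#' of the Laplace equation using the surrounding pixels as Dirichlet
#' boundary (a smooth membrane fill), removing the high-contrast marker
#' spots that would otherwise cause streak/blob artifacts in the
#' reconstruction.  All pixels outside the disks are returned bit-identical.
#'
#' @param stack [projection_stack()] or array.
#' @param markers_2d List of per-view n x 2 matrices of (row, col) pixel
#'   positions, e.g. from [project_points()]; or a single n x 3 matrix of
#'   3D world positions, which is projected per view with the geometry.
#' @param radius Disk radius in pixels (> 0).
#' @param geometry Needed when 3D positions are given and `stack` is a bare
#'   array.
#' @return Array with marker disks inpainted.
#' @export
inpaint_markers <- function(stack, markers_2d, radius, geometry = NULL) {
  if (radius <= 0) stop("radius must be positive")
  data <- stack_data(stack)
  nv <- dim(data)[3]
  if (is.matrix(markers_2d) && ncol(markers_2d) == 3) {
    if (is.null(geometry)) {
      stopifnot(inherits(stack, "projection_stack"))
      geometry <- stack$geometry
    }
    markers_2d <- lapply(seq_len(nv), function(k)
      project_points(markers_2d, geometry, k))
  }
  stopifnot(length(markers_2d) == nv)
  out <- data
  for (k in seq_len(nv)) {
    img <- out[, , k]
    pos <- markers_2d[[k]]
    for (i in seq_len(NROW(pos)))
      img <- inpaint_disk(img, pos[i, 1], pos[i, 2], radius)
    out[, , k] <- img
  }
  out
}

# harmonic fill of one disk (dense Laplace solve on the disk pixels)
inpaint_disk <- function(img, r0, c0, radius) {
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(1, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  if (!length(rs) || !length(cs)) return(img)
  pix <- expand.grid(r = rs, c = cs)
  inside <- (pix$r - r0)^2 + (pix$c - c0)^2 <= radius^2
  if (!any(inside)) return(img)
  pix <- pix[inside, ]
  m <- nrow(pix)
  key <- paste(pix$r, pix$c)
  idx <- seq_len(m); names(idx) <- key
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    deg <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- pix$r[i] + d[1]; cc <- pix$c[i] + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      deg <- deg + 1
      j <- idx[paste(rr, cc)]
      if (is.na(j)) b[i] <- b[i] + img[rr, cc] else A[i, j] <- -1
    }
    A[i, i] <- deg
    if (deg == 0) { A[i, i] <- 1; b[i] <- img[pix$r[i], pix$c[i]] }
  }
  img[cbind(pix$r, pix$c)] <- solve(A, b)
  img
}
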