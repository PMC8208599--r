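#' Affine moving-least-squares deformation from paired control points
#'
#' Given initial control points \code{p} (e.g. marker positions in the
#' low-dose scan) and target positions \code{q} (the same markers in the
#' AEC scan), the deformation evaluates, for every query point v, the
#' affine map minimizing the weighted least-squares objective
#' \deqn{\sum_i w_i(v)\,|A\,p_i + b - q_i|^2,\qquad
#'       w_i(v) = 1/|p_i - v|^{2\alpha},}
#' i.e. a *different* affine map for every point, smoothly interpolating
#' the control points: as \eqn{v \to p_i} the weight diverges and
#' \eqn{f(p_i) = q_i} exactly (handled as a special case within
#' \code{eps}).  With \code{p = q} the deformation is the identity
#' everywhere, and a pure translation of all controls is reproduced exactly
#' at every query point.
#'
#' A full affine solve needs at least 4 control points spread in all three
#' dimensions.  Coplanar or collinear configurations leave some affine
#' degrees of freedom unconstrained — e.g. markers placed only on the
#' anterior skin surface barely spread along the depth direction, and the
#' affine solve would amplify localization noise into large shears there.
#' Queries whose weighted control covariance is ill-conditioned (smallest
#' to largest eigenvalue ratio below \code{cond_tol}) therefore fall back
#' to a weighted rigid (Kabsch) solve; exactly rank-deficient control sets
#' additionally produce a warning at construction.
#'
#' @param p,q n x 3 matrices of initial and target control points (world
#'   mm), in corresponding row order (see [match_markers()]).
#' @param alpha Weight falloff exponent (> 0, default 1).
#' @param cond_tol Eigenvalue-ratio threshold below which the per-query
#'   solve is rigid instead of affine (default 0.01).
#' @return Object of class \code{mls_deformation}.
#' @export
mls_deformation <- function(p, q, alpha = 1, cond_tol = 0.01) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3, ncol(q) == 3, nrow(p) == nrow(q), alpha > 0)
  if (nrow(p) < 4)
    stop("at least 4 control points are required for an affine solve")
  degenerate <- qr(sweep(p, 2, colMeans(p)))$rank < 3
  if (degenerate)
    warning("control points are (near-)coplanar; using rigid fallback")
  ev <- eigen(crossprod(sweep(p, 2, colMeans(p))), symmetric = TRUE,
              only.values = TRUE)$values
  structure(list(p = p, q = q, alpha = alpha, cond_tol = cond_tol,
                 degenerate = degenerate,
                 identity = identical(unname(p), unname(q)),
                 solve_mode = if (degenerate || ev[3] < cond_tol * ev[1])
                   "rigid" else "affine"),
            class = "mls_deformation")
}

#' @export
print.mls_deformation <- function(x, ...) {
  cat(sprintf("MLS deformation: %d control points, alpha = %g (%s solve)\n",
              nrow(x$p), x$alpha, x$solve_mode))
  cat(sprintf("  mean control displacement: %.3f mm\n",
              mean(sqrt(rowSums((x$q - x$p)^2)))))
  invisible(x)
}

#' Apply a moving-least-squares deformation to points
#'
#' @param points N x 3 matrix (or length-3 vector) of world coordinates.
#' @param deformation An [mls_deformation()].
#' @param eps Queries within this distance of a control point return the
#'   corresponding target exactly (default 1e-9 mm).
#' @return Deformed coordinates, same shape as the input.
#' @export
mls_transform <- function(points, deformation, eps = 1e-9) {
  stopifnot(inherits(deformation, "mls_deformation"))
  vec <- is.null(dim(points))
  V <- if (vec) matrix(points, 1) else as.matrix(points)
  stopifnot(ncol(V) == 3)
  # p = q solves to the identity; short-circuit so it is exact
  if (isTRUE(deformation$identity)) return(if (vec) as.numeric(V) else V)
  res <- cpp_mls_apply(V, deformation$p, deformation$q,
                       deformation$alpha, eps,
                       deformation$cond_tol %||% 0.01)
  if (res$fallback && identical(deformation$solve_mode, "affine") &&
      !deformation$degenerate)
    warning("MLS solve was singular for some queries; rigid fallback used")
  if (vec) as.numeric(res$points) else res$points
}
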