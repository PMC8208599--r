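# separable Gaussian filtering with "valid" output region
gaussian_kernel_1d <- function(sigma, radius = ceiling(3.5 * sigma)) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# filter a matrix along rows then columns, valid region only
conv2_sep_valid <- function(M, k) {
  nt <- length(k)
  nr <- nrow(M); nc <- ncol(M)
  A <- matrix(0, nr - nt + 1, nc)
  for (i in seq_len(nt))
    A <- A + k[i] * M[i:(nr - nt + i), , drop = FALSE]
  B <- matrix(0, nrow(A), nc - nt + 1)
  for (j in seq_len(nt))
    B <- B + k[j] * A[, j:(nc - nt + j), drop = FALSE]
  B
}

#' Structural similarity index of two volumes
#'
#' Mean local SSIM with a Gaussian window (sigma = 1.5, 11 x 11 support)
#' and the standard constants \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}
#' where \eqn{L} is the data range.  By default the local statistics are
#' computed slice-wise over axial (z) slices and averaged; \code{window =
#' "3d"} uses a full 3D Gaussian window instead.  Window positions are
#' restricted to the valid region (no padding).
#'
#' @param vol,reference 3D arrays of equal shape (2D matrices also work in
#'   slice mode).
#' @param data_range Value range \eqn{L}; default
#'   \code{max(reference) - min(reference)}.
#' @param sigma Gaussian window standard deviation in voxels (default 1.5).
#' @param window `"slice"` (default) or `"3d"`.
#' @return SSIM score in `[-1, 1]`.
#' @export
ssim_volume <- function(vol, reference, data_range = NULL, sigma = 1.5,
                        window = c("slice", "3d")) {
  window <- match.arg(window)
  stopifnot(identical(dim(vol), dim(reference)))
  if (is.null(data_range)) data_range <- max(reference) - min(reference)
  if (data_range <= 0) stop("data_range must be positive")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  k <- gaussian_kernel_1d(sigma, radius = 5)
  ssim_of <- function(f) {
    mu1 <- f(vol); mu2 <- f(reference)
    v1 <- f(vol^2) - mu1^2
    v2 <- f(reference^2) - mu2^2
    cov12 <- f(vol * reference) - mu1 * mu2
    mean(((2 * mu1 * mu2 + C1) * (2 * cov12 + C2)) /
           ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
  }
  if (window == "slice") {
    if (length(dim(vol)) == 2) return(ssim_of(function(a) conv2_sep_valid(a, k)))
    nz <- dim(vol)[3]
    scores <- vapply(seq_len(nz), function(z) {
      v <- vol[, , z]; r <- reference[, , z]
      mu1 <- conv2_sep_valid(v, k); mu2 <- conv2_sep_valid(r, k)
      v1 <- conv2_sep_valid(v^2, k) - mu1^2
      v2 <- conv2_sep_valid(r^2, k) - mu2^2
      cov12 <- conv2_sep_valid(v * r, k) - mu1 * mu2
      mean(((2 * mu1 * mu2 + C1) * (2 * cov12 + C2)) /
             ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
    }, 0)
    mean(scores)
  } else {
    f <- function(a) conv3_sep_valid(a, k)
    ssim_of(f)
  }
}

# 3D separable valid convolution
conv3_sep_valid <- function(A, k) {
  nt <- length(k)
  d <- dim(A)
  B <- array(0, c(d[1] - nt + 1, d[2], d[3]))
  for (i in seq_len(nt))
    B <- B + k[i] * A[i:(d[1] - nt + i), , , drop = FALSE]
  C <- array(0, c(dim(B)[1], d[2] - nt + 1, d[3]))
  for (j in seq_len(nt))
    C <- C + k[j] * B[, j:(d[2] - nt + j), , drop = FALSE]
  D <- array(0, c(dim(C)[1], dim(C)[2], d[3] - nt + 1))
  for (m in seq_len(nt))
    D <- D + k[m] * C[, , m:(d[3] - nt + m), drop = FALSE]
  D
}

#' Range-normalized root mean squared error
#'
#' \deqn{nRMSE = \sqrt{mean((vol - reference)^2)} / (\max(reference) -
#' \min(reference))}
#'
#' @param vol,reference Arrays of equal shape.
#' @return Non-negative score (0 for identical volumes).
#' @export
nrmse_volume <- function(vol, reference) {
  stopifnot(identical(dim(vol), dim(reference)))
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("reference has zero value range")
  sqrt(mean((vol - reference)^2)) / rng
}

#' Strip a boundary shell from a volume
#'
#' Cone-beam edge voxels are not fully determined by the data; quality
#' metrics are therefore evaluated excluding a thin boundary shell.
#'
#' @param vol 3D array.
#' @param n Shell thickness in voxels (default 2).
#' @return The inner sub-array.
#' @export
strip_boundary <- function(vol, n = 2) {
  d <- dim(vol)
  stopifnot(all(d > 2 * n))
  vol[(n + 1):(d[1] - n), (n + 1):(d[2] - n), (n + 1):(d[3] - n),
      drop = FALSE]
}
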