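#' Fast radial symmetry transform of one image
#'
#' Gradient-based blob detector: every pixel with sufficient gradient
#' magnitude votes at the point a distance \code{n} along its gradient
#' direction.  Radially symmetric bright blobs of radius \code{n}
#' concentrate votes at their centers.  Per radius, an orientation image
#' (vote counts, capped at \code{kappa}) and a magnitude image (summed
#' gradient magnitudes) are combined as
#' \eqn{F_n = (\tilde O_n/\kappa)^{\alpha}\,\tilde M_n/\kappa} and smoothed
#' with a Gaussian of width proportional to the radius; the responses are
#' averaged over radii.  Being built from gradients, the response is
#' invariant to constant intensity offsets; a constant image yields a zero
#' response.
#'
#' Projected metal markers are *bright* in line-integral images (high
#' attenuation), so the default polarity votes along the positive gradient
#' direction only; \code{polarity = "dark"} inverts it.
#'
#' @param image Numeric matrix.
#' @param radii Integer vector of blob radii in pixels.
#' @param gradient_threshold Ignore pixels with gradient magnitude below
#'   this fraction of the maximum (default 0.05).
#' @param alpha Radial-strictness exponent (default 2).
#' @param kappa Vote normalization (default 8).
#' @param polarity `"bright"` or `"dark"` blobs.
#' @return Response matrix of the same size as the input.
#' @export
frst_response <- function(image, radii, gradient_threshold = 0.05,
                          alpha = 2, kappa = 8,
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  nr <- nrow(image); nc <- ncol(image)
  if (any(radii >= min(nr, nc) / 2))
    stop("radii must be smaller than half the image extent")
  # central-difference gradients (zero on the border)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  if (polarity == "dark") { gr <- -gr; gc <- -gc }
  mag <- sqrt(gr^2 + gc^2)
  thr <- gradient_threshold * max(mag)
  if (thr <= 0) return(matrix(0, nr, nc))
  sel <- which(mag > thr)
  if (!length(sel)) return(matrix(0, nr, nc))
  rr <- (sel - 1) %% nr + 1
  cc <- (sel - 1) %/% nr + 1
  ur <- gr[sel] / mag[sel]
  uc <- gc[sel] / mag[sel]
  S <- matrix(0, nr, nc)
  for (n in radii) {
    pr <- rr + round(n * ur)
    pc <- cc + round(n * uc)
    ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
    idx <- pr[ok] + (pc[ok] - 1) * nr
    O <- array(tabulate(idx, nbins = nr * nc), c(nr, nc))
    M <- matrix(0, nr, nc)
    acc <- rowsum(mag[sel][ok], idx)
    M[as.integer(rownames(acc))] <- acc
    O <- pmin(O, kappa)
    F_n <- (O / kappa)^alpha * (M / kappa)
    S <- S + gaussian_blur(F_n, sigma = max(0.5, n / 2))
  }
  S / length(radii)
}

# Gaussian blur with zero padding, same-size output
gaussian_blur <- function(M, sigma) {
  k <- gaussian_kernel_1d(sigma)
  rad <- (length(k) - 1) / 2
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 2 * rad, nc + 2 * rad)
  P[rad + seq_len(nr), rad + seq_len(nc)] <- M
  conv2_sep_valid(P, k)
}

# Otsu threshold of a numeric array (maximizes between-class variance)
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  lo + which.max(sigma_b) / n_bins * (hi - lo)
}
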