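#' Polychromatic X-ray spectrum model
#'
#' Filtered Kramers bremsstrahlung model: the photon weight in each energy
#' bin is proportional to \eqn{(kVp/E - 1)} attenuated by a fixed inherent
#' aluminum filtration, and the whole spectrum scales linearly with the
#' tube current-time product (mAs).  The unattenuated detected intensity
#' \code{I0} is the mAs-scaled sum of the bin weights; intensity units are
#' arbitrary but consistent across scans, which is all the saturation model
#' requires.
#'
#' @param kvp Peak kilovoltage (kV), > 10.
#' @param mas Tube current-time product (mAs), > 0.
#' @param n_bins Number of energy bins (default 30).
#' @param filtration_mm_al Inherent aluminum filtration in mm (default 2.5).
#' @return An object of class \code{xray_spectrum} with fields
#'   \code{energies} (keV bin centers), \code{weights} (mAs-scaled photon
#'   weights), \code{kvp}, \code{mas} and \code{I0 = sum(weights)}.
#' @examples
#' low <- xray_spectrum(60, 0.21)
#' high <- xray_spectrum(120, 2.5)
#' low$I0 / high$I0   # << 1
#' @export
xray_spectrum <- function(kvp, mas, n_bins = 30, filtration_mm_al = 2.5) {
  stopifnot(kvp > 10, mas > 0, n_bins >= 1)
  emax <- min(kvp, 150)
  energies <- seq(10, emax, length.out = n_bins + 1)
  energies <- (energies[-1] + energies[-length(energies)]) / 2  # bin centers
  w <- pmax(kvp / energies - 1, 0) *
    exp(-material_attenuation("aluminum", energies) * filtration_mm_al)
  w <- w * mas
  structure(list(energies = energies, weights = w,
                 kvp = kvp, mas = mas, I0 = sum(w)),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("X-ray spectrum: %g kVp, %g mAs, %d bins, I0 = %.4g\n",
              x$kvp, x$mas, length(x$energies), x$I0))
  invisible(x)
}

#' Maximum measurable detector intensity
#'
#' The saturation threshold is a convex mix of the unattenuated intensities
#' of the low- and high-dose spectra,
#' \deqn{I_{max} = (1 - t)\, I_{0,low} + t\, I_{0,high},}
#' so that the high-dose scan saturates in weakly attenuated regions while
#' the low-dose scan never does.
#'
#' @param I0_low,I0_high Unattenuated detected intensities, > 0.
#' @param t Mixing factor in `[0, 1]` (default 0.2).
#' @return The maximum measurable intensity.
#' @examples
#' compute_imax(1000, 10000, 0.2)  # 2800
#' @export
compute_imax <- function(I0_low, I0_high, t = 0.2) {
  stopifnot(I0_low > 0, I0_high > 0)
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  (1 - t) * I0_low + t * I0_high
}

#' Detector saturation and quantization model
#'
#' Bundles the saturation threshold [compute_imax()] with the detector bit
#' depth: intensities are clipped at \code{I_max} and quantized to bins of
#' width \code{I_max / 2^bit_depth}.  Reference (higher-dynamic-range) scans
#' skip the clipping but keep the same bin width so that results stay
#' comparable.
#'
#' @param I0_low,I0_high Unattenuated intensities of the two spectra.
#' @param t Mixing factor (default 0.2).
#' @param bit_depth Detector dynamic range in bits (default 14).
#' @return An object of class \code{saturation_model}.
#' @export
saturation_model <- function(I0_low, I0_high, t = 0.2, bit_depth = 14) {
  imax <- compute_imax(I0_low, I0_high, t)
  structure(list(t = t, I_max = imax, bit_depth = as.integer(bit_depth),
                 bin_width = imax / 2^bit_depth),
            class = "saturation_model")
}

#' @export
print.saturation_model <- function(x, ...) {
  cat(sprintf(
    "Saturation model: t = %g, I_max = %.4g, %d-bit (bin width %.4g)\n",
    x$t, x$I_max, x$bit_depth, x$bin_width))
  invisible(x)
}
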