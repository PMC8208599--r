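#' Simulate a polychromatic cone-beam scan of a phantom
#'
#' Casts one ray bundle per detector pixel through the analytic phantom and
#' accumulates the polychromatic detected intensity
#' \deqn{I = \sum_E w(E) \exp(-\sum_m \mu_m(E) L_m)}
#' from the exact per-material intersection lengths \eqn{L_m}.  With a
#' [saturation_model()] and \code{clip = TRUE}, intensities above
#' \code{I_max} are clipped before quantization (detector overexposure);
#' reference scans use \code{clip = FALSE} to emulate a higher-dynamic-range
#' detector while keeping the same quantization bin width.  Intensities are
#' quantized by flooring to bins of width \code{I_max / 2^bit_depth};
#' intensities that quantize to zero (photon starvation) are floored to one
#' bin and flagged.  The stored projections are line integrals
#' \eqn{-\ln(I/I_0)}.
#'
#' The simulation is noise-free and fully deterministic; optional Poisson
#' noise on the detected photon intensities can be enabled for robustness
#' experiments.
#'
#' @param phantom A [knee_phantom()].
#' @param geometry A [cone_beam_geometry()].
#' @param spectrum An [xray_spectrum()].
#' @param saturation Optional [saturation_model()]; NULL disables clipping
#'   and quantization entirely.
#' @param clip Apply the `I_max` clipping (default TRUE when a saturation
#'   model is given).  Reference scans set this to FALSE.
#' @param supersample Sub-rays per pixel edge (default 2, i.e. a 2 x 2
#'   bundle averaged per pixel) so that structures smaller than a detector
#'   pixel, such as 1 mm markers, remain visible.
#' @param poisson_noise Add Poisson noise to the detected intensities
#'   (default FALSE; uses the session RNG — set a seed for reproducibility).
#' @return An object of class \code{sim_scan}: list with \code{stack}
#'   ([projection_stack()] of line integrals), \code{intensity} (raw
#'   intensities before clipping), logical arrays \code{clipped} (raw
#'   intensity above `I_max`) and \code{starved} (quantized to zero), and
#'   the inputs.
#' @export
simulate_scan <- function(phantom, geometry, spectrum, saturation = NULL,
                          clip = !is.null(saturation), supersample = 2,
                          poisson_noise = FALSE) {
  stopifnot(inherits(phantom, "knee_phantom"),
            inherits(spectrum, "xray_spectrum"))
  if (clip && is.null(saturation))
    stop("clipping requires a saturation model")
  enc <- encode_phantom(phantom)
  mu <- vapply(enc$materials, material_attenuation,
               numeric(length(spectrum$energies)),
               energy = spectrum$energies)
  mu <- matrix(mu, nrow = length(spectrum$energies))
  I <- cpp_simulate_stack(enc$prims, enc$mat, enc$prio,
                          length(enc$materials), mu, spectrum$weights,
                          view_angles(geometry),
                          geometry$source_isocenter_distance,
                          geometry$source_detector_distance,
                          geometry$detector_rows, geometry$detector_cols,
                          geometry$pixel_spacing,
                          geometry$detector_offset[1],
                          geometry$detector_offset[2],
                          as.integer(supersample))
  if (poisson_noise) {
    dm <- dim(I)
    I <- array(rpois(length(I), lambda = I), dim = dm)
  }
  clipped <- starved <- NULL
  Iq <- I
  if (!is.null(saturation)) {
    clipped <- I > saturation$I_max
    if (clip) Iq <- pmin(I, saturation$I_max)
    bins <- floor(Iq / saturation$bin_width)
    starved <- bins < 1
    bins[starved] <- 1
    Iq <- bins * saturation$bin_width
    dim(clipped) <- dim(starved) <- dim(I)
  }
  li <- -log(Iq / spectrum$I0)
  dim(li) <- dim(I)
  structure(list(stack = projection_stack(li, geometry),
                 intensity = I, clipped = clipped, starved = starved,
                 spectrum = spectrum, saturation = saturation, clip = clip),
            class = "sim_scan")
}

#' @export
print.sim_scan <- function(x, ...) {
  cat(sprintf("Simulated scan (%g kVp, %g mAs)%s\n", x$spectrum$kvp,
              x$spectrum$mas,
              if (x$clip) " with saturation clipping" else ""))
  if (!is.null(x$clipped))
    cat(sprintf("  clipped pixels: %.1f%%, starved: %.1f%%\n",
                100 * mean(x$clipped), 100 * mean(x$starved)))
  print(x$stack)
  invisible(x)
}

#' Scan presets
#'
#' Bundled acquisition conditions: `"paper"` is the full-scale setting
#' (640 x 480 detector at 0.616 mm, 248 views at 0.8 deg, SDD 1198 mm);
#' `"desk"` is the same physical setup with 4 x 4 detector binning
#' (160 x 120 at 2.464 mm, 62 views at 3.2 deg) and a 96^3 reconstruction
#' grid, small enough for routine runs on one CPU; `"micro"` halves the desk
#' resolution again for fast unit-style experiments.  The SID of 650 mm
#' places the lateral field-of-view edge inside the silhouette of the
#' default phantom for anterior-posterior-ish views (no overexposure there),
#' matching an automatic-exposure-controlled acquisition in which only the
#' lateral view range saturates.  The trajectory is centered on the
#' anterior-posterior direction (start angle `90 - span/2`), so the scan
#' starts and ends at lateral-ish views.
#'
#' @param name `"desk"`, `"paper"` or `"micro"`.
#' @param include_markers Passed to [knee_phantom()].
#' @return List with elements \code{geometry}, \code{grid}, \code{phantom},
#'   \code{kvp_low}, \code{mas_low}, \code{kvp_high}, \code{mas_high},
#'   \code{t}.
#' @export
scan_preset <- function(name = c("desk", "paper", "micro"),
                        include_markers = TRUE) {
  name <- match.arg(name)
  geom <- switch(name,
    paper = cone_beam_geometry(650, 1198, 480, 640, 0.616, 248,
                               start_angle = 90 - 248 * 0.8 / 2,
                               angular_increment = 0.8),
    desk = cone_beam_geometry(650, 1198, 120, 160, 2.464, 62,
                              start_angle = 90 - 62 * 3.2 / 2,
                              angular_increment = 3.2),
    micro = cone_beam_geometry(650, 1198, 48, 64, 6.16, 31,
                               start_angle = 90 - 31 * 6.4 / 2,
                               angular_increment = 6.4))
  grid <- switch(name,
    paper = volume_grid(c(256, 256, 224), c(0.83, 0.83, 0.6)),
    desk = volume_grid(c(96, 96, 96), c(2.2, 2.2, 1.4)),
    micro = volume_grid(c(48, 48, 32), c(4.4, 4.4, 2.8)))
  list(geometry = geom, grid = grid,
       phantom = knee_phantom(include_markers = include_markers),
       kvp_low = 60, mas_low = 0.21, kvp_high = 120, mas_high = 2.5,
       t = 0.2)
}

#' Simulate the reference / overexposed / low-dose scan triple
#'
#' Convenience wrapper producing the three scans of the saturation
#' correction experiment from one preset (or explicit phantom/geometry):
#' a clipped high-dose scan (the AEC stand-in), an unclipped reference scan
#' with the same spectrum and quantization bin width, and a low-dose scan.
#' All three share one [saturation_model()] built from the two spectra.
#'
#' @param preset A [scan_preset()] list (fields geometry, phantom, kvp/mas
#'   settings and t); the phantom may be overridden per scan for inter-scan
#'   motion experiments.
#' @param phantom_low Phantom for the low-dose scan (defaults to the
#'   preset's phantom; pass a moved phantom to emulate inter-scan motion).
#' @param supersample Passed to [simulate_scan()].
#' @return List with \code{reference}, \code{overexposed}, \code{lowdose}
#'   (class \code{sim_scan}) and the shared \code{saturation} model.
#' @export
simulate_scan_triple <- function(preset, phantom_low = preset$phantom,
                                 supersample = 2) {
  sp_low <- xray_spectrum(preset$kvp_low, preset$mas_low)
  sp_high <- xray_spectrum(preset$kvp_high, preset$mas_high)
  sat <- saturation_model(sp_low$I0, sp_high$I0, t = preset$t)
  list(
    reference = simulate_scan(preset$phantom, preset$geometry, sp_high,
                              saturation = sat, clip = FALSE,
                              supersample = supersample),
    overexposed = simulate_scan(preset$phantom, preset$geometry, sp_high,
                                saturation = sat, clip = TRUE,
                                supersample = supersample),
    lowdose = simulate_scan(phantom_low, preset$geometry, sp_low,
                            saturation = sat, clip = TRUE,
                            supersample = supersample),
    saturation = sat)
}

#' Default lateral correction view set
#'
#' The projection combination is only applied to the first and last
#' \code{n_lateral} views (the lateral view range where overexposure
#' occurs); at full scale 80 of 248 views per side, scaled proportionally
#' for smaller view counts.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param n_lateral Views per side, or NULL for the proportional default
#'   \code{round(num_views * 80 / 248)}.
#' @return Integer vector of view indices.
#' @export
correction_view_set <- function(geometry, n_lateral = NULL) {
  nv <- geometry$num_views
  if (is.null(n_lateral)) n_lateral <- round(nv * 80 / 248)
  n_lateral <- min(n_lateral, floor(nv / 2))
  c(seq_len(n_lateral), seq(nv - n_lateral + 1, nv))
}
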