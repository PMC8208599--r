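# Embedded linear attenuation data for the phantom materials.
#
# Mass attenuation coefficients (cm^2/g) at tabulated photon energies,
# approximate values taken from published photon cross-section tables
# (NIST XCOM / ICRU-44 tissue compositions), log-log interpolated in
# between.  The tantalum table carries two extra support points bracketing
# the K edge near 67.4 keV.  Densities in g/cm^3.

.mat_energies <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

.mat_tables <- list(
  air = list(density = 0.001205, mu_rho = c(
    5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662, 0.1541, 0.1356)),
  fat = list(density = 0.95, mu_rho = c(
    3.268, 1.083, 0.5577, 0.3062, 0.2396, 0.2123, 0.1974, 0.1805, 0.1694, 0.1536)),
  soft_tissue = list(density = 1.05, mu_rho = c(
    5.356, 1.693, 0.8205, 0.3783, 0.2685, 0.2262, 0.2048, 0.1823, 0.1693, 0.1492)),
  cortical_bone = list(density = 1.92, mu_rho = c(
    28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148, 0.2229, 0.1855, 0.1480)),
  bone_marrow = list(density = 0.98, mu_rho = c(
    3.535, 1.162, 0.5962, 0.3164, 0.2432, 0.2132, 0.1972, 0.1793, 0.1677, 0.1514)),
  water = list(density = 1.00, mu_rho = c(
    5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837, 0.1707, 0.1505)),
  aluminum = list(density = 2.699, mu_rho = c(
    26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704, 0.1378)),
  marker_metal = list(
    energies = c(10, 15, 20, 30, 40, 50, 60, 67, 68, 80, 100, 150),
    density = 16.654, mu_rho = c(
      100.5, 36.0, 17.0, 6.5, 3.18, 1.83, 1.18, 0.95, 4.50, 3.10, 1.94, 0.95))
)

#' Phantom material names
#'
#' @return Character vector of material labels known to
#'   [material_attenuation()].
#' @export
material_names <- function() names(.mat_tables)

#' Linear attenuation coefficient of a phantom material
#'
#' Log-log interpolation of an embedded per-material mass-attenuation table,
#' scaled by the material density, giving the linear attenuation coefficient
#' in 1/mm.  Tabulated energies span 10-150 keV.
#'
#' @param material One of [material_names()].
#' @param energy Photon energy (keV), vectorized; must lie within 10-150.
#' @return Numeric vector of attenuation coefficients (1/mm).
#' @examples
#' material_attenuation("cortical_bone", 50) > material_attenuation("fat", 50)
#' @export
material_attenuation <- function(material, energy) {
  tab <- .mat_tables[[material]]
  if (is.null(tab))
    stop("unknown material '", material, "'; see material_names()")
  if (any(energy < 10 | energy > 150))
    stop("energy out of tabulated range [10, 150] keV")
  en <- if (is.null(tab$energies)) .mat_energies else tab$energies
  mu_rho <- exp(approx(log(en), log(tab$mu_rho), xout = log(energy),
                       rule = 1)$y)
  mu_rho * tab$density / 10  # cm^2/g * g/cm^3 -> 1/cm -> 1/mm
}
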