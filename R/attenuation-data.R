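# Embedded photon mass-attenuation and electron stopping-power compilations.
#
# Mass attenuation coefficients (total, with coherent scattering) are
# transcribed from the standard NIST-style elemental/compound tables on a
# fixed energy grid; values are interpolated log-log between knots.  Filter
# materials are tabulated from 10 keV upward (all K-edges of Be, C, Al lie
# below 2 keV and Cu's at 8.98 keV, so the tabulated range is edge-free);
# water extends down to 1 keV because multiply-scattered photons inside the
# phantom soften well below the source band.

.att_env <- new.env(parent = emptyenv())

# energy grid (keV) shared by the filter materials
.e_filter <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 400,
               500, 600, 800, 1000)

# water: extended grid
.e_water <- c(1, 1.5, 2, 3, 4, 5, 6, 8, .e_filter)

.mu_rho <- list(
  water = list(
    energy_keV = .e_water,
    mu_rho = c(4078, 1376, 617.3, 192.9, 82.78, 42.58, 24.64, 10.37,
               5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
               0.1837, 0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.09687,
               0.08956, 0.07865, 0.07072),
    density = 1.000),
  Be = list(
    energy_keV = .e_filter,
    mu_rho = c(0.6466, 0.3070, 0.2251, 0.1792, 0.1640, 0.1554, 0.1493,
               0.1401, 0.1328, 0.1190, 0.1089, 0.09463, 0.08471, 0.07739,
               0.07155, 0.06286, 0.05652),
    density = 1.848),
  C = list(
    energy_keV = .e_filter,
    mu_rho = c(2.373, 0.8071, 0.4420, 0.2562, 0.2076, 0.1871, 0.1753,
               0.1610, 0.1514, 0.1347, 0.1229, 0.1066, 0.09546, 0.08715,
               0.08058, 0.07076, 0.06361),
    density = 1.700),
  Al = list(
    energy_keV = .e_filter,
    mu_rho = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778,
               0.2018, 0.1704, 0.1378, 0.1223, 0.1042, 0.09276, 0.08445,
               0.07802, 0.06841, 0.06146),
    density = 2.699),
  Cu = list(
    energy_keV = .e_filter,
    mu_rho = c(215.9, 74.05, 33.79, 10.92, 4.862, 2.613, 1.593, 0.763,
               0.4584, 0.2217, 0.1559, 0.1119, 0.09413, 0.08362, 0.07625,
               0.06605, 0.05901),
    density = 8.960)
)

# Electron collision stopping power in liquid water (MeV cm^2/g).
.estar_water <- list(
  energy_keV = c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60,
                 80, 100, 150, 200, 300, 400, 500, 600, 800, 1000),
  stopping = c(126.3, 96.05, 77.27, 56.12, 45.06, 37.93, 32.93, 26.32,
               22.56, 16.47, 13.17, 9.653, 7.781, 6.603, 5.797, 4.757,
               4.115, 3.238, 2.793, 2.355, 2.148, 2.034, 1.963, 1.886,
               1.849)
)

# Anchored power-law partition of the water total coefficient into
# photoelectric and coherent components (incoherent is the remainder).
# Anchors: photoelectric 4.944 cm^2/g at 10 keV and 2.763e-3 at 100 keV;
# coherent 0.25 at 10 keV and 5.53e-3 at 100 keV.
.water_pe_mu_rho <- function(energy_keV) {
  expo_lo <- log(4.944 / 2.763e-3) / log(10)   # 10 -> 100 keV
  ifelse(energy_keV <= 100,
         2.763e-3 * (100 / energy_keV)^expo_lo,
         2.763e-3 * (100 / energy_keV)^3.0)
}

.water_coh_mu_rho <- function(energy_keV) {
  expo <- log(0.25 / 5.53e-3) / log(10)
  5.53e-3 * (100 / energy_keV)^expo
}

#' Mass attenuation coefficient of an embedded material
#'
#' Log-log interpolation of the embedded compilation.  Supported materials
#' are `"water"`, `"Be"`, `"C"`, `"Al"`, `"Cu"`.
#'
#' @param material material symbol.
#' @param energy_keV photon energies in keV (vectorised).
#' @return mass attenuation coefficient(s) in cm^2/g.
#' @export
mu_over_rho <- function(material, energy_keV) {
  tab <- .mu_rho[[material]]
  if (is.null(tab)) {
    stop("unknown material '", material,
         "'; embedded attenuation data exist for: ",
         paste(names(.mu_rho), collapse = ", "), call. = FALSE)
  }
  rng <- range(tab$energy_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2])) {
    stop("energy outside tabulated range [", rng[1], ", ", rng[2],
         "] keV for ", material, call. = FALSE)
  }
  exp(stats::approx(log(tab$energy_keV), log(tab$mu_rho),
                    xout = log(energy_keV))$y)
}

#' Density of an embedded material (g/cm^3)
#' @param material material symbol.
#' @export
material_density <- function(material) {
  tab <- .mu_rho[[material]]
  if (is.null(tab)) stop("unknown material '", material, "'", call. = FALSE)
  tab$density
}

#' Linear attenuation coefficient of water
#'
#' @param energy_keV photon energies in keV.
#' @return linear attenuation coefficient(s) in 1/cm.
#' @export
water_mu <- function(energy_keV) {
  mu_over_rho("water", energy_keV) * .mu_rho$water$density
}

#' Partial interaction coefficients of water
#'
#' Splits the embedded total mass attenuation coefficient into
#' photoelectric, incoherent (Compton) and coherent (Rayleigh) components
#' using anchored power-law models for the photoelectric and coherent
#' parts; the incoherent part is the remainder, so the three always sum to
#' the tabulated total.
#'
#' @param energy_keV photon energies in keV.
#' @return data.frame with columns `energy_keV`, `pe`, `incoherent`,
#'   `coherent`, `total` (all cm^2/g).
#' @export
water_partial_mu_rho <- function(energy_keV) {
  tot <- mu_over_rho("water", energy_keV)
  pe <- pmin(.water_pe_mu_rho(energy_keV), tot)
  coh <- .water_coh_mu_rho(energy_keV)
  inc <- pmax(tot - pe - coh, 0)
  # renormalise tiny clamping residue so components sum to the total
  coh <- tot - pe - inc
  data.frame(energy_keV = energy_keV, pe = pe, incoherent = inc,
             coherent = coh, total = tot)
}

#' Electron collision stopping power in water
#'
#' @param energy_keV electron kinetic energies in keV (1--1000 keV).
#' @return stopping power in MeV cm^2/g, log-log interpolated.
#' @export
water_stopping_power <- function(energy_keV) {
  tab <- .estar_water
  rng <- range(tab$energy_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2])) {
    stop("electron energy outside tabulated range [", rng[1], ", ",
         rng[2], "] keV", call. = FALSE)
  }
  exp(stats::approx(log(tab$energy_keV), log(tab$stopping),
                    xout = log(energy_keV))$y)
}

#' CSDA range of an electron in water
#'
#' Continuous-slowing-down range obtained by integrating the reciprocal of
#' the embedded collision stopping power from the 1 keV transport cutoff up
#' to the given energy.  Electrons below the cutoff are treated as locally
#' absorbed, so the residual sub-cutoff range is not included.
#'
#' @param energy_keV electron kinetic energies in keV.
#' @return range in cm (water density 1 g/cm^3).
#' @export
csda_range_cm <- function(energy_keV) {
  grid <- .csda_grid()
  out <- numeric(length(energy_keV))
  below <- energy_keV <= 1
  out[!below] <- stats::approx(grid$loge, grid$range_cm,
                               xout = log(pmin(energy_keV[!below], 1000)))$y
  out
}

.csda_grid <- function() {
  if (!is.null(.att_env$csda)) return(.att_env$csda)
  loge <- seq(log(1), log(1000), length.out = 400)
  e <- exp(loge)
  inv_s <- 1e-3 / water_stopping_power(e)  # cm per keV at unit density
  # cumulative trapezoid in energy
  de <- diff(e)
  r <- c(0, cumsum(0.5 * (inv_s[-1] + inv_s[-length(e)]) * de))
  .att_env$csda <- list(loge = loge, range_cm = r)
  .att_env$csda
}
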