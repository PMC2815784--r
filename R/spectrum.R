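# Filtered wiggler-like photon spectrum: construction, filtration,
# calibration of the critical energy against a target median, and sampling.

.spec_env <- new.env(parent = emptyenv())

#' Construct an energy spectrum object
#'
#' @param energies_keV strictly increasing bin-center grid (keV).
#' @param weights relative fluence per bin; normalised to sum to one.
#' @param band two-element numeric, the nominal [min, max] band in keV.
#' @param edges_keV optional bin edges (length = nbins + 1); defaults to
#'   midpoints extended to the band limits.
#' @return object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies_keV, weights, band = range(energies_keV),
                            edges_keV = NULL) {
  stopifnot(length(energies_keV) == length(weights), all(weights >= 0))
  if (length(energies_keV) > 1 && any(diff(energies_keV) <= 0)) {
    stop("energies must be strictly increasing", call. = FALSE)
  }
  if (any(energies_keV < band[1] - 1e-9 | energies_keV > band[2] + 1e-9)) {
    stop("energies outside band", call. = FALSE)
  }
  s <- sum(weights)
  if (s <= 0) stop("spectrum has zero total weight", call. = FALSE)
  if (is.null(edges_keV)) {
    if (length(energies_keV) == 1) {
      edges_keV <- c(band[1], band[2])
    } else {
      mid <- (energies_keV[-1] + energies_keV[-length(energies_keV)]) / 2
      edges_keV <- c(band[1], mid, band[2])
    }
  }
  structure(list(energies_keV = energies_keV, weights = weights / s,
                 band = band, edges_keV = edges_keV),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("energy_spectrum: %d bins on [%g, %g] keV, median %.1f keV\n",
              length(x$energies_keV), x$band[1], x$band[2],
              median_energy(x)))
  invisible(x)
}

# universal synchrotron emission function y * int_y^Inf K_{5/3}(t) dt,
# evaluated by adaptive quadrature of the modified Bessel function
.sync_flux <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(0)
    if (yi > 60) return(0)  # exponentially negligible
    yi * stats::integrate(function(t) besselK(t, 5 / 3), lower = yi,
                          upper = Inf, rel.tol = 1e-8)$value
  }, numeric(1))
}

#' Build an unfiltered wiggler-like spectrum
#'
#' Models the raw emission with the universal synchrotron spectral shape
#' parameterised by a critical energy, truncated to the requested band
#' (energies outside the band carry zero weight rather than being tapered).
#'
#' @param critical_energy_keV critical energy of the emission model (> 0).
#' @param band photon energy band `c(min, max)` in keV, within [1, 1000].
#' @param n_bins number of bins (default 512).
#' @return an [energy_spectrum].
#' @export
build_raw_spectrum <- function(critical_energy_keV, band = c(50, 350),
                               n_bins = 512) {
  if (!is.finite(critical_energy_keV) || critical_energy_keV <= 0) {
    stop("critical energy must be positive", call. = FALSE)
  }
  if (length(band) != 2 || band[1] > band[2] || band[1] < 1 ||
      band[2] > 1000) {
    stop("band must lie within [1, 1000] keV with min <= max",
         call. = FALSE)
  }
  if (band[1] == band[2]) {  # degenerate single-line band
    return(energy_spectrum(band[1], 1, band))
  }
  edges <- seq(band[1], band[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- .sync_flux(centers / critical_energy_keV)
  if (sum(w) <= 0) stop("spectrum empty on requested band", call. = FALSE)
  energy_spectrum(centers, w, band, edges_keV = edges)
}

#' Filter stack constructor
#'
#' @param ... named thicknesses in mm, e.g. `filter_stack(Be = 0.5, Cu = 1)`;
#'   layer order follows argument order.
#' @return data.frame with columns `material`, `thickness_mm`.
#' @export
filter_stack <- function(...) {
  t <- c(...)
  if (length(t) && (is.null(names(t)) || any(names(t) == ""))) {
    stop("filter layers must be named by material symbol", call. = FALSE)
  }
  if (any(t <= 0)) stop("filter thicknesses must be positive", call. = FALSE)
  data.frame(material = names(t) %||% character(0),
             thickness_mm = unname(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The beamline filter stack used throughout
#'
#' Be 0.5 mm, C 1.5 mm, Al 1.5 mm, Cu 1.0 mm.
#' @export
default_filter_stack <- function() {
  filter_stack(Be = 0.5, C = 1.5, Al = 1.5, Cu = 1.0)
}

#' Attenuate a spectrum through a filter stack
#'
#' Each weight is multiplied by `exp(-sum_i mu_i(E) t_i)` and the spectrum
#' is renormalised.
#'
#' @param spectrum an [energy_spectrum].
#' @param stack a [filter_stack] data.frame (may have zero rows).
#' @return the filtered [energy_spectrum].
#' @export
apply_filtration <- function(spectrum, stack) {
  w <- spectrum$weights
  if (nrow(stack)) {
    unknown <- setdiff(stack$material, names(.mu_rho))
    if (length(unknown)) {
      stop("no embedded attenuation data for material(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(stack))) {
      m <- stack$material[i]
      mu <- mu_over_rho(m, spectrum$energies_keV) * material_density(m)
      w <- w * exp(-mu * stack$thickness_mm[i] / 10)
    }
  }
  energy_spectrum(spectrum$energies_keV, w, spectrum$band,
                  edges_keV = spectrum$edges_keV)
}

#' Median energy of a spectrum
#'
#' Linear interpolation of the cumulative weight across bin edges (each
#' bin's weight is spread uniformly over the bin), matching the sampler.
#'
#' @param spectrum an [energy_spectrum].
#' @return median energy in keV.
#' @export
median_energy <- function(spectrum) {
  if (length(spectrum$weights) == 1) return(spectrum$energies_keV)
  cw <- c(0, cumsum(spectrum$weights))
  stats::approx(cw, spectrum$edges_keV, xout = 0.5, ties = "ordered")$y
}

#' Calibrate the critical energy to a target filtered median
#'
#' Deterministic bisection on the critical energy so that the spectrum,
#' after filtration and band truncation, has the requested median energy.
#'
#' @param target_median_keV target median of the filtered spectrum (keV),
#'   strictly inside `band`.
#' @param stack filter stack applied before taking the median.
#' @param band photon band in keV.
#' @param n_bins spectral resolution.
#' @param bracket search bracket for the critical energy (keV).
#' @param tol_keV convergence tolerance on the median (default 0.05 keV).
#' @return the calibrated critical energy in keV.
#' @export
calibrate_median <- function(target_median_keV, stack = default_filter_stack(),
                             band = c(50, 350), n_bins = 512,
                             bracket = c(2, 400), tol_keV = 0.05) {
  if (target_median_keV <= band[1] || target_median_keV >= band[2]) {
    stop("target median must lie strictly inside the band", call. = FALSE)
  }
  med_at <- function(ec) {
    median_energy(apply_filtration(build_raw_spectrum(ec, band, n_bins),
                                   stack))
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- med_at(lo) - target_median_keV
  f_hi <- med_at(hi) - target_median_keV
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste0("target median %.1f keV unattainable in bracket ",
                        "[%g, %g] keV (medians %.2f and %.2f)"),
                 target_median_keV, lo, hi,
                 f_lo + target_median_keV, f_hi + target_median_keV),
         call. = FALSE)
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    f_mid <- med_at(mid) - target_median_keV
    if (abs(f_mid) < tol_keV || (hi - lo) < 1e-4) break
    if (f_lo * f_mid <= 0) hi <- mid else { lo <- mid; f_lo <- f_mid }
  }
  mid
}

#' The calibrated, filtered source spectrum
#'
#' Convenience wrapper: calibrates the critical energy so the filtered
#' 50--350 keV spectrum has a 107 keV median, then returns the filtered
#' spectrum.  The result is cached per session.
#'
#' @param n_bins spectral resolution.
#' @return the filtered [energy_spectrum].
#' @export
source_spectrum <- function(n_bins = 512) {
  key <- paste0("src", n_bins)
  if (!is.null(.spec_env[[key]])) return(.spec_env[[key]])
  ec <- calibrate_median(107, default_filter_stack(), c(50, 350), n_bins)
  sp <- apply_filtration(build_raw_spectrum(ec, c(50, 350), n_bins),
                         default_filter_stack())
  attr(sp, "critical_energy_keV") <- ec
  .spec_env[[key]] <- sp
  sp
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling: a bin is drawn with probability equal to its
#' weight and the energy is uniform within the bin.
#'
#' @param spectrum an [energy_spectrum].
#' @param n number of samples (0 returns `numeric(0)`).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of energies in keV.
#' @export
sample_energies <- function(spectrum, n, seed = NULL) {
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  cw <- c(0, cumsum(spectrum$weights))
  if (length(spectrum$weights) == 1) {
    return(rep(spectrum$energies_keV, n))
  }
  stats::approx(cw, spectrum$edges_keV, xout = u, ties = "ordered")$y
}

#' Write / read a spectrum as two-column TSV
#'
#' Format: `#`-prefixed header lines (band), then `energy_keV<TAB>weight`.
#' @param spectrum an [energy_spectrum].
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# band_keV\t%g\t%g", spectrum$band[1],
                       spectrum$band[2]),
               "# energy_keV\tweight"), con)
  utils::write.table(data.frame(spectrum$energies_keV, spectrum$weights),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  band_line <- hdr[grepl("band_keV", hdr)]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           sep = "\t")
  band <- if (length(band_line)) {
    as.numeric(strsplit(band_line[1], "\t")[[1]][2:3])
  } else range(tab[[1]])
  energy_spectrum(tab[[1]], tab[[2]], band)
}
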