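# Multi-port combination: interlaced (uniform-target) and intersecting
# (non-interlaced) composites, interlacement enhancement, target metrics.

#' Irradiation port specification
#'
#' Ports are modelled as laterally shifted copies of one array at the
#' common target depth (the equal-depth cross-firing idealisation); the
#' rotation angle is bookkeeping only.
#'
#' @param rotation_deg port rotation about the target vertical axis.
#' @param lateral_shift_um interlace offset of this port's array (>= 0).
#' @param entrance_dose_Gy in-beam entrance peak dose for this port (>= 0).
#' @param depth_to_target_cm distance from the entrance point to the target.
#' @return object of class `port_spec`.
#' @export
port_spec <- function(rotation_deg = 0, lateral_shift_um = 0,
                      entrance_dose_Gy = 200, depth_to_target_cm = 1) {
  stopifnot(entrance_dose_Gy >= 0, lateral_shift_um >= 0)
  structure(list(rotation_deg = rotation_deg,
                 lateral_shift_um = lateral_shift_um,
                 entrance_dose_Gy = entrance_dose_Gy,
                 depth_to_target_cm = depth_to_target_cm),
            class = "port_spec")
}

#' Interlace plan: an array delivered from several ports
#'
#' @param array an [array_spec].
#' @param ports list of [port_spec]; for canonical interlaced plans the
#'   shifts form an arithmetic sequence with step `spacing / n_ports`.
#' @param mode `"interlaced"` (shifted arrays tile the gaps in the target)
#'   or `"intersecting"` (co-registered arrays, spatial fractionation
#'   preserved).
#' @return object of class `interlace_plan`.
#' @export
interlace_plan <- function(array, ports,
                           mode = c("interlaced", "intersecting")) {
  mode <- match.arg(mode)
  stopifnot(inherits(array, "array_spec"), length(ports) >= 1,
            all(vapply(ports, inherits, logical(1), "port_spec")))
  structure(list(array = array, ports = ports, mode = mode),
            class = "interlace_plan")
}

#' Canonical interlace plan
#'
#' Port `p` (0-based) rotates by `p * 360 / n_ports / 2` degrees and shifts
#' by `p * spacing / n_ports`; with 4 ports and 200 um spacing this is the
#' 50 um incremental step.
#'
#' @param array an [array_spec].
#' @param n_ports number of ports.
#' @param entrance_dose_Gy entrance peak dose per port.
#' @param depth_to_target_cm common entrance-to-target distance.
#' @param mode plan mode.
#' @return an [interlace_plan].
#' @export
canonical_plan <- function(array, n_ports = 4, entrance_dose_Gy = 200,
                           depth_to_target_cm = 1, mode = "interlaced") {
  step <- array$spacing_um / n_ports
  ports <- lapply(seq_len(n_ports) - 1, function(p) {
    port_spec(rotation_deg = p * 45,
              lateral_shift_um = if (mode == "interlaced") p * step else 0,
              entrance_dose_Gy = entrance_dose_Gy,
              depth_to_target_cm = depth_to_target_cm)
  })
  interlace_plan(array, ports, mode)
}

#' Build the interlaced composite profile at the target depth
#'
#' Sums, over ports `p` and beams `k`, the single-beam profile shifted by
#' `k * spacing + shift_p`, each port weighted by its entrance dose.  The
#' port shifts are recentered on their mean so the composite stays centered
#' at 0.  All ports must share the same depth to target (the equal-depth
#' assumption of the cross-firing idealisation).
#'
#' @param profile single-beam [lateral_profile] at the target depth, in
#'   peak-dose units (entrance peak = 1).
#' @param plan an [interlace_plan] with `mode = "interlaced"`.
#' @return composite [lateral_profile] in Gy.
#' @export
build_interlaced_profile <- function(profile, plan) {
  if (plan$mode != "interlaced") {
    stop("plan mode must be 'interlaced'", call. = FALSE)
  }
  depths <- vapply(plan$ports, `[[`, numeric(1), "depth_to_target_cm")
  if (max(depths) - min(depths) > 1e-9) {
    stop(paste("unequal port depths are not supported: the cross-firing",
               "idealisation assumes one common target depth"),
         call. = FALSE)
  }
  shifts <- vapply(plan$ports, `[[`, numeric(1), "lateral_shift_um")
  shifts <- shifts - mean(shifts)
  doses <- vapply(plan$ports, `[[`, numeric(1), "entrance_dose_Gy")
  beam_offs <- beam_offsets_um(plan$array)
  n <- length(profile$dose)
  out <- numeric(n)
  for (p in seq_along(shifts)) {
    for (k in seq_along(beam_offs)) {
      off <- beam_offs[k] + shifts[p]
      if (abs(off - round(off)) > 1e-9) {
        stop("port/beam offsets must be whole micrometres", call. = FALSE)
      }
      sh <- as.integer(round(off))
      src <- seq_len(n) - sh
      ok <- src >= 1 & src <= n
      out[ok] <- out[ok] + doses[p] * profile$dose[src[ok]]
    }
  }
  res <- lateral_profile(profile$positions_um, out, profile$depth_mm)
  attr(res, "plan") <- plan
  res
}

#' Peak and valley doses of an intersecting (non-interlaced) delivery
#'
#' Co-registered arrays from every port: peaks add and valleys add, and the
#' spatial fractionation of a single array is preserved.
#'
#' @param plan an [interlace_plan] with `mode = "intersecting"`.
#' @param inbeam_dose_Gy per-port in-beam dose at the target depth (length
#'   1, recycled, or one per port).
#' @param valley_dose_Gy per-port valley dose at the target depth.
#' @return list with `peak_Gy` and `valley_Gy`.
#' @export
build_intersecting_peak <- function(plan, inbeam_dose_Gy,
                                    valley_dose_Gy = NULL) {
  if (plan$mode != "intersecting") {
    stop("plan mode must be 'intersecting'", call. = FALSE)
  }
  np <- length(plan$ports)
  inb <- rep_len(inbeam_dose_Gy, np)
  out <- list(peak_Gy = sum(inb))
  out$valley_Gy <- if (is.null(valley_dose_Gy)) NA_real_ else
    sum(rep_len(valley_dose_Gy, np))
  out
}

#' Interlacement enhancement factor
#'
#' Fractional excess of the interlaced-target plateau dose over the in-beam
#' dose of a single array at the same depth: `plateau / in_beam - 1`.
#'
#' @param interlaced_plateau_dose plateau dose (any unit).
#' @param single_array_inbeam_dose single-array in-beam dose at the same
#'   depth, same normalisation.
#' @return the enhancement as a fraction; `NA` with attribute
#'   `undefined = TRUE` when the in-beam dose is zero.
#' @export
interlacement_enhancement <- function(interlaced_plateau_dose,
                                      single_array_inbeam_dose) {
  if (single_array_inbeam_dose == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  interlaced_plateau_dose / single_array_inbeam_dose - 1
}

#' Target-region report for an interlaced composite
#'
#' The plateau is the contiguous central region where the dose stays at or
#' above `threshold` times the central dose.  Reports the plateau mean,
#' width, dose heterogeneity `(max - min) / mean` inside the plateau, and,
#' if a single-array in-beam dose is supplied, the interlacement
#' enhancement factor.
#'
#' @param composite interlaced composite [lateral_profile].
#' @param plan the [interlace_plan] used to build it.
#' @param single_array_inbeam optional single-array in-beam dose at the
#'   same depth and normalisation.
#' @param threshold plateau flatness threshold (default 0.90).
#' @return list with `plateau_mean`, `width_mm`, `heterogeneity`,
#'   `int_ef`, `degenerate` (TRUE when no plateau wider than one interlace
#'   step exists).
#' @export
target_report <- function(composite, plan, single_array_inbeam = NULL,
                          threshold = 0.9) {
  center <- window_mean(composite, 0, 5)
  ok <- composite$dose >= threshold * center
  icenter <- which.min(abs(composite$positions_um))
  # contiguous run around the center
  lo <- icenter
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- icenter
  while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  if (!ok[icenter]) { lo <- icenter; hi <- icenter }
  region <- composite$dose[lo:hi]
  width_um <- hi - lo + 1
  step <- plan$array$spacing_um / length(plan$ports)
  degenerate <- width_um < 2 * step
  list(plateau_mean = mean(region),
       width_mm = width_um / 1000,
       heterogeneity = (max(region) - min(region)) / mean(region),
       int_ef = if (is.null(single_array_inbeam)) NA_real_ else
         interlacement_enhancement(mean(region), single_array_inbeam),
       degenerate = degenerate)
}

#' Write / read an interlace plan as JSON
#' @param plan an [interlace_plan].
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(array = unclass(plan$array),
                            ports = lapply(plan$ports, unclass),
                            mode = plan$mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  interlace_plan(
    array_spec(x$array$n_beams, x$array$spacing_um, x$array$width_um),
    lapply(x$ports, function(p) {
      port_spec(p$rotation_deg, p$lateral_shift_um, p$entrance_dose_Gy,
                p$depth_to_target_cm)
    }),
    x$mode)
}
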