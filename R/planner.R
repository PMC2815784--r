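# Entrance-dose back-planning: from a prescribed target dose and the
# interlacement enhancement, PVDR and depth-attenuation of a configuration,
# compute the required in-beam, entrance-peak and valley doses.

#' Planner input for one irradiation configuration
#'
#' @param target_dose_Gy prescribed homogeneous dose in the interlaced
#'   region at the target depth.
#' @param int_ef interlacement enhancement factor (fraction, >= 0).
#' @param pvdr_depth PVDR of a single array at the target depth.
#' @param pvdr_entrance PVDR of a single array at the entrance.
#' @param attenuation_factor in-beam peak dose at depth divided by the
#'   entrance peak dose (0 < a <= 1).
#' @param field label of the irradiation field (e.g. `"2x2 mm2"`).
#' @param spacing_um,n_ports geometry bookkeeping.
#' @return object of class `planner_input`.
#' @export
planner_input <- function(target_dose_Gy, int_ef, pvdr_depth,
                          pvdr_entrance, attenuation_factor,
                          field = "", spacing_um = NA, n_ports = NA) {
  stopifnot(target_dose_Gy > 0, int_ef >= 0, pvdr_depth > 0,
            pvdr_entrance > 0, attenuation_factor > 0,
            attenuation_factor <= 1)
  structure(list(target_dose_Gy = target_dose_Gy, int_ef = int_ef,
                 pvdr_depth = pvdr_depth, pvdr_entrance = pvdr_entrance,
                 attenuation_factor = attenuation_factor, field = field,
                 spacing_um = spacing_um, n_ports = n_ports),
            class = "planner_input")
}

#' Required single-array in-beam dose at the target depth
#'
#' The interlaced plateau receives `(1 + int_ef)` times the single-array
#' in-beam dose, so delivering `target_dose` requires
#' `target_dose / (1 + int_ef)` in-beam.  In `"table"` rounding mode the
#' result is rounded to integer Gy (the convention used downstream of the
#' printed planning table); `"exact"` keeps full precision.
#'
#' @param target_dose_Gy prescribed target dose.
#' @param int_ef interlacement enhancement factor (fraction >= 0).
#' @param rounding `"table"` or `"exact"`.
#' @return in-beam dose in Gy.
#' @export
required_inbeam_dose <- function(target_dose_Gy, int_ef,
                                 rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(int_ef >= 0)
  d <- target_dose_Gy / (1 + int_ef)
  if (rounding == "table") round(d) else d
}

#' Valley dose from an in-beam dose and a PVDR
#'
#' @param inbeam_dose_Gy in-beam dose.
#' @param pvdr peak-to-valley dose ratio (> 0).
#' @return valley dose in Gy.
#' @export
valley_dose <- function(inbeam_dose_Gy, pvdr) {
  if (any(pvdr <= 0)) stop("PVDR must be positive", call. = FALSE)
  inbeam_dose_Gy / pvdr
}

#' Entrance peak dose from an in-beam dose at depth
#'
#' @param inbeam_dose_Gy in-beam dose at the target depth.
#' @param attenuation_factor depth attenuation factor (0 < a <= 1).
#' @return entrance peak dose in Gy.
#' @export
entrance_peak_dose <- function(inbeam_dose_Gy, attenuation_factor) {
  stopifnot(all(attenuation_factor > 0), all(attenuation_factor <= 1))
  inbeam_dose_Gy / attenuation_factor
}

#' Plan one irradiation configuration
#'
#' Chains [required_inbeam_dose()], [valley_dose()] and
#' [entrance_peak_dose()] into one planning row.
#'
#' @param input a [planner_input].
#' @param rounding `"table"` (in-beam dose rounded to integer Gy before the
#'   valley computation) or `"exact"`.
#' @return object of class `planner_result`: `inbeam_dose_Gy`,
#'   `valley_dose_at_depth_Gy`, `entrance_peak_dose_Gy`,
#'   `valley_dose_at_entrance_Gy`, `rounding_mode` and the input.
#' @export
plan_configuration <- function(input, rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  inb <- required_inbeam_dose(input$target_dose_Gy, input$int_ef, rounding)
  ent <- entrance_peak_dose(inb, input$attenuation_factor)
  structure(list(
    inbeam_dose_Gy = inb,
    valley_dose_at_depth_Gy = valley_dose(inb, input$pvdr_depth),
    entrance_peak_dose_Gy = ent,
    valley_dose_at_entrance_Gy = valley_dose(ent, input$pvdr_entrance),
    rounding_mode = rounding,
    input = input), class = "planner_result")
}

#' @export
print.planner_result <- function(x, ...) {
  cat(sprintf(paste0("planner_result [%s, %s mode]: in-beam %.4g Gy, ",
                     "valley %.3g Gy, entrance %.4g Gy, entrance valley ",
                     "%.3g Gy\n"),
              x$input$field, x$rounding_mode, x$inbeam_dose_Gy,
              x$valley_dose_at_depth_Gy, x$entrance_peak_dose_Gy,
              x$valley_dose_at_entrance_Gy))
  invisible(x)
}

#' Depth attenuation factor from a dose grid
#'
#' In-beam peak dose at the requested depth divided by the in-beam peak
#' dose at the entrance bin.  If an [array_spec] is supplied, the ratio is
#' taken between the centermost composite peaks of the array built at both
#' depths (scattered contributions from neighbouring beams included).
#'
#' @param grid a `dose_grid`.
#' @param depth_cm target depth in cm (inside the phantom).
#' @param array optional [array_spec] for a composite-peak ratio.
#' @return the attenuation factor (<= 1 + buildup).
#' @export
depth_attenuation_factor <- function(grid, depth_cm, array = NULL) {
  zmax_cm <- grid$z_edges_mm[length(grid$z_edges_mm)] / 10
  if (depth_cm < 0 || depth_cm > zmax_cm) {
    stop("depth beyond phantom", call. = FALSE)
  }
  entrance_mm <- (grid$z_edges_mm[1] + grid$z_edges_mm[2]) / 2
  if (is.null(array)) {
    p0 <- extract_profile(grid, entrance_mm)
    p1 <- extract_profile(grid, depth_cm * 10)
    window_mean(p1, 0, 5) / window_mean(p0, 0, 5)
  } else {
    c0 <- superpose_array(extract_profile(grid, entrance_mm), array)
    c1 <- superpose_array(extract_profile(grid, depth_cm * 10), array)
    compute_pvdr(c1, array)$peak / compute_pvdr(c0, array)$peak
  }
}
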