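# End-to-end study drivers: spectrum -> single-beam MC -> composition ->
# interlacing -> metrics, for the rat and human phantom geometries.

#' Rat-head dosimetry study
#'
#' Simulates a single 50-um microbeam in the 1.5 cm-radius water cylinder
#' with the calibrated spectrum, extracts the profile at the 1 cm target
#' depth, builds the 10-beam/200-um single-array composite and the 4-port
#' interlaced composite (200 Gy entrance per port, 50 um step), and
#' evaluates the in-beam dose, PVDR, valley dose, interlaced plateau and
#' the intersecting-control doses.
#'
#' @param n_histories photon histories for the single-beam simulation.
#' @param seed integer seed.
#' @param entrance_dose_Gy entrance peak dose per port.
#' @param grid optional precomputed single-beam `dose_grid` (skips the
#'   simulation).
#' @return list with the dose grid, profiles and a `metrics` list.
#' @export
rat_study <- function(n_histories = 2e6, seed = 1, entrance_dose_Gy = 200,
                      grid = NULL) {
  sp <- source_spectrum()
  if (is.null(grid)) {
    grid <- simulate_single_microbeam(
      rat_phantom(), microbeam_spec(50, 2), sp,
      transport_config(n_histories = n_histories, seed = seed))
  }
  arr <- array_spec(n_beams = 10, spacing_um = 200, width_um = 50)
  prof <- extract_profile(grid, depth_mm = 10, symmetrize = TRUE)
  single <- superpose_array(prof, arr)
  pv <- compute_pvdr(single, arr)
  plan <- canonical_plan(arr, n_ports = 4,
                         entrance_dose_Gy = entrance_dose_Gy,
                         depth_to_target_cm = 1)
  inter <- build_interlaced_profile(prof, plan)
  rep <- target_report(inter, plan,
                       single_array_inbeam = pv$peak * entrance_dose_Gy)
  inbeam_Gy <- pv$peak * entrance_dose_Gy
  valley_Gy <- pv$valley * entrance_dose_Gy
  ctrl <- build_intersecting_peak(
    canonical_plan(arr, 4, entrance_dose_Gy, 1, mode = "intersecting"),
    inbeam_dose_Gy = inbeam_Gy, valley_dose_Gy = valley_Gy)
  list(grid = grid, profile_1cm = prof, single_array = single,
       interlaced = inter, plan = plan,
       metrics = list(
         inbeam_1cm_Gy = inbeam_Gy,
         valley_1cm_Gy = valley_Gy,
         pvdr_1cm = pv$pvdr,
         plateau_Gy = rep$plateau_mean,
         plateau_width_mm = rep$width_mm,
         heterogeneity = rep$heterogeneity,
         int_ef = rep$int_ef,
         control_peak_Gy = ctrl$peak_Gy,
         control_valley_Gy = ctrl$valley_Gy))
}

#' Human-sized head phantom study for one field size
#'
#' Simulates a single 50-um microbeam (beam height equal to the field
#' height) in the 8 cm-radius, 16 cm-tall water cylinder and evaluates, at
#' the 7.5 cm planning depth: the composite PVDR, the depth attenuation
#' factor of the composite peak, the interlaced plateau and enhancement
#' factor, and the edge penumbra of the interlaced and single-array
#' composites.
#'
#' @param field_width_mm lateral field size (2, 10 or 30 mm in the planning
#'   table); the beam count is `field_width_mm * 1000 / spacing_um`.
#' @param spacing_um center-to-center spacing (200 or 400 um).
#' @param n_ports ports for the interlaced delivery (4 at 200 um, 8 at
#'   400 um in the canonical plans).
#' @param n_histories,seed simulation controls.
#' @param depth_cm evaluation depth (default 7.5).
#' @param grid optional precomputed single-beam `dose_grid` for this field
#'   height.
#' @return list with the grid, composites and a `metrics` list.
#' @export
human_study <- function(field_width_mm = 2, spacing_um = 200,
                        n_ports = if (spacing_um == 200) 4 else 8,
                        n_histories = 2e6, seed = 1, depth_cm = 7.5,
                        grid = NULL) {
  sp <- source_spectrum()
  if (is.null(grid)) {
    grid <- simulate_single_microbeam(
      human_phantom(), microbeam_spec(50, field_width_mm), sp,
      transport_config(n_histories = n_histories, seed = seed))
  }
  n_beams <- round(field_width_mm * 1000 / spacing_um)
  arr <- array_spec(n_beams = n_beams, spacing_um = spacing_um,
                    width_um = 50)
  prof <- extract_profile(grid, depth_mm = depth_cm * 10,
                          symmetrize = TRUE)
  single <- superpose_array(prof, arr)
  pv <- compute_pvdr(single, arr)
  plan <- canonical_plan(arr, n_ports = n_ports, entrance_dose_Gy = 1,
                         depth_to_target_cm = depth_cm)
  inter <- build_interlaced_profile(prof, plan)
  rep <- target_report(inter, plan, single_array_inbeam = pv$peak)
  att <- depth_attenuation_factor(grid, depth_cm, array = arr)
  list(grid = grid, profile = prof, single_array = single,
       interlaced = inter, plan = plan,
       metrics = list(
         field_width_mm = field_width_mm, spacing_um = spacing_um,
         n_ports = n_ports, n_beams = n_beams,
         pvdr = pv$pvdr, peak = pv$peak, valley = pv$valley,
         attenuation = att,
         plateau = rep$plateau_mean, int_ef = rep$int_ef,
         plateau_width_mm = rep$width_mm,
         penumbra_interlaced_um = as.numeric(penumbra_90_10(inter)),
         penumbra_single_um = as.numeric(penumbra_90_10(single))))
}

#' Peak and valley depth-dose curves for an array
#'
#' Composite peak and valley (centermost definitions) of an array built
#' from the single-beam grid at every depth bin.
#'
#' @param grid a `dose_grid`.
#' @param array an [array_spec].
#' @param depths_mm depth bin midpoints to evaluate (default: every bin).
#' @return data.frame with `depth_mm`, `peak`, `valley`, `pvdr`.
#' @export
array_depth_dose <- function(grid, array, depths_mm = NULL) {
  if (is.null(depths_mm)) {
    z <- grid$z_edges_mm
    depths_mm <- (z[-1] + z[-length(z)]) / 2
  }
  rows <- lapply(depths_mm, function(d) {
    comp <- superpose_array(extract_profile(grid, d, symmetrize = TRUE),
                            array)
    pv <- compute_pvdr(comp, array)
    data.frame(depth_mm = d, peak = pv$peak, valley = pv$valley,
               pvdr = pv$pvdr)
  })
  do.call(rbind, rows)
}
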