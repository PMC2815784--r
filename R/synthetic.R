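# Synthetic fixtures: analytic single-beam kernels with closed-form array
# sums (exact oracles for superposition, PVDR and interlacing), the printed
# planning-table fixture, the rat dosimetry fixture, and film-like images.

#' Analytic single-beam kernel
#'
#' A top-hat core of width `core_width_um` convolved with a Gaussian of
#' standard deviation `core_sigma_um`, plus a two-sided exponential scatter
#' tail `tail_amp * exp(-|x| / tail_scale_um)`.  The kernel value, and
#' array peak/valley sums built from it, have closed forms, which makes the
#' family an exact oracle for the composition machinery.
#'
#' @param core_width_um top-hat core width (the beam width).
#' @param core_sigma_um Gaussian blur of the core edges (0 = sharp).
#' @param tail_amp tail amplitude as a fraction of the core height.
#' @param tail_scale_um exponential tail length scale.
#' @return object of class `analytic_kernel`.
#' @export
analytic_kernel <- function(core_width_um = 50, core_sigma_um = 0,
                            tail_amp = 0.02, tail_scale_um = 150) {
  stopifnot(core_width_um >= 0, core_sigma_um >= 0, tail_amp >= 0,
            tail_scale_um > 0)
  structure(list(core_width_um = core_width_um,
                 core_sigma_um = core_sigma_um, tail_amp = tail_amp,
                 tail_scale_um = tail_scale_um),
            class = "analytic_kernel")
}

#' Closed-form kernel value
#'
#' @param kernel an [analytic_kernel].
#' @param x_um positions in um (vectorised).
#' @return kernel values (core height 1 at the center for sharp cores).
#' @export
kernel_value <- function(kernel, x_um) {
  w2 <- kernel$core_width_um / 2
  core <- if (kernel$core_sigma_um == 0) {
    as.numeric(abs(x_um) <= w2)
  } else {
    s <- kernel$core_sigma_um
    stats::pnorm((x_um + w2) / s) - stats::pnorm((x_um - w2) / s)
  }
  core + kernel$tail_amp * exp(-abs(x_um) / kernel$tail_scale_um)
}

#' Render an analytic kernel as a lateral profile
#'
#' Evaluates the closed form at the 1-um cell centers (half-integer
#' positions) over `[-extent_um, extent_um]`.
#'
#' @param kernel an [analytic_kernel].
#' @param extent_um half-extent of the profile; must cover any array it
#'   will be superposed into.
#' @param depth_mm depth label for the profile.
#' @return a [lateral_profile].
#' @export
make_kernel <- function(kernel, extent_um = 5000, depth_mm = 10) {
  pos <- seq(-extent_um + 0.5, extent_um - 0.5, by = 1)
  lateral_profile(pos, kernel_value(kernel, pos), depth_mm)
}

#' Closed-form composite peak and valley of a kernel array
#'
#' Exact sums of the closed-form kernel over the beam offsets of an
#' `n`-beam array at center-to-center `spacing_um`, evaluated at the
#' centermost beam center (`peak`) and the centermost gap midpoint
#' (`valley`); the tail part telescopes to geometric series.
#'
#' @param kernel an [analytic_kernel].
#' @param n_beams,spacing_um array geometry.
#' @return list with `peak`, `valley`, `pvdr`.
#' @export
kernel_array_closed_form <- function(kernel, n_beams, spacing_um) {
  offs <- (seq_len(n_beams) - 1 - (n_beams - 1) / 2) * spacing_um
  peak_pos <- offs[order(abs(offs), offs)][1]
  mids <- (offs[-1] + offs[-length(offs)]) / 2
  valley_pos <- mids[order(abs(mids), mids)][1]
  peak <- sum(kernel_value(kernel, peak_pos - offs))
  valley <- sum(kernel_value(kernel, valley_pos - offs))
  list(peak = peak, valley = valley, pvdr = peak / valley)
}

#' Tail amplitude giving an exact target composite PVDR
#'
#' For a sharp-core kernel whose core does not reach neighbouring beams,
#' the composite peak is `1 + a * S_p` and the valley `a * S_v`, where
#' `S_p` and `S_v` are geometric tail sums over the beam offsets; solving
#' `PVDR = (1 + a S_p) / (a S_v)` for `a` gives the amplitude.
#'
#' @param target_pvdr desired composite PVDR.
#' @param n_beams,spacing_um array geometry.
#' @param core_width_um,tail_scale_um kernel shape (core must satisfy
#'   `core_width_um < spacing_um`).
#' @return an [analytic_kernel] whose `n_beams`/`spacing_um` composite has
#'   exactly the target PVDR (point definitions).
#' @export
kernel_for_pvdr <- function(target_pvdr, n_beams = 10, spacing_um = 200,
                            core_width_um = 50, tail_scale_um = 150) {
  stopifnot(core_width_um < spacing_um)
  offs <- (seq_len(n_beams) - 1 - (n_beams - 1) / 2) * spacing_um
  peak_pos <- offs[order(abs(offs), offs)][1]
  mids <- (offs[-1] + offs[-length(offs)]) / 2
  valley_pos <- mids[order(abs(mids), mids)][1]
  s_p <- sum(exp(-abs(peak_pos - offs) / tail_scale_um))
  s_v <- sum(exp(-abs(valley_pos - offs) / tail_scale_um))
  a <- 1 / (target_pvdr * s_v - s_p)
  stopifnot(a > 0)
  analytic_kernel(core_width_um, 0, a, tail_scale_um)
}

#' The printed human-phantom planning-table fixture
#'
#' Six configurations (three field sizes, two spacings/port counts) with
#' the published PVDRs at 7.5 cm and at the entrance, interlacement
#' enhancement factors, depth attenuation factors and the printed planned
#' doses.  Values carry their source quotes in the `"citation"` attribute.
#'
#' @return data.frame, one row per configuration.
#' @export
make_table1_fixture <- function() {
  fx <- data.frame(
    field = c("2x2 mm2", "2x2 mm2", "1x1 cm2", "1x1 cm2",
              "3x3 cm2", "3x3 cm2"),
    field_width_mm = c(2, 2, 10, 10, 30, 30),
    spacing_um = c(200, 400, 200, 400, 200, 400),
    n_ports = c(4L, 8L, 4L, 8L, 4L, 8L),
    pvdr_75 = c(51, 197.5, 19.7, 45.9, 7.9, 15.9),
    target_dose_Gy = 100,
    int_ef = c(0.14, 0.15, 0.22, 0.23, 0.43, 0.52),
    inbeam_printed_Gy = c(88, 87, 82, 81, 70, 66),
    valley_75_printed_Gy = c(1.73, 0.45, 4.16, 1.76, 8.7, 4.1),
    attenuation = c(0.30, 0.30, 0.30, 0.30, 0.32, 0.31),
    entrance_printed_Gy = c(297, 293, 273, 270, 216, 210),
    pvdr_entrance = c(71, 342, 38, 118, 22, 52),
    valley_entrance_printed_Gy = c(4.2, 0.9, 7.1, 2.3, 9.8, 4.0))
  attr(fx, "citation") <- paste(
    "Human-sized head phantom planning table: calculated PVDRs, peak and",
    "valley doses at 7.5 cm depth and at the entrance site for an",
    "arbitrary 100 Gy dose at the interlaced region, 50-um wide beams,",
    "200/400 um spacings, 4/8 ports.")
  fx
}

#' The rat dosimetry fixture
#'
#' Published values for the rat irradiation: 200 Gy entrance peak per port,
#' 175 Gy in-beam at 1 cm, 3.1 Gy valley (PVDR ~ 56), delivered as 4 ports
#' of 10 beams at 200 um spacing with a 50 um interlace step.
#'
#' @return named list with a `"citation"` attribute per value.
#' @export
make_rat_fixture <- function() {
  fx <- list(entrance_dose_Gy = 200, inbeam_1cm_Gy = 175,
             valley_1cm_Gy = 3.1, pvdr = 56,
             n_ports = 4L, n_beams = 10L, spacing_um = 200,
             shift_um = 50, width_um = 50, depth_cm = 1)
  attr(fx, "citation") <- c(
    entrance_dose_Gy = "the in-microbeam entrance dose was fixed at 200 Gy",
    inbeam_1cm_Gy = "in-beam dose at 1 cm depth of 175 Gy",
    valley_1cm_Gy = "valley dose in the surrounding tissues was 3.1 Gy",
    pvdr = "PVDR ~ 56")
  fx
}
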