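# Radiochromic-film emulation: render 2-D dose maps to film-like images,
# extract profiles back from (synthetic) films, and compare lateral
# falloffs against external reference profiles.

#' Render a dose map as a film-like image
#'
#' The dose map (1-um base resolution) is box-averaged onto square pixels
#' of `pitch_um`, mapped through a monotone dose-to-reading response, and
#' degraded with additive Gaussian noise.
#'
#' @param dose_map numeric matrix of dose on a 1-um grid (rows = vertical
#'   position, columns = lateral position).
#' @param pitch_um pixel pitch in um (>= 1, integer).
#' @param response monotone function mapping dose to film reading (default
#'   identity: dose-proportional optical density).
#' @param noise_sigma standard deviation of the additive readout noise, in
#'   response units.
#' @param seed integer seed for the noise.
#' @return object of class `film_image`: `pixels`, `pitch_um`, `response`
#'   and the response range.
#' @export
render_film <- function(dose_map, pitch_um = 5, response = identity,
                        noise_sigma = 0, seed = 1) {
  stopifnot(pitch_um >= 1)
  pitch_um <- as.integer(pitch_um)
  nr <- nrow(dose_map) %/% pitch_um
  nc <- ncol(dose_map) %/% pitch_um
  if (nr < 1 || nc < 1) stop("dose map smaller than one pixel",
                             call. = FALSE)
  m <- dose_map[seq_len(nr * pitch_um), seq_len(nc * pitch_um),
                drop = FALSE]
  # box average by block sums
  rowg <- (seq_len(nrow(m)) - 1) %/% pitch_um
  colg <- (seq_len(ncol(m)) - 1) %/% pitch_um
  px <- rowsum(t(rowsum(m, rowg)), colg) / pitch_um^2
  px <- t(px)
  px <- matrix(response(px), nrow = nr)
  if (noise_sigma > 0) {
    set.seed(seed)
    px <- px + matrix(stats::rnorm(length(px), 0, noise_sigma), nrow = nr)
  }
  structure(list(pixels = px, pitch_um = pitch_um, response = response,
                 dose_range = range(dose_map)), class = "film_image")
}

#' Extract a lateral profile from a film image
#'
#' Averages the pixel readings over the requested band of rows, inverts the
#' film response numerically, and resamples to the 1-um profile grid
#' (piecewise constant over pixels).  Pixels outside the invertible
#' response range are masked (set to `NA` before inversion) with a warning.
#'
#' @param image a `film_image`.
#' @param band_rows integer vector of row indices to average over.
#' @return a [lateral_profile] in dose units, centered on the image.
#' @export
profile_from_film <- function(image, band_rows = seq_len(nrow(image$pixels))) {
  stopifnot(all(band_rows >= 1), all(band_rows <= nrow(image$pixels)))
  reading <- colMeans(image$pixels[band_rows, , drop = FALSE])
  # numeric inversion of the monotone response on the rendered dose range
  dgrid <- seq(image$dose_range[1], image$dose_range[2],
               length.out = 2048)
  rgrid <- image$response(dgrid)
  lo <- min(rgrid); hi <- max(rgrid)
  sat <- reading < lo - 1e-9 | reading > hi + 1e-9
  if (any(sat)) {
    warning(sum(sat), " pixel column(s) outside the film response range",
            " were masked")
    reading[sat] <- NA
  }
  dose <- stats::approx(rgrid, dgrid, xout = pmin(pmax(reading, lo), hi),
                        ties = "ordered")$y
  dose[is.na(reading)] <- NA
  np <- length(dose)
  pitch <- image$pitch_um
  half <- np * pitch / 2
  pos <- seq(-half + 0.5, half - 0.5, by = 1)
  lateral_profile(pos, rep(dose, each = pitch))
}

#' Compare lateral falloff between two centered profiles
#'
#' Both profiles are normalised to their central dose; reports the 90-10%
#' edge falloff distance of each and the dose fraction remaining at the
#' stated lateral offsets.
#'
#' @param profile_a,profile_b centered [lateral_profile]s (e.g. an
#'   interlaced composite and an externally supplied reference profile).
#' @param offsets_mm lateral offsets at which to report the residual dose
#'   fraction (default 10 mm); must lie inside both profiles.
#' @return list with `falloff_a_um`, `falloff_b_um`, and a data.frame
#'   `fractions` (offset, fraction_a, fraction_b).
#' @export
falloff_comparison <- function(profile_a, profile_b, offsets_mm = 10) {
  norm <- function(p) {
    c0 <- window_mean(p, 0, 5)
    lateral_profile(p$positions_um, p$dose / c0, p$depth_mm)
  }
  a <- norm(profile_a); b <- norm(profile_b)
  frac_at <- function(p, off_um) {
    ext <- max(abs(p$positions_um))
    if (off_um > ext) stop("offset ", off_um / 1000,
                           " mm beyond profile extent", call. = FALSE)
    (window_mean(p, off_um, 10) + window_mean(p, -off_um, 10)) / 2
  }
  fr <- data.frame(
    offset_mm = offsets_mm,
    fraction_a = vapply(offsets_mm * 1000, frac_at, numeric(1), p = a),
    fraction_b = vapply(offsets_mm * 1000, frac_at, numeric(1), p = b))
  list(falloff_a_um = as.numeric(penumbra_90_10(a)),
       falloff_b_um = as.numeric(penumbra_90_10(b)),
       fractions = fr)
}

#' Film fixture: interlaced target band over single-array background
#'
#' Builds a 2-D dose map emulating a verification film: rows in the central
#' vertical band carry the interlaced composite profile, outer rows carry a
#' single-port array profile, then renders it with [render_film()].
#'
#' @param profile single-beam [lateral_profile] (peak-dose units).
#' @param plan an interlaced [interlace_plan].
#' @param height_um total image height; the interlaced band occupies the
#'   central third.
#' @param pitch_um,noise_sigma,seed rendering parameters.
#' @return a `film_image`; the dose map and band rows are attached as
#'   attributes `dose_map` and `band_rows`.
#' @export
make_film_fixture <- function(profile, plan, height_um = 900,
                              pitch_um = 5, noise_sigma = 0, seed = 1) {
  inter <- build_interlaced_profile(profile, plan)
  single <- superpose_array(profile, plan$array)
  dose1 <- single$dose * plan$ports[[1]]$entrance_dose_Gy
  band <- seq(floor(height_um / 3) + 1, floor(2 * height_um / 3))
  dm <- matrix(rep(dose1, each = height_um), nrow = height_um)
  dm[band, ] <- matrix(rep(inter$dose, each = length(band)),
                       nrow = length(band))
  img <- render_film(dm, pitch_um, identity, noise_sigma, seed)
  attr(img, "dose_map") <- dm
  attr(img, "band_rows") <- unique((band - 1) %/% pitch_um + 1)
  img
}

#' Write a film image as 16-bit TIFF
#'
#' Readings are scaled linearly onto [0, 1] (stored scale in a sidecar JSON
#' so the image can be converted back to dose units).
#'
#' @param image a `film_image`.
#' @param path output `.tiff` path.
#' @export
write_film_tiff <- function(image, path) {
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  scl <- if (hi > lo) (px - lo) / (hi - lo) else px * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 16)
  jsonlite::write_json(list(min = lo, max = hi,
                            pitch_um = image$pitch_um),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
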