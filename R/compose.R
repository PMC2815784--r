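# Lateral dose profiles, array superposition, PVDR and penumbra metrics.

#' Lateral dose profile on a uniform 1-um grid
#'
#' @param positions_um cell centers (uniform 1 um pitch; position 0 is the
#'   beam/array center, cells are centered on half-integers).
#' @param dose dose values (peak-dose units or Gy); `NA` marks masked
#'   cells (e.g. film pixels outside the invertible response range).
#' @param depth_mm depth label.
#' @param uncertainty optional relative statistical uncertainty per cell.
#' @return object of class `lateral_profile`.
#' @export
lateral_profile <- function(positions_um, dose, depth_mm = NA_real_,
                            uncertainty = NULL) {
  stopifnot(length(positions_um) == length(dose),
            all(dose >= -1e-12, na.rm = TRUE))
  if (length(positions_um) > 1) {
    d <- diff(positions_um)
    if (max(abs(d - 1)) > 1e-9) {
      stop("profile grid must be uniform with 1 um pitch", call. = FALSE)
    }
  }
  structure(list(positions_um = positions_um, dose = pmax(dose, 0),
                 depth_mm = depth_mm, uncertainty = uncertainty),
            class = "lateral_profile")
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf(paste0("lateral_profile at %.1f mm depth: [%g, %g] um, ",
                     "peak %.3g\n"), x$depth_mm, min(x$positions_um),
              max(x$positions_um), max(x$dose)))
  invisible(x)
}

#' Microbeam array specification
#'
#' @param n_beams number of microbeams (>= 1).
#' @param spacing_um center-to-center spacing (> beam width).
#' @param width_um beam width.
#' @return object of class `array_spec`.
#' @export
array_spec <- function(n_beams = 10, spacing_um = 200, width_um = 50) {
  stopifnot(n_beams >= 1, spacing_um > width_um, width_um > 0)
  structure(list(n_beams = as.integer(n_beams), spacing_um = spacing_um,
                 width_um = width_um), class = "array_spec")
}

#' Centered beam offsets of an array
#'
#' @param array an [array_spec].
#' @return numeric vector of beam-center offsets in micrometres, centered
#'   on zero (ties at even `n_beams` resolved symmetrically), ascending.
#' @export
beam_offsets_um <- function(array) {
  (seq_len(array$n_beams) - 1 - (array$n_beams - 1) / 2) * array$spacing_um
}

#' Extract a lateral profile from a dose grid
#'
#' Resamples the (generally non-uniform) transverse bins of the grid at the
#' requested depth onto a uniform 1-um grid by conservative piecewise-
#' constant interpolation: every 1-um cell takes the dose of the source bin
#' covering it, which preserves the integral dose exactly because the
#' source bin edges are whole micrometres.
#'
#' @param grid a `dose_grid`.
#' @param depth_mm depth of the profile; must lie inside the grid.
#' @param symmetrize average the profile with its mirror image (valid for
#'   the symmetric single-beam geometry; halves the variance).
#' @return a [lateral_profile] in peak-dose units.
#' @export
extract_profile <- function(grid, depth_mm, symmetrize = FALSE) {
  zmax <- grid$z_edges_mm[length(grid$z_edges_mm)]
  if (depth_mm < 0 || depth_mm > zmax) {
    stop("depth ", depth_mm, " mm outside phantom [0, ", zmax, "] mm",
         call. = FALSE)
  }
  iz <- min(max(1L, findInterval(depth_mm, grid$z_edges_mm,
                                 rightmost.closed = TRUE)),
            length(grid$z_edges_mm) - 1)
  edges <- grid$x_edges_um
  dose_bins <- grid$dose[, iz]
  unc_bins <- grid$rel_unc[, iz]
  lo <- edges[1]; hi <- edges[length(edges)]
  pos <- seq(lo + 0.5, hi - 0.5, by = 1)
  idx <- findInterval(pos, edges)
  dose <- dose_bins[idx]
  unc <- unc_bins[idx]
  if (symmetrize) {
    dose <- (dose + rev(dose)) / 2
    unc <- sqrt(unc^2 + rev(unc)^2) / 2
  }
  lateral_profile(pos, dose, depth_mm, unc)
}

# closest cell index to a position on the half-integer grid
.cell_index <- function(profile, x_um) {
  i <- round(x_um - profile$positions_um[1]) + 1
  if (any(i < 1 | i > length(profile$positions_um))) {
    stop("position outside profile extent", call. = FALSE)
  }
  as.integer(i)
}

#' Mean dose over a centered window of a lateral profile
#'
#' Averages the 1-um cells whose centers lie within
#' `center_um +/- halfwidth_um` (the windowed peak/valley estimator used by
#' [compute_pvdr()]).
#'
#' @param profile a [lateral_profile].
#' @param center_um window center in um.
#' @param halfwidth_um window half-width in um.
#' @return mean dose over the window.
#' @export
window_mean <- function(profile, center_um, halfwidth_um) {
  sel <- abs(profile$positions_um - center_um) <= halfwidth_um + 1e-9
  mean(profile$dose[sel])
}

#' Superpose a single-beam profile into an array composite
#'
#' Exact linear sum of integer-micron shifted copies of the profile, one
#' per beam, with no renormalisation:
#' `out(x) = sum_k profile(x - (k - (n-1)/2) * spacing)`.
#'
#' @param profile a [lateral_profile] of a single beam (position 0 at the
#'   beam center).
#' @param array an [array_spec]; all beam offsets must be whole
#'   micrometres.
#' @param margin_um required single-beam tail extent beyond the array
#'   half-width (default two spacings); an error names the required extent
#'   if the profile is too short.
#' @return composite [lateral_profile] on the same grid.
#' @export
superpose_array <- function(profile, array, margin_um = 2 * array$spacing_um) {
  offs <- beam_offsets_um(array)
  if (max(abs(offs - round(offs))) > 1e-9) {
    stop("beam offsets must be whole micrometres on the 1-um grid",
         call. = FALSE)
  }
  half_extent <- min(-profile$positions_um[1],
                     profile$positions_um[length(profile$positions_um)])
  need <- max(abs(offs)) + margin_um
  if (half_extent < need) {
    stop(sprintf(paste0("profile half-extent %.0f um insufficient for the ",
                        "array: at least %.0f um required"),
                 half_extent, need), call. = FALSE)
  }
  n <- length(profile$dose)
  out <- numeric(n)
  for (k in seq_along(offs)) {
    sh <- as.integer(round(offs[k]))
    src <- seq_len(n) - sh          # out[i] += profile[i - sh]
    ok <- src >= 1 & src <= n
    out[ok] <- out[ok] + profile$dose[src[ok]]
  }
  res <- lateral_profile(profile$positions_um, out, profile$depth_mm)
  attr(res, "array") <- array
  res
}

#' Peak-to-valley dose ratio of a composite profile
#'
#' The peak is the mean dose over the central 10 um at the centermost beam
#' center; the valley is the mean over the central 20 um of the centermost
#' gap between beams.  For even beam counts the centermost midpoint lies
#' between the two central beams; peak ties are resolved toward negative
#' positions.
#'
#' @param profile composite [lateral_profile].
#' @param array the [array_spec] used to build it (>= 2 beams).
#' @return list with `pvdr`, `peak`, `valley`, `peak_position_um`,
#'   `valley_position_um`, `undefined` (TRUE when the valley is zero).
#' @export
compute_pvdr <- function(profile, array) {
  stopifnot(array$n_beams >= 2)
  offs <- sort(beam_offsets_um(array))
  peak_pos <- offs[order(abs(offs), offs)][1]  # ties -> negative side
  mids <- (offs[-1] + offs[-length(offs)]) / 2
  valley_pos <- mids[order(abs(mids), mids)][1]
  peak <- window_mean(profile, peak_pos, 5)
  valley <- window_mean(profile, valley_pos, 10)
  undefined <- valley <= 0
  list(pvdr = if (undefined) Inf else peak / valley,
       peak = peak, valley = valley,
       peak_position_um = peak_pos, valley_position_um = valley_pos,
       undefined = undefined)
}

#' 90--10% lateral penumbra at an array edge
#'
#' After smoothing over `smooth_um`, locates the outermost peak on the
#' requested side, then the positions (linear interpolation between grid
#' points) where the dose first falls through 90% and 10% of that peak
#' value moving outward, and returns the distance between them.  If the
#' tail rises back above the 10% level further out, the first-crossing
#' convention is used and the result carries attribute
#' `non_monotone = TRUE`.
#'
#' @param profile a [lateral_profile].
#' @param side `"right"` or `"left"` array edge.
#' @param smooth_um moving-average window (default 3 um; 1 disables).
#' @return penumbra distance in um, with attributes `x90_um`, `x10_um`.
#' @export
penumbra_90_10 <- function(profile, side = c("right", "left"),
                           smooth_um = 3) {
  side <- match.arg(side)
  pos <- profile$positions_um
  d <- profile$dose
  if (side == "left") { pos <- rev(-pos); d <- rev(d) }
  if (smooth_um > 1) {
    k <- rep(1 / smooth_um, smooth_um)
    ds <- stats::filter(d, k, sides = 2)
    d[!is.na(ds)] <- ds[!is.na(ds)]
  }
  # outermost local maximum above half the global maximum
  ref_level <- 0.5 * max(d)
  n <- length(d)
  cand <- which(d >= ref_level)
  ipk <- max(cand)
  # walk back to the local maximum of the outermost lobe
  while (ipk > 1 && d[ipk - 1] >= d[ipk]) ipk <- ipk - 1
  while (ipk < n && d[ipk + 1] > d[ipk]) ipk <- ipk + 1
  ref <- d[ipk]
  cross_out <- function(level) {
    i <- ipk
    while (i < n && d[i + 1] > level) i <- i + 1
    if (i >= n) return(NA_real_)
    pos[i] + (d[i] - level) / (d[i] - d[i + 1])  # 1-um pitch
  }
  x90 <- cross_out(0.9 * ref)
  x10 <- cross_out(0.1 * ref)
  if (is.na(x90) || is.na(x10)) {
    stop("profile extent does not reach the 10% level", call. = FALSE)
  }
  res <- x10 - x90
  tail_idx <- which(pos > x10)
  attr(res, "x90_um") <- x90
  attr(res, "x10_um") <- x10
  attr(res, "non_monotone") <- length(tail_idx) > 0 &&
    any(d[tail_idx] > 0.1 * ref)
  res
}

#' Write / read a lateral profile as TSV
#'
#' Columns `position_um`, `dose`, `uncertainty`; `#` header lines carry the
#' depth label.
#' @param profile a [lateral_profile].
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# depth_mm\t%g", profile$depth_mm),
               "# position_um\tdose\tuncertainty"), con)
  unc <- profile$uncertainty %||% rep(NA_real_, length(profile$dose))
  utils::write.table(data.frame(profile$positions_um, profile$dose, unc),
                     con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  depth <- NA_real_
  dl <- hdr[grepl("depth_mm", hdr)]
  if (length(dl)) depth <- as.numeric(strsplit(dl[1], "\t")[[1]][2])
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           sep = "\t")
  unc <- if (ncol(tab) >= 3 && !all(is.na(tab[[3]]))) tab[[3]] else NULL
  lateral_profile(tab[[1]], tab[[2]], depth, unc)
}
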