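bruteforce_superpose <- function(profile, array) {
  offs <- beam_offsets_um(array)
  n <- length(profile$dose)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (k in seq_along(offs)) {
      j <- i - as.integer(round(offs[k]))
      if (j >= 1 && j <= n) s <- s + profile$dose[j]
    }
    s
  }, numeric(1))
}

test_that("profile extraction conserves the integral dose", {
  g <- small_grid()
  p <- extract_profile(g, 10)
  widths <- diff(g$x_edges_um)
  iz <- findInterval(10, g$z_edges_mm)
  expect_equal(sum(p$dose), sum(g$dose[, iz] * widths), tolerance = 1e-9)
  expect_equal(diff(p$positions_um), rep(1, length(p$dose) - 1))
})

test_that("symmetrized profiles are exactly even", {
  g <- small_grid()
  p <- extract_profile(g, 10, symmetrize = TRUE)
  expect_equal(p$dose, rev(p$dose))
})

test_that("superposition equals brute-force summation bit-for-bit on
           random analytic kernels", {
  set.seed(99)
  for (i in 1:5) {
    k <- analytic_kernel(core_width_um = sample(20:80, 1),
                         core_sigma_um = stats::runif(1, 0, 5),
                         tail_amp = stats::runif(1, 0.005, 0.05),
                         tail_scale_um = stats::runif(1, 50, 300))
    arr <- array_spec(n_beams = sample(2:12, 1),
                      spacing_um = sample(c(200, 400), 1))
    prof <- make_kernel(k, extent_um = 3500)
    comp <- superpose_array(prof, arr)
    expect_identical(comp$dose, bruteforce_superpose(prof, arr))
  }
})

test_that("analytic-kernel composite PVDR equals the closed form", {
  k <- analytic_kernel(50, 0, 0.02, 150)
  arr <- array_spec(10, 200, 50)
  comp <- superpose_array(make_kernel(k, 4000), arr)
  pv <- compute_pvdr(comp, arr)
  cf <- kernel_array_closed_form(k, 10, 200)
  # windowed estimates vs point closed form: within the window variation
  expect_lt(abs(pv$peak / cf$peak - 1), 1e-3)
  expect_lt(abs(pv$pvdr / cf$pvdr - 1), 5e-3)
})

test_that("kernel_for_pvdr yields a composite with PVDR exactly 50", {
  k <- kernel_for_pvdr(50, n_beams = 10, spacing_um = 200)
  cf <- kernel_array_closed_form(k, 10, 200)
  expect_equal(cf$pvdr, 50, tolerance = 1e-12)
  comp <- superpose_array(make_kernel(k, 4000), array_spec(10, 200, 50))
  pv <- compute_pvdr(comp, array_spec(10, 200, 50))
  expect_lt(abs(pv$pvdr / 50 - 1), 5e-3)     # grid/window error only
})

test_that("delta-like kernel gives an undefined PVDR", {
  prof <- make_kernel(analytic_kernel(50, 0, 0, 150), 2500)
  arr <- array_spec(4, 200, 50)
  pv <- compute_pvdr(superpose_array(prof, arr), arr)
  expect_true(pv$undefined)
  expect_identical(pv$pvdr, Inf)
})

test_that("insufficient profile extent raises an informative error", {
  prof <- make_kernel(analytic_kernel(), extent_um = 500)
  expect_error(superpose_array(prof, array_spec(10, 200, 50)),
               "at least")
})

test_that("PVDR decreases when the spacing shrinks (fixed kernel)", {
  k <- analytic_kernel(50, 0, 0.02, 150)
  pv200 <- kernel_array_closed_form(k, 10, 200)$pvdr
  pv400 <- kernel_array_closed_form(k, 5, 400)$pvdr
  expect_lt(pv200, pv400)
})

test_that("penumbra of a linear ramp over 100 um is 80 um", {
  pos <- seq(-499.5, 499.5, by = 1)
  dose <- pmin(1, pmax(0, (100 - pos) / 100))   # 1 until 0, ramp to 200
  prof <- lateral_profile(pos, dose)
  pen <- penumbra_90_10(prof, smooth_um = 1)
  expect_equal(as.numeric(pen), 80, tolerance = 0.5)
})

test_that("penumbra of a sharp step is at most the smoothing window", {
  pos <- seq(-299.5, 299.5, by = 1)
  dose <- as.numeric(pos < 50)
  prof <- lateral_profile(pos, dose)
  pen <- penumbra_90_10(prof, smooth_um = 1)
  expect_lt(as.numeric(pen), 1.01)
  expect_error(penumbra_90_10(lateral_profile(pos, rep(1, length(pos)))),
               "10% level")
})

test_that("window_mean averages the expected cells", {
  pos <- seq(-9.5, 9.5, by = 1)
  prof <- lateral_profile(pos, seq_along(pos))
  expect_equal(window_mean(prof, 0, 5), mean(6:15))
  expect_true(is.nan(window_mean(prof, 50, 5)))   # empty window
})

test_that("profile TSV round trip preserves content", {
  prof <- make_kernel(analytic_kernel(), 300, depth_mm = 10)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$positions_um, prof$positions_um)
  expect_equal(back$dose, prof$dose, tolerance = 1e-9)
  expect_equal(back$depth_mm, prof$depth_mm)
})
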