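test_that("raw spectrum is normalised, banded and shape-sane", {
  sp <- build_raw_spectrum(40, band = c(50, 350), n_bins = 256)
  expect_s3_class(sp, "energy_spectrum")
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
  expect_true(all(sp$energies_keV >= 50 & sp$energies_keV <= 350))
  expect_true(all(sp$weights >= 0))
  # wiggler spectrum decays towards high energy well above the critical
  # energy: last bin must carry less weight than the first
  expect_lt(sp$weights[length(sp$weights)], sp$weights[1])
})

test_that("degenerate one-bin band is supported", {
  sp <- build_raw_spectrum(40, band = c(100, 101), n_bins = 1)
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
  expect_equal(length(sp$energies_keV), 1)
  expect_equal(sample_energies(sp, 5), rep(sp$energies_keV, 5))
})

test_that("filtration matches the exponential attenuation oracle", {
  sp <- build_raw_spectrum(40, n_bins = 64)
  stack <- filter_stack(Cu = 2)
  filt <- apply_filtration(sp, stack)
  # per-bin survival must be exp(-mu * t) up to the common renormalisation
  mu <- mu_over_rho("Cu", sp$energies_keV) * material_density("Cu")
  expected <- sp$weights * exp(-mu * 0.2)
  expect_equal(filt$weights, expected / sum(expected), tolerance = 1e-12)
  expect_equal(sum(filt$weights), 1, tolerance = 1e-12)
})

test_that("filtration hardens the beam and preserves normalisation", {
  sp <- build_raw_spectrum(40, n_bins = 256)
  filt <- apply_filtration(sp, default_filter_stack())
  expect_gt(median_energy(filt), median_energy(sp))
  expect_equal(sum(filt$weights), 1, tolerance = 1e-12)
})

test_that("filter stack validates inputs", {
  expect_error(filter_stack(0.5), "named")
  expect_error(filter_stack(Be = -1), "positive")
  sp <- build_raw_spectrum(40, n_bins = 16)
  expect_error(apply_filtration(sp, filter_stack(Xx = 1)), "Xx")
})

test_that("median calibration hits the target and is monotone", {
  ec <- calibrate_median(107, default_filter_stack(), c(50, 350), 256)
  sp <- apply_filtration(build_raw_spectrum(ec, c(50, 350), 256),
                         default_filter_stack())
  expect_lt(abs(median_energy(sp) - 107), 0.5)
  # harder critical energy -> harder filtered spectrum
  med_at <- function(e) median_energy(apply_filtration(
    build_raw_spectrum(e, c(50, 350), 128), default_filter_stack()))
  expect_lt(med_at(20), med_at(60))
})

test_that("unattainable calibration targets error", {
  expect_error(calibrate_median(40), "inside the band")
  expect_error(calibrate_median(340, bracket = c(2, 5)), "unattainable")
})

test_that("calibrated source spectrum satisfies band and median", {
  sp <- source_spectrum()
  expect_true(all(sp$energies_keV >= 50 & sp$energies_keV <= 350))
  expect_lt(abs(median_energy(sp) - 107), 0.5)
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
  expect_true(is.finite(attr(sp, "critical_energy_keV")))
})

test_that("sampled energies follow the spectrum", {
  sp <- source_spectrum()
  e <- sample_energies(sp, 2e4, seed = 42)
  expect_true(all(e >= 50 & e <= 350))
  expect_lt(abs(stats::median(e) - 107), 2)
  expect_identical(sample_energies(sp, 100, seed = 1),
                   sample_energies(sp, 100, seed = 1))
  expect_identical(sample_energies(sp, 0), numeric(0))
})

test_that("spectrum TSV round trip preserves content", {
  sp <- source_spectrum()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$energies_keV, sp$energies_keV)
  expect_equal(back$weights, sp$weights, tolerance = 1e-12)
  expect_equal(back$band, sp$band)
})
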