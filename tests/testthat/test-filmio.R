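film_test_plan <- function() {
  canonical_plan(array_spec(4, 200, 50), n_ports = 4,
                 entrance_dose_Gy = 100)
}

test_that("noise-free film round trip recovers the profile within 1%", {
  prof <- make_kernel(analytic_kernel(50, 4, 0.03, 150), 1500)
  plan <- film_test_plan()
  img <- make_film_fixture(prof, plan, height_um = 300, pitch_um = 5,
                           noise_sigma = 0)
  band <- attr(img, "band_rows")
  rec <- profile_from_film(img, band)
  truth <- build_interlaced_profile(prof, plan)
  # truth at the film's own resolution: box average over the pixel pitch
  n <- length(truth$dose) %/% 5 * 5
  px_truth <- colMeans(matrix(truth$dose[seq_len(n)], nrow = 5))
  px_rec <- rec$dose[seq(3, by = 5, length.out = length(px_truth))]
  sel <- px_truth >= 0.05 * window_mean(truth, 0, 5)
  expect_lt(max(abs(px_rec[sel] / px_truth[sel] - 1)), 0.01)
})

test_that("film rendering with a fixed seed is deterministic", {
  prof <- make_kernel(analytic_kernel(), 1200)
  plan <- film_test_plan()
  a <- make_film_fixture(prof, plan, 150, 5, noise_sigma = 0.5, seed = 3)
  b <- make_film_fixture(prof, plan, 150, 5, noise_sigma = 0.5, seed = 3)
  d <- make_film_fixture(prof, plan, 150, 5, noise_sigma = 0.5, seed = 4)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, d$pixels))
})

test_that("nonlinear film response is inverted numerically", {
  prof <- make_kernel(analytic_kernel(50, 2, 0.03, 150), 1200)
  single <- superpose_array(prof, array_spec(4, 200, 50))
  # vertically uniform map: column means commute with the response
  dm <- matrix(rep(200 * single$dose, each = 50), nrow = 50)
  resp <- function(d) 1 - exp(-d / 150)        # saturating response
  img <- render_film(dm, 5, response = resp)
  rec <- profile_from_film(img)
  lin <- profile_from_film(render_film(dm, 5))
  sel <- lin$dose >= 0.1 * max(lin$dose)
  expect_lt(max(abs(rec$dose[sel] / lin$dose[sel] - 1)), 0.02)
})

test_that("readings outside the response range are masked with a warning", {
  prof <- make_kernel(analytic_kernel(), 1200)
  plan <- film_test_plan()
  dm <- attr(make_film_fixture(prof, plan, 150, 5), "dose_map")
  img <- render_film(dm, 5, noise_sigma = 50, seed = 2)
  expect_warning(rec <- profile_from_film(img), "masked")
  expect_true(any(is.na(rec$dose)))
})

test_that("film peaks sit 200 um apart within one pixel", {
  prof <- make_kernel(analytic_kernel(50, 2, 0.01, 120), 1200)
  arr <- array_spec(4, 200, 50)
  single <- superpose_array(prof, arr)
  dm <- matrix(rep(single$dose, each = 50), nrow = 50)
  img <- render_film(dm, 5)
  rec <- profile_from_film(img)
  d <- rec$dose
  thr <- 0.5 * max(d)
  above <- d >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centers <- (rec$positions_um[starts[runs$values]] +
              rec$positions_um[ends[runs$values]]) / 2
  expect_equal(length(centers), 4)
  expect_true(all(abs(diff(centers) - 200) <= img$pitch_um))
})

test_that("falloff comparison is invariant under profile rescaling", {
  prof <- make_kernel(analytic_kernel(50, 3, 0.02, 200), 12000)
  plan <- film_test_plan()
  comp <- build_interlaced_profile(prof, plan)
  scaled <- lateral_profile(comp$positions_um, 7.3 * comp$dose,
                            comp$depth_mm)
  fc <- falloff_comparison(comp, scaled, offsets_mm = 10)
  expect_equal(fc$falloff_a_um, fc$falloff_b_um, tolerance = 1e-9)
  expect_equal(fc$fractions$fraction_a, fc$fractions$fraction_b,
               tolerance = 1e-12)
  expect_error(falloff_comparison(comp, scaled, offsets_mm = 99),
               "extent")
})

test_that("interlaced central band reads hotter than the side bands", {
  prof <- make_kernel(analytic_kernel(50, 2, 0.02, 150), 1200)
  plan <- film_test_plan()
  img <- make_film_fixture(prof, plan, 300, 5)
  band <- attr(img, "band_rows")
  side <- setdiff(seq_len(nrow(img$pixels)), band)
  expect_gt(mean(profile_from_film(img, band)$dose, na.rm = TRUE),
            mean(profile_from_film(img, side)$dose, na.rm = TRUE))
})

test_that("film TIFF export writes the image and its scale sidecar", {
  prof <- make_kernel(analytic_kernel(), 1200)
  img <- make_film_fixture(prof, film_test_plan(), 150, 5)
  path <- tempfile(fileext = ".tiff")
  on.exit(unlink(paste0(path, c("", ".json"))))
  write_film_tiff(img, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$pitch_um, 5)
  back <- tiff::readTIFF(path)
  expect_equal(dim(back), dim(img$pixels))
  rescaled <- back * (meta$max - meta$min) + meta$min
  expect_equal(rescaled, img$pixels, tolerance = 1e-3)
})
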