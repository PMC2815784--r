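test_that("a one-port unit-dose interlaced plan reproduces superpose_array
           bit-for-bit", {
  prof <- make_kernel(analytic_kernel(50, 2, 0.02, 150), 3000)
  arr <- array_spec(10, 200, 50)
  plan <- interlace_plan(arr, list(port_spec(0, 0, 1, 1)), "interlaced")
  expect_identical(build_interlaced_profile(prof, plan)$dose,
                   superpose_array(prof, arr)$dose)
})

test_that("interlaced composite matches the 40-term closed-form sum", {
  k <- analytic_kernel(50, 3, 0.03, 120)
  prof <- make_kernel(k, 3000)
  arr <- array_spec(10, 200, 50)
  plan <- canonical_plan(arr, n_ports = 4, entrance_dose_Gy = 200)
  comp <- build_interlaced_profile(prof, plan)
  offs <- beam_offsets_um(arr)
  shifts <- (0:3) * 50 - mean((0:3) * 50)
  at <- c(-512.5, -100.5, 0.5, 37.5, 900.5)
  for (x in at) {
    expected <- sum(vapply(shifts, function(s) {
      200 * sum(kernel_value(k, x - offs - s))
    }, numeric(1)))
    expect_equal(comp$dose[match(x, comp$positions_um)], expected,
                 tolerance = 1e-12)
  }
})

test_that("perfectly tiling sharp beams give a flat plateau with zero
           enhancement", {
  prof <- make_kernel(analytic_kernel(50, 0, 0, 150), 3000)
  arr <- array_spec(10, 200, 50)
  plan <- canonical_plan(arr, n_ports = 4, entrance_dose_Gy = 100)
  comp <- build_interlaced_profile(prof, plan)
  rep <- target_report(comp, plan, single_array_inbeam = 100)
  expect_equal(rep$plateau_mean, 100, tolerance = 1e-12)
  expect_equal(rep$heterogeneity, 0, tolerance = 1e-12)
  expect_equal(rep$int_ef, 0, tolerance = 1e-12)
  expect_equal(rep$width_mm, 2.0, tolerance = 1e-9)
  expect_false(rep$degenerate)
})

test_that("composite and plateau scale linearly with the port dose; the
           enhancement does not", {
  prof <- make_kernel(analytic_kernel(50, 2, 0.02, 150), 3000)
  arr <- array_spec(10, 200, 50)
  p1 <- canonical_plan(arr, 4, entrance_dose_Gy = 100)
  p2 <- canonical_plan(arr, 4, entrance_dose_Gy = 200)
  c1 <- build_interlaced_profile(prof, p1)
  c2 <- build_interlaced_profile(prof, p2)
  expect_equal(c2$dose, 2 * c1$dose, tolerance = 1e-12)
  r1 <- target_report(c1, p1, single_array_inbeam = 100)
  r2 <- target_report(c2, p2, single_array_inbeam = 200)
  expect_equal(r1$int_ef, r2$int_ef, tolerance = 1e-12)
})

test_that("a single 50-um beam against a 200-um plan is degenerate", {
  prof <- make_kernel(analytic_kernel(50, 0, 0, 150), 2000)
  plan <- interlace_plan(array_spec(1, 200, 50),
                         list(port_spec(0, 0, 1, 1)), "interlaced")
  rep <- target_report(build_interlaced_profile(prof, plan), plan)
  expect_true(rep$degenerate)
  expect_true(is.na(rep$int_ef))
})

test_that("unequal port depths and fractional shifts are rejected", {
  prof <- make_kernel(analytic_kernel(), 2000)
  arr <- array_spec(4, 200, 50)
  bad_depth <- interlace_plan(arr, list(port_spec(0, 0, 1, 1),
                                        port_spec(90, 50, 1, 2)),
                              "interlaced")
  expect_error(build_interlaced_profile(prof, bad_depth), "depth")
  bad_shift <- interlace_plan(arr, list(port_spec(0, 0, 1, 1),
                                        port_spec(90, 50.5, 1, 1)),
                              "interlaced")
  expect_error(build_interlaced_profile(prof, bad_shift),
               "whole micrometres")
  inter <- canonical_plan(arr, 4, mode = "intersecting")
  expect_error(build_interlaced_profile(prof, inter), "interlaced")
  expect_error(build_intersecting_peak(canonical_plan(arr, 4), 175),
               "intersecting")
})

test_that("intersecting delivery adds peaks and valleys across ports", {
  plan <- canonical_plan(array_spec(10, 200, 50), 4,
                         mode = "intersecting")
  out <- build_intersecting_peak(plan, 175, 3.125)
  expect_equal(out$peak_Gy, 700)
  expect_equal(out$valley_Gy, 12.5)
  expect_true(is.na(build_intersecting_peak(plan, 175)$valley_Gy))
})

test_that("enhancement against a zero in-beam dose is flagged undefined", {
  x <- interlacement_enhancement(10, 0)
  expect_true(is.na(x))
  expect_true(attr(x, "undefined"))
  expect_equal(interlacement_enhancement(1.14, 1), 0.14, tolerance = 1e-12)
})

test_that("plan JSON round trip preserves geometry, doses and mode", {
  plan <- canonical_plan(array_spec(10, 200, 50), 4,
                         entrance_dose_Gy = 297, depth_to_target_cm = 7.5)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$array, plan$array)
  expect_equal(back$mode, plan$mode)
  expect_equal(lapply(back$ports, unclass), lapply(plan$ports, unclass))
})
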