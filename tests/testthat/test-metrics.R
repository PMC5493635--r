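test_that("diagonal and cross profiles extract the expected slices", {
  expect_equal(diagonal_profile(diag(3)), rep(1, 3))
  grid <- camera_grid(10, 100)
  C <- outer(1:10, 1:10)
  expect_equal(cross_profile(C, grid, -50), C[5, ])
  expect_error(cross_profile(C, grid, 9000), "outside")
  # C1 cross profile is proportional to the mean image (rank-1 structure)
  G <- build_system_matrix(emitter_pair(100), grid)
  cs <- compute_components(G)
  cp <- cross_profile(cs$C1, grid, -50)
  gt <- mean_image(G)
  expect_lt(max(abs(cp / cp[which.max(gt)] - gt / max(gt))), 1e-12)
})

test_that("between close emitters C2 and C3 diagonals nearly coincide", {
  grid <- ideal_grid(500, 1)
  cs <- compute_components(build_system_matrix(emitter_pair(100), grid))
  mid <- which.min(abs(grid$centers))
  d2 <- diagonal_profile(cs$C2); d3 <- diagonal_profile(cs$C3)
  expect_gt(d3[mid], 0)
  expect_lt(d2[mid] - d3[mid], 0.02 * d2[mid])
})

test_that("FWHM recovers the half-width of a triangle and is scale/grid stable", {
  x <- seq(-100, 100, by = 1)
  tri <- pmax(0, 1 - abs(x) / 40)
  expect_equal(profile_fwhm(tri, x), 40)
  expect_equal(profile_fwhm(250 * tri, x), 40)
  x2 <- seq(-100, 100, by = 2)
  expect_lt(abs(profile_fwhm(pmax(0, 1 - abs(x2) / 40), x2) - 40), 2)
  expect_error(profile_fwhm(rep(1, 5), 1:5), "half maximum")
})

test_that("minima-to-maxima ratio is 1 for unresolved and < 1 for resolved pairs", {
  x <- seq(-300, 300, by = 1)
  expect_equal(min_max_ratio(exp(-x^2 / 1e4), x), 1)
  two <- exp(-(x - 120)^2 / 5e3) + exp(-(x + 120)^2 / 5e3)
  expect_lt(min_max_ratio(two, x), 1)
})

test_that("diag(C2) resolves at 118 nm and the mean image at 172 nm", {
  thr2 <- resolution_threshold("C2", ideal_grid(600, 1))
  expect_lt(abs(thr2$threshold - 118), 4)
  thr1 <- resolution_threshold("meanimg", ideal_grid(600, 1))
  expect_lt(abs(thr1$threshold - 172), 4)
  # R is 1 below threshold and non-increasing over the scan for the mean image
  expect_true(all(thr1$R[thr1$delta_y < thr1$threshold] == 1))
  sel <- thr1$delta_y >= 100 & thr1$delta_y <= 250
  expect_true(all(diff(thr1$R[sel]) <= 1e-12))
})

test_that("FWHM ordering below the C2 threshold is C3 < C1 < C2 < mean image", {
  grid <- ideal_grid(600, 1)
  fc <- fwhm_curve(c(60, 100), c("meanimg", "C1", "C2", "C3"), grid)
  for (i in 1:2) {
    v <- fc$values[i, ]
    expect_lt(v["C3"], v["C1"])
    expect_lt(v["C1"], v["C2"])
    expect_lt(v["C2"], v["meanimg"])
  }
})

test_that("magnitudes agree in the unresolved regime and split beyond it", {
  ds <- seq(10, 400, by = 2)
  mc <- magnitude_curve(ds, c("C1", "C2", "C3", "C2minusC3"))
  v <- mc$values
  # C2 and C3 magnitudes coincide for a symmetric pair
  expect_lt(max(abs(v[, "C2"] - v[, "C3"])), 1e-9)
  # near-coincident emitters: fluctuation magnitude vanishes
  expect_lt(v[1, "C2minusC3"], 0.01)
  # in the deeply unresolved regime all three share the central magnitude
  sel <- ds <= 80
  expect_lt(max(abs(v[sel, "C1"] - v[sel, "C2"])), 1e-6)
  # beyond the Rayleigh limit C1 is clearly smaller
  expect_lt(v[ds == 400, "C1"], 0.26)
  expect_gt(v[ds == 400, "C2"], 0.49)
})

test_that("inflection detection recovers the analytic point of a cubic", {
  ds <- seq(10, 400, by = 2)
  expect_equal(inflection_point((ds - 100)^3, delta_y = ds, min_delta = 50),
               100, tolerance = 0.05)
})

test_that("magnitude curves inflect at 118 nm (C2/C3) and 172 nm (C1)", {
  ds <- seq(10, 400, by = 2)
  mc <- magnitude_curve(ds, c("C1", "C2", "C3"))
  expect_lt(abs(inflection_point(mc, matrix_id = "C2") - 118), 4)
  expect_lt(abs(inflection_point(mc, matrix_id = "C3") - 118), 4)
  expect_lt(abs(inflection_point(mc, matrix_id = "C1") - 172), 4)
})

test_that("the mean-image-to-fluctuation magnitude ratio is log-log linear", {
  ds <- seq(10, 150, by = 4)
  rc <- magnitude_ratio_curve(ds)
  expect_gt(rc$values[1, "ratio"], 100)     # orders of magnitude at 10 nm
  expect_gt(rc$r_squared, 0.98)
  expect_lt(rc$slope, 0)
})

test_that("noise lowers the mean-image-to-fluctuation ratio", {
  ds <- seq(20, 120, by = 20)
  clean <- magnitude_ratio_curve(ds)
  noisy <- magnitude_ratio_curve(ds, peak_snr = 16, n_realizations = 20,
                                 seed = 2)
  expect_true(all(noisy$values[, "ratio"] < clean$values[, "ratio"]))
})
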