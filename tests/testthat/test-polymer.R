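test_that("FRC Kuhn and persistence lengths match direct evaluation", {
  frc <- frc_params(1, pi / 3)
  expect_equal(frc_kuhn_length(frc), 3.4641, tolerance = 1e-4)
  expect_equal(frc_persistence_length(frc), 1.2494, tolerance = 1e-4)
  # both scale linearly with the bond length
  frc2 <- frc_params(0.4, pi / 3)
  expect_equal(frc_kuhn_length(frc2), 0.4 * frc_kuhn_length(frc))
  expect_equal(frc_persistence_length(frc2),
               0.4 * frc_persistence_length(frc))
  expect_equal(frc_kuhn_length(frc2), 1.3856, tolerance = 1e-4)
  expect_equal(frc_persistence_length(frc2), 0.4998, tolerance = 1e-4)
  # gamma -> pi/2 limit of the Kuhn length: 1/cos(pi/4)
  frc3 <- frc_params(1, pi / 2 - 1e-9)
  expect_equal(frc_kuhn_length(frc3), 1 / cos(pi / 4), tolerance = 1e-6)
  # gamma -> 0: persistence length diverges
  expect_gt(frc_persistence_length(frc_params(1, 1e-6)), 1e9)
  expect_error(frc_params(1, 0), "gamma")
  expect_error(frc_params(-1, pi / 4), "bond_length_b")
})

test_that("FRC relative extension selects branches like the brute-force oracle", {
  frc <- frc_params()  # b = 0.4, gamma = 41 deg
  expect_identical(frc_relative_extension(0, frc), 0)
  forces <- c(0.05, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100, 300, 700)
  got <- frc_relative_extension(forces, frc)
  orc <- frc_branches_oracle(forces, 0.4, 41 * pi / 180)
  expected <- ifelse(orc$in_low, orc$low,
                     ifelse(orc$in_mid, orc$mid, orc$high))
  expect_equal(got, pmin(pmax(expected, 0), 1 - 1e-12), tolerance = 1e-12)
  # high-force limit approaches full extension
  expect_gt(frc_relative_extension(1e7, frc), 0.999)
  expect_error(frc_relative_extension(-1, frc), "force")
})

test_that("relative extension is non-decreasing within each branch", {
  frc <- frc_params()
  orc <- frc_branches_oracle(1, 0.4, 41 * pi / 180)
  kBT <- ctx0$kBT
  f_lowmid <- (0.4 / orc$p) * kBT / 0.4
  f_midhigh <- (orc$p / 0.4) * kBT / 0.4
  for (rng in list(c(1e-6, f_lowmid * 0.999), c(f_lowmid, f_midhigh),
                   c(f_midhigh * 1.001, 1000))) {
    f <- seq(rng[1], rng[2], length.out = 200)
    expect_true(all(diff(frc_relative_extension(f, frc)) >= 0))
  }
  # boundary discontinuities are reported, not masked
  d <- frc_branch_diagnostics(frc)
  expect_named(d, c("boundary", "force_pN", "x_over_L_below",
                    "x_over_L_above", "jump"))
  expect_equal(nrow(d), 2)
})

test_that("contour-length inversion round-trips above the noise floor", {
  frc <- frc_params()
  # definitional example
  f90 <- 30
  xl <- frc_relative_extension(f90, frc)
  expect_equal(frc_contour_length(f90, 150 * xl, frc), 150,
               tolerance = 1e-9)
  # round trip across forces above the floor
  for (f in c(10, 15, 40, 120, 400)) {
    xl <- frc_relative_extension(f, frc)
    expect_equal(frc_contour_length(f, 100 * xl, frc), 100,
                 tolerance = 1e-9)
  }
  # at the floor retained, below excluded as NA (flagged, not zero)
  expect_false(is.na(frc_contour_length(10, 50, frc)))
  expect_true(is.na(frc_contour_length(9.99, 50, frc)))
  expect_error(frc_contour_length(20, -1, frc), "extension")
})

test_that("FRC force inversion agrees with the forward law", {
  frc <- frc_params()
  xl <- c(0.05, 0.3, 0.6, 0.8, 0.9, 0.95, 0.99)
  f <- frc_force(xl, frc)
  back <- frc_relative_extension(f, frc)
  expect_equal(back, xl, tolerance = 1e-6)
})

test_that("WLC force follows the Marko-Siggia interpolation", {
  w <- wlc_params(100, 0.4)
  expect_equal(wlc_force(0, w), 0)
  expect_equal(wlc_force(50, w), 12.86, tolerance = 1e-3)
  # strictly increasing and convex beyond half extension
  x <- seq(51, 99, by = 1)
  f <- wlc_force(x, w)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) > 0))
  # divergence near full extension
  expect_gt(wlc_force(99.99, w), 1e4)
  expect_error(wlc_force(100, w), "extension")
  expect_error(wlc_params(-1, 0.4), "contour_length_L")
})
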