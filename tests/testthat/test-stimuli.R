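test_that("rotation onto the motion axis is a rigid rotation", {
  expect_equal(rotate_to_motion_axis(1.3, -0.7, 0), list(u = 1.3, v = -0.7))
  r <- rotate_to_motion_axis(1, 0, pi / 2)
  expect_equal(r$u, 0)
  expect_equal(r$v, -1)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(1); y <- rnorm(1); th <- runif(1, 0, 2 * pi)
    r <- rotate_to_motion_axis(x, y, th)
    expect_equal(r$u^2 + r$v^2, x^2 + y^2, tolerance = 1e-12)
  }
})

test_that("grating drive closed form matches its limits", {
  # zero spatial frequency: no spatial attenuation, amplitude exactly c
  sp <- grating_spec(contrast = 0.7, direction = 1, sf = 0, tf = 2 * pi)
  t <- seq(0, 1, by = 0.01)
  d <- grating_drive(sp, 2, -1, t, r_sub = 0.4)
  expect_equal(d, 0.7 * cos(-2 * pi * t))
  # half-period offset inverts the drive at all times
  sp0 <- grating_spec(0.3, direction = 0, offset_right = 0)
  sp1 <- grating_spec(0.3, direction = 0, offset_right = pi / sp0$sf)
  dL0 <- grating_drive(sp0, 0.3, 0.1, t, 0.4, eye = "R")
  dL1 <- grating_drive(sp1, 0.3, 0.1, t, 0.4, eye = "R")
  expect_equal(dL1, -dL0, tolerance = 1e-12)
  # drive is linear in contrast
  spa <- grating_spec(0.1, direction = 2)
  spb <- grating_spec(0.4, direction = 2)
  expect_equal(4 * grating_drive(spa, 1, 1, t, 0.4),
               grating_drive(spb, 1, 1, t, 0.4), tolerance = 1e-12)
  # disabled eye is silent
  spm <- grating_spec(0.3, eyes = "left")
  expect_equal(grating_drive(spm, 1, 1, 0.2, 0.4, eye = "R"), 0)
})

test_that("grating closed form agrees with 2-D quadrature of the defining cross-correlation", {
  r_sub <- 0.4
  for (case in list(c(sf = 2 * pi * 0.5, th = 0, x = 0, y = 0, t = 0),
                    c(sf = 2 * pi * 0.5, th = pi / 3, x = 0.7, y = -0.3,
                      t = 0.12),
                    c(sf = 2 * pi * 1.0, th = 4.1, x = -0.4, y = 0.2,
                      t = 0.31),
                    c(sf = 2 * pi * 0.25, th = 2.0, x = 0.1, y = 0.9,
                      t = 0.05))) {
    sp <- grating_spec(1, case[["th"]], case[["sf"]], 2 * pi * 2)
    closed <- grating_drive(sp, case[["x"]], case[["y"]], case[["t"]], r_sub)
    oracle <- quadrature_drive(function(xx, yy) {
      u <- rotate_to_motion_axis(xx, yy, case[["th"]])$u
      cos(case[["sf"]] * u - sp$tf * case[["t"]])
    }, case[["x"]], case[["y"]], r_sub)
    expect_lt(abs(closed - oracle), 1e-4)
  }
  # the attenuation value at the default grating parameters
  sp <- grating_spec(1, 0, 2 * pi * 0.5, 2 * pi * 2)
  expect_equal(grating_drive(sp, 0, 0, 0, r_sub),
               exp(-(0.4^2) * (pi^2) / 4), tolerance = 1e-12)
  expect_equal(grating_drive(sp, 0, 0, 0, r_sub), 0.6738, tolerance = 1e-3)
})

test_that("sparse-square drive matches its limits and the quadrature oracle", {
  sq <- sparse_square_spec(0.2, -0.1, width = 1, contrast = -1,
                           onset = 0.1, duration = 0.05)
  # outside the presentation window the drive is 0
  expect_equal(sparse_drive(sq, 0.2, -0.1, 0.0999, 0.4), 0)
  expect_equal(sparse_drive(sq, 0.2, -0.1, 0.151, 0.4), 0)
  # a very wide square converges to c (unit-integral kernel)
  wide <- sparse_square_spec(0, 0, width = 50, contrast = 0.8,
                             onset = 0, duration = 1)
  expect_equal(sparse_drive(wide, 0, 0, 0.5, 0.4), 0.8, tolerance = 1e-9)
  # quadrature agreement at several probe offsets; the 2-D integral of
  # the separable Gaussian-times-box integrand is evaluated as a product
  # of adaptive 1-D quadratures
  gauss_mass <- function(lo, hi, r) {
    stats::integrate(function(u) exp(-u^2 / r^2) / (sqrt(pi) * r),
                     lo, hi, rel.tol = 1e-10)$value
  }
  for (probe in list(c(0.2, -0.1), c(0.6, 0.2), c(-0.3, -0.8))) {
    closed <- sparse_drive(sq, probe[1], probe[2], 0.12, 0.4)
    oracle <- -1 * gauss_mass(0.2 - 0.5 - probe[1], 0.2 + 0.5 - probe[1], 0.4) *
      gauss_mass(-0.1 - 0.5 - probe[2], -0.1 + 0.5 - probe[2], 0.4)
    expect_lt(abs(closed - oracle), 1e-4)
  }
})

test_that("direction and offset sets match the development protocol", {
  d <- direction_set(16)
  expect_equal(length(d), 16)
  expect_equal(diff(d), rep(pi / 8, 15))
  o <- offset_set(5, 0.5)
  expect_equal(o, c(-0.5, -0.25, 0, 0.25, 0.5))
  expect_equal(o + rev(o), rep(0, 5))
})
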