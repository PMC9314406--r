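test_that("von Mises fit recovers known parameters exactly", {
  th <- direction_set(16)
  truth <- list(r0 = 2, rp = 30, rs = 10, tp = 40 * pi / 180,
                ts = 220 * pi / 180, k = 4)
  r <- truth$r0 +
    truth$rp * exp(truth$k * (cos(th - truth$tp) - 1)) +
    truth$rs * exp(truth$k * (cos(th - truth$ts) - 1))
  ft <- fit_von_mises(th, r)
  expect_lt(abs(ft$r0 - truth$r0) / truth$r0, 1e-3)
  expect_lt(abs(ft$rp - truth$rp) / truth$rp, 1e-3)
  expect_lt(abs(ft$rs - truth$rs) / truth$rs, 1e-3)
  expect_lt(abs(ft$theta_p - truth$tp), 1e-3)
  expect_lt(abs(ft$theta_s - truth$ts), 1e-3)
  expect_lt(abs(ft$k - truth$k) / truth$k, 1e-3)
  expect_false(ft$degenerate)
  expect_gt(ft$r2, 0.9999)
})

test_that("half-width at half-height follows from the concentration", {
  # k chosen so the half-height condition is met at exactly 45 degrees
  k45 <- log(2) / (1 - cos(45 * pi / 180))
  th <- direction_set(16)
  r <- 20 * exp(k45 * (cos(th) - 1))
  ft <- fit_von_mises(th, r)
  expect_equal(ft$hwhh_deg, 45, tolerance = 1e-3)
  # brute-force half-height search on the fitted lobe
  grid <- seq(0, pi, by = 1e-4)
  lobe <- exp(ft$k * (cos(grid) - 1))
  brute <- grid[which(lobe <= 0.5)[1]] * 180 / pi
  expect_lt(abs(brute - ft$hwhh_deg), 0.1)
})

test_that("flat tuning curves are flagged degenerate", {
  th <- direction_set(16)
  ft <- fit_von_mises(th, rep(3, 16))
  expect_true(ft$degenerate)
  expect_true(is.na(ft$pref_orientation))
  expect_true(is.na(ft$hwhh_deg))
})

test_that("circular correlation behaves as an axial-data statistic", {
  set.seed(11)
  a <- runif(60, 0, pi)
  r <- circular_correlation(a, a, pi, n_perm = 200)
  expect_equal(r$rho_c, 1, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
  # independent shuffle: near zero, non-significant
  b <- sample(a)
  r2 <- circular_correlation(a, b, pi, n_perm = 500)
  expect_lt(abs(r2$rho_c), 0.35)
  expect_gt(r2$p_value, 0.05)
  # invariance under a constant rotation of one sample
  r3 <- circular_correlation(a, (a + 0.7) %% pi, pi, n_perm = 0)
  expect_equal(r3$rho_c, 1, tolerance = 1e-9)
  expect_error(circular_correlation(a[1:5], a[1:5], pi), "at least 10")
})

test_that("interocular difference statistics wrap to (-90, 90] degrees", {
  l <- c(0, 0.2, 3.0)
  r <- c(0, 0.2, 3.0)
  s <- interocular_difference_stats(l, r)
  expect_equal(s$diff_deg, c(0, 0, 0))
  expect_equal(s$sd_deg, 0)
  # a 170 deg orientation vs 10 deg orientation differs by -20 deg
  s2 <- interocular_difference_stats(170 * pi / 180, 10 * pi / 180)
  expect_equal(s2$diff_deg, -20, tolerance = 1e-9)
  # independent uniform orientations: SD near 180/sqrt(12) = 51.96 deg
  set.seed(21)
  u1 <- runif(4000, 0, pi)
  u2 <- runif(4000, 0, pi)
  s3 <- interocular_difference_stats(u1, u2)
  expect_equal(s3$sd_deg, 180 / sqrt(12), tolerance = 0.05 * 52)
})

test_that("ocular dominance index and monocularity have the stated limits", {
  expect_equal(monocularity(0.5), 0)
  expect_equal(monocularity(1), 1)
  expect_equal(monocularity(0), 1)
  net <- tiny_net()
  ms <- random_mod_state(net, m_ie = 1)
  od <- ocular_dominance(net, ms, contrast = 0.3, n_directions = 8)
  ok <- !od$undefined
  expect_true(all(od$odi[ok] >= 0 & od$odi[ok] <= 1))
  expect_equal(od$monocularity[ok], 2 * abs(od$odi[ok] - 0.5))
})

test_that("disparity fit recovers a known preferred disparity", {
  sf <- pi  # rad/deg; period 2 deg
  u <- seq(-1, 0.875, by = 0.125)
  r <- 1.5 + 8 * abs(cos(sf * (u - 0.3) / 2))
  ft <- fit_disparity(u, r, sf)
  expect_lt(abs(ft$u_p - 0.3), 0.01)
  expect_lt(abs(ft$r0 - 1.5), 0.05)
  expect_lt(abs(ft$rp - 8), 0.05)
  # maximum of the fitted curve is r0 + rp at u_p; zero of the second term
  # at u_p + half period
  expect_equal(ft$r0 + ft$rp * abs(cos(sf * 0 / 2)), ft$r0 + ft$rp)
  expect_equal(abs(cos(sf * ((ft$u_p + pi / sf) - ft$u_p) / 2)), 0,
               tolerance = 1e-12)
})

test_that("map periodicity recovers the period of a synthetic sinusoidal map", {
  spacing <- 0.2
  n <- 31
  xy <- (seq_len(n) - (n + 1) / 2) * spacing
  per <- 1.6
  m <- outer(xy, xy, function(a, b) sin(2 * pi * a / per))
  res <- map_periodicity(m, spacing, mm_per_deg = 1 / 1.6)
  expect_false(res$aperiodic)
  expect_lt(abs(res$distance_deg - per), spacing + 1e-9)
  expect_equal(res$distance_mm, res$distance_deg / 1.6)
  # white noise has no reliable off-origin peaks
  set.seed(5)
  noise <- matrix(rnorm(n^2), n)
  res2 <- map_periodicity(noise, spacing)
  expect_true(res2$aperiodic || res2$distance_deg < 3 * spacing)
})

test_that("degrees convert linearly to cortical millimetres", {
  expect_equal(deg_to_cortical_mm(1.6), 1)
  expect_equal(deg_to_cortical_mm(0), 0)
  expect_equal(deg_to_cortical_mm(0.7) + deg_to_cortical_mm(0.9),
               deg_to_cortical_mm(1.6))
})
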