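test_that("attenuation follows the Gaussian convergence function", {
  x <- matrix(c(0, 0), 1)
  expect_equal(attenuation(x, x, 0.95)[1, 1], 1)
  y <- matrix(c(0.95, 0), 1)
  expect_equal(attenuation(x, y, 0.95)[1, 1], exp(-1))
  expect_equal(attenuation(x, y, 0.95), attenuation(y, x, 0.95))
  set.seed(3)
  a <- matrix(rnorm(10), 5)
  b <- matrix(rnorm(6), 3)
  expect_equal(attenuation(a, b, 0.7), t(attenuation(b, a, 0.7)))
  expect_error(attenuation(x, y, 0), "positive")
})

test_that("synaptic weights are modulated, attenuated and row-normalised", {
  # single source: weight 1 regardless of modulation and attenuation
  expect_equal(build_weights(matrix(0.37, 1, 1), m = 1.4)[1, 1], 1)
  # two equidistant sources with modulations 2 and 1
  w <- build_weights(matrix(c(0.5, 0.5), 1), m = matrix(c(2, 1), 1))
  expect_equal(drop(w), c(2 / 3, 1 / 3))
  # random instance vs brute-force normalisation
  set.seed(7)
  a <- matrix(runif(30, 0.01, 1), 5)
  m <- matrix(runif(30, 0, 2), 5)
  w <- build_weights(a, m)
  expect_equal(rowSums(w), rep(1, 5))
  for (i in 1:5) {
    expect_equal(w[i, ], (m * a)[i, ] / sum((m * a)[i, ]))
  }
  # all-zero row is a degenerate input naming the cell
  m2 <- m
  m2[3, ] <- 0
  expect_error(build_weights(a, m2), "degenerate.*3")
})

test_that("rectification and impulse rate follow the threshold-linear rule", {
  expect_equal(rectify(-1), 0)
  expect_equal(impulse_rate(-1), 0)
  expect_equal(impulse_rate(1.9, 7.2), 13.68)  # resting ganglion rate
  p <- c(-2, -0.1, 0, 0.5, 3)
  expect_equal(rectify(rectify(p)), rectify(p))  # idempotent
})

test_that("resting fixed points match the closed form", {
  p <- model_params()
  rs <- resting_state(p)
  expect_equal(rs$ganglion, 1.9)
  expect_equal(rs$geniculate, 1.9)
  expect_equal(rs$excitatory, 7 * 1.9 * (1 - 1.66))
  expect_equal(rs$excitatory, -8.778)
  net <- tiny_net()
  ms <- new_modulation_state(net)
  ms$m_ie <- p$k_ie
  tr <- integrate_dynamics(net, ms, make_grating_drive(
    net, grating_spec(contrast = 0)), t_max = 1.2, record = "all")
  n <- nrow(tr$exc)
  expect_equal(max(abs(tr$ganglion[n, ] - rs$ganglion)), 0, tolerance = 1e-6)
  expect_equal(max(abs(tr$geniculate[n, ] - rs$geniculate)), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(tr$soma[n, ] - rs$soma)), 0, tolerance = 1e-6)
  expect_equal(max(abs(tr$exc[n, ] - rs$excitatory)), 0, tolerance = 1e-5)
})

test_that("a single stage shows the first-order exponential step response", {
  # step drive into the cone stage of a one-channel cascade
  net <- tiny_net()
  p <- net$params
  ms <- new_modulation_state(net)
  drive <- function(t) rep(-1 / p$k_sens, net$n_chan)  # cone input step +1
  tr <- integrate_dynamics(net, ms, drive, t_max = 0.06, record = "all")
  expected <- 1 - exp(-tr$times / p$tau)
  expect_equal(tr$cone[, 1], expected, tolerance = 1e-6)
})

test_that("off pathway leads the on pathway by about 1 ms per stage pair", {
  net <- tiny_net()
  p <- net$params
  ms <- new_modulation_state(net)
  # identical positive step into every cone; compare bipolar half-rise
  drive <- function(t) rep(-1 / p$k_sens, net$n_chan)
  tr <- integrate_dynamics(net, ms, drive, t_max = 0.12, record = "all",
                           dt = 1e-4)
  i_off <- which(net$channels$sign == "off")[1]
  i_on <- which(net$channels$sign == "on")[1]
  half_time <- function(y) {
    y <- abs(y)  # the on-bipolar response is sign-inverted
    tr$times[which(y >= y[length(y)] / 2)[1]]
  }
  lag <- half_time(tr$bipolar[, i_on]) - half_time(tr$bipolar[, i_off])
  # one stage of tau +- delta: ln(2) * 2 * delta ~ 0.7 ms per stage
  expect_gt(lag, 0.0003)
  expect_lt(lag, 0.0015)
})

test_that("f1_amplitude measures the fundamental component", {
  t <- seq(0, 1 - 0.001, by = 0.001)
  om <- 2 * pi * 3
  expect_equal(f1_amplitude(5 + 2.5 * cos(om * t + 0.7), t, om), 2.5,
               tolerance = 1e-9)
  expect_equal(f1_amplitude(rep(4, length(t)), t, om), 0, tolerance = 1e-12)
  # half-wave rectified cosine of amplitude A has fundamental A/2
  expect_equal(f1_amplitude(pmax(3 * cos(om * t), 0), t, om), 1.5,
               tolerance = 1e-9)
  expect_error(f1_amplitude(cos(om * t[1:100]), t[1:100], 2 * pi * 0.5),
               "shorter than one")
})

test_that("steady_response rejects non-periodic stimuli and zero contrast is silent", {
  net <- tiny_net()
  ms <- random_mod_state(net)
  expect_error(steady_response(net, ms, sparse_square_spec()), "unsupported")
  sr <- steady_response(net, ms, grating_spec(contrast = 0))
  expect_equal(max(sr$f1_rate), 0)
})

test_that("doubling one neuron's modulations leaves its response unchanged", {
  net <- tiny_net()
  ms <- random_mod_state(net, m_ie = 1)
  sp <- grating_spec(0.3, direction = 1)
  r1 <- steady_response(net, ms, sp)
  ms2 <- ms
  ms2$m[4, ] <- 2 * ms2$m[4, ]
  r2 <- steady_response(net, ms2, sp)
  expect_equal(r2$f1_rate[4, 1], r1$f1_rate[4, 1], tolerance = 1e-12)
})

test_that("fast steady-state path agrees with time-domain integration", {
  net <- tiny_net()
  ms <- random_mod_state(net, m_ie = 1)
  specs <- list(grating_spec(0.3, direction = pi / 3),
                grating_spec(0.3, direction = 5.1, offset_right = 0.25),
                grating_spec(0.3, direction = 0, eyes = "left"))
  for (sp in specs) {
    fast <- steady_response(net, ms, sp, n_time = 256)$f1_rate[, 1]
    slow <- integrated_f1(net, ms, sp, n_transient = 10, n_measure = 2)
    sel <- which(slow > 0.05 * max(slow))
    expect_gt(length(sel), 5)
    expect_lt(max(abs(fast[sel] - slow[sel]) / slow[sel]), 1e-3)
    # the development-speed grid stays within a looser bound
    fast64 <- steady_response(net, ms, sp, n_time = 64)$f1_rate[, 1]
    expect_lt(max(abs(fast64[sel] - slow[sel]) / slow[sel]), 1e-2)
  }
})

test_that("responses are monotone non-decreasing in contrast", {
  net <- tiny_net()
  ms <- random_mod_state(net, m_ie = 1)
  cs <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  r <- vapply(cs, function(cc) {
    max(steady_response(net, ms, grating_spec(cc, direction = 1))$f1_rate)
  }, 0)
  expect_true(all(diff(r) > -1e-9))
})
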