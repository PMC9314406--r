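# Development-rule mechanics and the compiled-loop/reference equivalence.
# The scientific outcomes of full development runs are exercised in
# test-acceptance.R at the scaled preset; here the desk-scale fixture and
# short cycle counts probe the rule itself.

dev_fixture <- function() {
  cached("devfix", {
    net <- test_net(seed = 3)
    cfg <- development_config(n_cycles_phase1 = 40, n_cycles_phase2 = 40,
                              n_directions = 8, log_every = 10)
    list(net = net, cfg = cfg)
  })
}

test_that("modulation update rule applies increments, reverts and clamps", {
  expect_equal(update_modulation(1.0, TRUE), 1.2)
  expect_equal(update_modulation(1.9, TRUE), 2.0)
  expect_equal(update_modulation(1.0, FALSE), 0.8)
  expect_equal(update_modulation(0.1, FALSE), 0.0)
  expect_equal(update_modulation(c(0, 2), c(TRUE, FALSE)), c(0.2, 1.8))
})

test_that("channel selection is uniform over both eyes", {
  set.seed(8)
  expect_equal(select_channel(1, 5), rep(1, 5))
  n <- 290
  draws <- select_channel(n, 60000)
  expect_true(all(draws >= 1 & draws <= n))
  # chi-square uniformity at alpha = 0.01
  p <- chisq.test(tabulate(draws, n))$p.value
  expect_gt(p, 0.01)
  # mean selections per channel at the published full-scale budget
  expect_equal(50000 / 10202, 4.9, tolerance = 0.01)
})

test_that("development configuration validates its schedule", {
  cfg <- development_config()
  expect_equal(cfg$n_cycles_phase1, 50000L)
  expect_equal(cfg$n_cycles_phase2, 75000L)
  expect_equal(cfg$dm, 0.2)
  expect_equal(cfg$n_directions, 16L)
  expect_equal(cfg$offsets, c(-0.5, -0.25, 0, 0.25, 0.5))
  expect_error(development_config(dm = 0), "positive")
  expect_error(development_config(n_directions = 7), "even")
  # offsets must land on the steady-state time grid
  expect_error(development_config(n_offsets = 7), "align")
})

test_that("compiled development loop matches the pure-R reference cycle", {
  fx <- dev_fixture()
  net <- fx$net
  cfg <- fx$cfg
  dev <- develop(net, cfg, seed = 7)
  pre <- binodev:::precompute_development(net, cfg)
  set.seed(binodev:::seed_stream(7, "selection"))
  sel <- sample.int(net$n_chan, 80, replace = TRUE)
  p <- net$params
  mie1 <- binodev:::m_ie_schedule(p, cfg, 1, 1:40)
  st <- list(m = matrix(1, net$n_cort, net$n_chan), best = NULL)
  for (c in 1:40) {
    st <- development_cycle(net, pre, st, sel[c], 1, mie1[c], cfg)
  }
  expect_equal(st$m, dev$state1$m, tolerance = 0)
  for (c in 41:80) {
    st <- development_cycle(net, pre, st, sel[c], 2, p$k_ie, cfg)
  }
  expect_equal(st$m, dev$state$m, tolerance = 0)
})

test_that("development respects clamps, determinism and the zero-cycle identity", {
  fx <- dev_fixture()
  net <- fx$net
  cfg <- fx$cfg
  d1 <- develop(net, cfg, seed = 5)
  d2 <- develop(net, cfg, seed = 5)
  expect_identical(d1$state$m, d2$state$m)
  d3 <- develop(net, cfg, seed = 6)
  expect_false(identical(d3$state$m, d1$state$m))
  expect_true(all(d1$state$m >= 0 & d1$state$m <= 2))
  expect_true(all(d1$state1$m >= 0 & d1$state1$m <= 2))
  # zero cycles leave the state untouched
  cfg0 <- development_config(n_cycles_phase1 = 0, n_cycles_phase2 = 0,
                             n_directions = 8)
  d0 <- develop(net, cfg0, seed = 5)
  expect_true(all(d0$state$m == 1))
})

test_that("the inhibitory-excitatory modulation ramps linearly through phase 1", {
  p <- model_params()
  cfg <- development_config(n_cycles_phase1 = 1000, n_cycles_phase2 = 10,
                            n_directions = 8)
  sched <- binodev:::m_ie_schedule(p, cfg, 1, c(1, 250, 500, 1000))
  expect_equal(sched[4], p$k_ie)
  expect_equal(diff(sched), (p$k_ie - 1) * diff(c(1, 250, 500, 1000)) / 1000)
  expect_true(all(diff(sched) > 0))
  expect_equal(binodev:::m_ie_schedule(p, cfg, 2, 1:5), rep(p$k_ie, 5))
})

test_that("a checkpointed run resumes bit-identically", {
  fx <- dev_fixture()
  net <- fx$net
  cfg <- fx$cfg
  cfg$refresh_every <- 20L
  straight <- develop(net, cfg, seed = 9)
  ckdir <- tempfile("ck")
  segmented <- develop(net, cfg, seed = 9, checkpoint_dir = ckdir,
                       checkpoint_every = 20)
  expect_identical(segmented$state$m, straight$state$m)
  cks <- list.files(ckdir, full.names = TRUE)
  expect_gt(length(cks), 0)
  resumed <- resume_develop(net, cks[1])
  expect_identical(resumed$state$m, straight$state$m)
  unlink(ckdir, recursive = TRUE)
})

test_that("development requires an initial state for a phase-2-only run", {
  fx <- dev_fixture()
  expect_error(develop(fx$net, fx$cfg, seed = 1, phases = 2),
               "init_state")
})

test_that("the reference cycle demands a cycle-0 evaluation for cached baselines", {
  fx <- dev_fixture()
  cfg <- fx$cfg
  cfg$baseline <- "accepted"
  st <- list(m = matrix(1, fx$net$n_cort, fx$net$n_chan), best = NULL)
  expect_error(development_cycle(fx$net, NULL, st, 1, 1, 1, cfg),
               "uninitialised")
})
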