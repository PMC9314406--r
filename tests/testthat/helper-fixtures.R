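# Shared fixtures, built once per test run. All geometry is generated in
# code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# minimal network (1.6 deg field, 290 channels, 81 cortical nodes)
test_net <- function(seed = 1) {
  cached(paste0("net", seed), make_fixture("test", seed = seed)$net)
}

# even smaller network for the slow time-domain oracle runs
tiny_net <- function(seed = 1) {
  cached(paste0("tiny", seed), {
    params <- model_params()
    ch <- make_channel_mosaic(0.8, 0.2, 0.05, seed = seed)
    build_network(ch, params)
  })
}

# a modulation state with reproducible random structure, so cortical
# responses are non-degenerate without running development
random_mod_state <- function(net, seed = 42, m_ie = 1) {
  st <- new_modulation_state(net)
  set.seed(seed)
  st$m <- matrix(runif(length(st$m), 0, 2), nrow(st$m))
  st$m_ie <- m_ie
  st
}

# brute-force 2-D quadrature of the subcortical drive (the defining
# cross-correlation), used as the independent oracle for the closed forms
quadrature_drive <- function(stim_fun, x0, y0, r_sub, half = 6 * r_sub,
                             n = 301) {
  gx <- seq(-half, half, length.out = n)
  gy <- gx
  h <- gx[2] - gx[1]
  k <- exp(-outer(gy^2, gx^2, "+") / r_sub^2) / (pi * r_sub^2)
  s <- outer(gy, gx, function(yy, xx) stim_fun(x0 + xx, y0 + yy))
  sum(k * s) * h^2
}
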