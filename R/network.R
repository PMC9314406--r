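#' Convergence attenuation
#'
#' Gaussian attenuation of a presynaptic signal as a function of the
#' visual-field distance between the pre- and postsynaptic receptive
#' fields: \code{exp(-|x_i - x_j|^2 / r^2)}.
#'
#' @param xi matrix (n x 2) of postsynaptic positions, deg.
#' @param xj matrix (m x 2) of presynaptic positions, deg.
#' @param r convergence radius, deg.
#' @return n x m matrix of attenuations in (0, 1].
#' @export
attenuation <- function(xi, xj, r) {
  if (r <= 0) stop("'r' must be positive")
  xi <- as.matrix(xi)
  xj <- as.matrix(xj)
  d2 <- outer(xi[, 1], xj[, 1], "-")^2 + outer(xi[, 2], xj[, 2], "-")^2
  exp(-d2 / r^2)
}

#' Synaptic weight matrix
#'
#' Weights are the product of the developmental modulation factor and the
#' distance attenuation, normalised so every postsynaptic row sums to 1:
#' \code{w_ij = m_ij a_ij / sum_j m_ij a_ij}. The normalisation makes each
#' neuron's resting potential equal to its presynaptic resting potential.
#'
#' @param a attenuation matrix (postsynaptic x presynaptic).
#' @param m modulation factors: a matrix conformable with \code{a}, or a
#'   scalar (default 1).
#' @return row-stochastic weight matrix.
#' @export
build_weights <- function(a, m = 1) {
  ma <- a * m
  if (any(ma < 0)) stop("modulations and attenuations must be non-negative")
  n <- rowSums(ma)
  bad <- which(n <= 0)
  if (length(bad)) {
    stop("degenerate input: postsynaptic cell(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " receive zero total modulated attenuation")
  }
  ma / n
}

#' Rectification and impulse rate
#'
#' Action potential rate is proportional to the rectified generator
#' potential: \code{rate = k_rect * max(p, 0)}.
#'
#' @param p generator potential, mV (vectorised).
#' @param k_rect rectification constant, Hz/mV.
#' @return \code{rectify}: rectified potential (mV); \code{impulse_rate}:
#'   rate (Hz).
#' @export
rectify <- function(p) pmax(p, 0)

#' @rdname rectify
#' @export
impulse_rate <- function(p, k_rect = 7.2) k_rect * rectify(p)

#' Build the network
#'
#' Assembles the model: the channel mosaic, the cortical grid (one
#' excitatory and one inhibitory neuron per node), the geniculocortical
#' attenuation matrix (radius \code{r_cort}, shared by excitatory and
#' inhibitory targets), and the row-normalised inhibitory-to-excitatory
#' convergence matrix (also radius \code{r_cort}).
#'
#' @param channels a \code{\link{make_channel_mosaic}} data.frame.
#' @param params a \code{\link{model_params}} object.
#' @return An object of class \code{binodev_network}.
#' @export
build_network <- function(channels, params = model_params()) {
  field_width <- attr(channels, "field_width")
  if (is.null(field_width)) {
    field_width <- 2 * max(abs(c(channels$x, channels$y)))
  }
  cortex <- cortical_grid(field_width, params$cortical_spacing,
                          params$r_cort)
  chan_xy <- cbind(channels$x, channels$y)
  cort_xy <- cbind(cortex$x, cortex$y)
  A <- attenuation(cort_xy, chan_xy, params$r_cort)
  W_ie <- build_weights(attenuation(cort_xy, cort_xy, params$r_cort))
  structure(list(
    channels = channels,
    cortex = cortex,
    params = params,
    field_width = field_width,
    n_chan = nrow(channels),
    n_cort = nrow(cortex),
    idx_L = which(channels$eye == "L"),
    idx_R = which(channels$eye == "R"),
    sign_n = ifelse(channels$sign == "off", 1, -1),
    tau_n = tau_n_for(params, channels$sign),
    A = A,
    W_ie = W_ie,
    D_inh = rowSums(A)
  ), class = "binodev_network")
}

#' @export
print.binodev_network <- function(x, ...) {
  cat(sprintf(
    "binodev network: %d channels (%d per eye), %d cortical nodes, %g deg field\n",
    x$n_chan, length(x$idx_L), x$n_cort, x$field_width))
  invisible(x)
}

#' Fresh modulation state
#'
#' All geniculocortical modulation factors start at 1, as does the
#' inhibitory-to-excitatory modulation scalar.
#'
#' @param net a \code{\link{build_network}} object.
#' @return list of class \code{binodev_modulation} with elements \code{m}
#'   (n_cortical x n_channels matrix in `[0, 2]`) and \code{m_ie} (scalar in
#'   `[1, k_ie]`).
#' @export
new_modulation_state <- function(net) {
  structure(list(m = matrix(1, net$n_cort, net$n_chan), m_ie = 1),
            class = "binodev_modulation")
}

# ---- periodic steady-state machinery ---------------------------------------

# Apply a first-order low-pass 1/(1 + i h w tau) to each row of X, where the
# rows hold one stimulus period sampled at N points. tau may be per-row.
fft_filter_rows <- function(X, tau, omega) {
  N <- ncol(X)
  k <- 0:(N - 1)
  h <- ifelse(k <= N / 2, k, k - N)
  Y <- stats::mvfft(t(X))                       # N x n, fft along time
  H <- 1 / (1 + 1i * omega * outer(h, rep_len(tau, ncol(Y))))
  Re(t(stats::mvfft(Y * H, inverse = TRUE))) / N
}

# Periodic waveform of filter_tau(h(p_gen)) for every channel of one eye,
# sampled at n_time points per stimulus period. This is the geniculate
# signal as seen through the cortical integration time constant; by
# linearity the tau filter can be applied before the convergence sum.
channel_waveforms <- function(net, spec, eye, n_time = 64) {
  p <- net$params
  idx <- if (eye == "L") net$idx_L else net$idx_R
  nch <- length(idx)
  enabled <- !((eye == "L" && spec$eyes == "right") ||
                 (eye == "R" && spec$eyes == "left"))
  if (!enabled || spec$contrast == 0) {
    return(matrix(p$p_rest, nch, n_time))
  }
  tau_n <- net$tau_n[idx]
  nsign <- net$sign_n[idx]
  off <- if (eye == "R") spec$offset_right else 0
  u <- rotate_to_motion_axis(net$channels$x[idx], net$channels$y[idx],
                             spec$direction)$u + off
  w <- spec$tf
  a0 <- spec$contrast * exp(-p$r_sub^2 * spec$sf^2 / 4)
  # complex amplitude of the ganglion potential: drive -> cone -> bipolar ->
  # ganglion, all linear
  camp <- a0 * exp(-1i * spec$sf * u) *
    (-p$k_sens / (1 + 1i * w * p$tau)) *
    (nsign / (1 + 1i * w * tau_n)) *
    (1 / (1 + 1i * w * tau_n))
  t_k <- (0:(n_time - 1)) * (2 * pi / w) / n_time
  p_gang <- p$p_rest + Re(camp %o% exp(1i * w * t_k))
  p_gen <- fft_filter_rows(pmax(p_gang, 0), tau_n, w)
  fft_filter_rows(pmax(p_gen, 0), p$tau, w)
}

# Cortical periodic steady state given per-eye geniculate waveform blocks.
cortical_steady <- function(net, m_state, HfL, HfR, omega) {
  p <- net$params
  Hf <- matrix(0, net$n_chan, ncol(HfL))
  Hf[net$idx_L, ] <- HfL
  Hf[net$idx_R, ] <- HfR
  p_soma <- p$k_gc * (net$A %*% Hf) / net$D_inh
  p_inh <- fft_filter_rows(pmax(p_soma, 0), p$tau_inh, omega)
  g_ie <- fft_filter_rows(pmax(p_inh, 0), p$tau, omega)
  MA <- m_state$m * net$A
  D <- rowSums(MA)
  if (any(D <= 0)) stop("degenerate modulation: a cortical cell lost all input")
  p_exc <- p$k_gc * (MA %*% Hf) / D -
    m_state$m_ie * (net$W_ie %*% g_ie)
  list(p_exc = p_exc, rate = p$k_rect * pmax(p_exc, 0),
       p_soma = p_soma, p_inh = p_inh)
}

f1_of_rows <- function(X) {
  N <- ncol(X)
  z <- X %*% exp(-1i * 2 * pi * (0:(N - 1)) / N)
  2 * Mod(z) / N
}

#' Periodic steady-state response to drifting gratings
#'
#' Fast response path: the periodic steady state of the cascade is
#' computed stage by stage, treating each stage as a first-order low-pass
#' applied per Fourier harmonic of the waveform (sampled at
#' \code{n_time} points per period) and applying each rectification
#' pointwise on the time grid. Returns the fundamental Fourier (F1)
#' amplitude of excitatory impulse rate, the measure used throughout the
#' analyses, and the F1 amplitude of the excitatory generator potential.
#' Agreement with \code{\link{integrate_dynamics}} is part of the test
#' contract.
#'
#' @param net a \code{\link{build_network}} object.
#' @param m_state a \code{\link{new_modulation_state}} object (developed or
#'   not).
#' @param stim a \code{\link{grating_spec}} or a list of them.
#' @param n_time samples per stimulus period (default 64).
#' @param waveforms if TRUE (single stimulus only) also return the
#'   excitatory potential and rate waveforms.
#' @return list with \code{f1_rate} and \code{f1_potential}: n_cortical x
#'   n_stimulus matrices (Hz and mV), plus waveforms when requested.
#' @export
steady_response <- function(net, m_state, stim, n_time = 64,
                            waveforms = FALSE) {
  if (inherits(stim, "grating_spec")) stim <- list(stim)
  if (!length(stim) || !all(vapply(stim, inherits, TRUE, "grating_spec"))) {
    stop("unsupported stimulus: steady_response requires periodic ",
         "drifting-grating specs; use integrate_dynamics for transients")
  }
  n_stim <- length(stim)
  f1r <- matrix(0, net$n_cort, n_stim)
  f1p <- matrix(0, net$n_cort, n_stim)
  out_waves <- NULL
  for (s in seq_len(n_stim)) {
    sp <- stim[[s]]
    HfL <- channel_waveforms(net, sp, "L", n_time)
    HfR <- channel_waveforms(net, sp, "R", n_time)
    cs <- cortical_steady(net, m_state, HfL, HfR, sp$tf)
    f1r[, s] <- f1_of_rows(cs$rate)
    f1p[, s] <- f1_of_rows(cs$p_exc)
    if (waveforms && n_stim == 1L) out_waves <- cs
  }
  out <- list(f1_rate = f1r, f1_potential = f1p)
  if (!is.null(out_waves)) out <- c(out, out_waves)
  out
}

#' F1 amplitude of a sampled response
#'
#' Modulus of the Fourier component at the stimulus frequency, scaled so a
#' pure cosine of amplitude A returns A. The samples must cover an integer
#' number of stimulus periods (after transient removal).
#'
#' @param x response samples (e.g. impulse rate, Hz).
#' @param times sample times, s (evenly spaced).
#' @param omega stimulus temporal frequency, rad/s.
#' @return F1 amplitude, same units as \code{x}.
#' @export
f1_amplitude <- function(x, times, omega) {
  if (length(x) != length(times) || length(x) < 2) {
    stop("'x' and 'times' must be equal-length vectors")
  }
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("'times' must be evenly spaced")
  span <- length(x) * dt[1]
  n_per <- span * omega / (2 * pi)
  if (n_per < 1 - 1e-6) {
    stop("sample span is shorter than one stimulus period")
  }
  if (abs(n_per - round(n_per)) > 1e-3) {
    stop("sample span must be an integer number of stimulus periods")
  }
  2 * Mod(mean(x * exp(-1i * omega * times)))
}

# ---- reference time-domain integrator --------------------------------------

#' Per-channel drive functions for the reference integrator
#'
#' \code{make_grating_drive} and \code{make_sparse_drive} return a function
#' of time giving the subcortical drive for every channel in the network
#' (both eyes), suitable for \code{\link{integrate_dynamics}}.
#'
#' @param net a \code{\link{build_network}} object.
#' @param spec a \code{\link{grating_spec}} or
#'   \code{\link{sparse_square_spec}}.
#' @param eye for sparse squares: which eye sees the stimulus.
#' @return function(t) -> numeric vector of length \code{net$n_chan}.
#' @export
make_grating_drive <- function(net, spec) {
  p <- net$params
  a0 <- spec$contrast * exp(-p$r_sub^2 * spec$sf^2 / 4)
  enab <- rep(1, net$n_chan)
  if (spec$eyes == "left") enab[net$idx_R] <- 0
  if (spec$eyes == "right") enab[net$idx_L] <- 0
  u <- rotate_to_motion_axis(net$channels$x, net$channels$y,
                             spec$direction)$u
  u[net$idx_R] <- u[net$idx_R] + spec$offset_right
  phase <- spec$sf * u
  function(t) enab * a0 * cos(phase - spec$tf * t)
}

#' @rdname make_grating_drive
#' @export
make_sparse_drive <- function(net, spec, eye = "L") {
  s <- rep(0, net$n_chan)
  idx <- if (eye == "L") net$idx_L else net$idx_R
  s[idx] <- sparse_drive(spec, net$channels$x[idx], net$channels$y[idx],
                         t = spec$onset, r_sub = net$params$r_sub)
  t0 <- spec$onset
  t1 <- spec$onset + spec$duration
  function(t) if (t >= t0 && t < t1) s else s * 0
}

#' Reference time-domain integration of the full cascade
#'
#' Integrates the coupled first-order equations of every stage (cones,
#' bipolar, ganglion, geniculate per channel; inhibitory soma and axon,
#' excitatory cell per cortical node) with a classical Runge-Kutta scheme,
#' starting from the zero-contrast resting state. This is the slow
#' reference path against which the periodic steady-state solver is
#' verified.
#'
#' @param net a \code{\link{build_network}} object.
#' @param m_state modulation state.
#' @param drive_fun per-channel drive function of time (see
#'   \code{\link{make_grating_drive}}).
#' @param t_max end of integration, s.
#' @param dt time step, s (default \code{tau/10}).
#' @param record "exc" to record excitatory potentials, "all" for every
#'   stage.
#' @param record_from discard samples before this time, s.
#' @return list with \code{times} and matrices of recorded potentials
#'   (time x neuron): \code{exc}, and for \code{record = "all"} also
#'   \code{cone}, \code{bipolar}, \code{ganglion}, \code{geniculate},
#'   \code{soma}, \code{inh}.
#' @export
integrate_dynamics <- function(net, m_state, drive_fun, t_max,
                               dt = net$params$tau / 10,
                               record = c("exc", "all"), record_from = 0) {
  record <- match.arg(record)
  p <- net$params
  nc <- net$n_chan
  nx <- net$n_cort
  MA <- m_state$m * net$A
  D <- rowSums(MA)
  m_ie <- m_state$m_ie
  i_cone <- seq_len(nc)
  i_bip <- nc + i_cone
  i_gang <- 2 * nc + i_cone
  i_gen <- 3 * nc + i_cone
  i_soma <- 4 * nc + seq_len(nx)
  i_inh <- 4 * nc + nx + seq_len(nx)
  i_exc <- 4 * nc + 2 * nx + seq_len(nx)
  y <- c(rep(0, 2 * nc), rep(p$p_rest, 2 * nc),
         rep(p$k_gc * p$p_rest, 2 * nx),
         rep(p$k_gc * p$p_rest * (1 - m_ie), nx))
  deriv <- function(t, y) {
    d <- drive_fun(t)
    hgen <- pmax(y[i_gen], 0)
    c(
      (-p$k_sens * d - y[i_cone]) / p$tau,
      (net$sign_n * y[i_cone] - y[i_bip]) / net$tau_n,
      (y[i_bip] + p$p_rest - y[i_gang]) / net$tau_n,
      (pmax(y[i_gang], 0) - y[i_gen]) / net$tau_n,
      (p$k_gc * drop(net$A %*% hgen) / net$D_inh - y[i_soma]) / p$tau,
      (pmax(y[i_soma], 0) - y[i_inh]) / p$tau_inh,
      (p$k_gc * drop(MA %*% hgen) / D -
         m_ie * drop(net$W_ie %*% pmax(y[i_inh], 0)) - y[i_exc]) / p$tau
    )
  }
  n_steps <- ceiling(t_max / dt)
  keep <- integer(0)
  times <- numeric(0)
  exc <- NULL
  all_rec <- NULL
  n_keep <- sum((0:n_steps) * dt >= record_from - 1e-12)
  exc <- matrix(NA_real_, n_keep, nx)
  if (record == "all") {
    all_rec <- list(cone = matrix(NA_real_, n_keep, nc),
                    bipolar = matrix(NA_real_, n_keep, nc),
                    ganglion = matrix(NA_real_, n_keep, nc),
                    geniculate = matrix(NA_real_, n_keep, nc),
                    soma = matrix(NA_real_, n_keep, nx),
                    inh = matrix(NA_real_, n_keep, nx))
  }
  times <- numeric(n_keep)
  row <- 0L
  for (step in 0:n_steps) {
    t <- step * dt
    if (t >= record_from - 1e-12) {
      row <- row + 1L
      times[row] <- t
      exc[row, ] <- y[i_exc]
      if (record == "all") {
        all_rec$cone[row, ] <- y[i_cone]
        all_rec$bipolar[row, ] <- y[i_bip]
        all_rec$ganglion[row, ] <- y[i_gang]
        all_rec$geniculate[row, ] <- y[i_gen]
        all_rec$soma[row, ] <- y[i_soma]
        all_rec$inh[row, ] <- y[i_inh]
      }
    }
    if (step == n_steps) break
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y))) {
      stop(sprintf("integration failure: non-finite state at t = %.4f s",
                   t + dt))
    }
  }
  out <- list(times = times[seq_len(row)], exc = exc[seq_len(row), , drop = FALSE])
  if (record == "all") {
    out <- c(out, lapply(all_rec, function(m) m[seq_len(row), , drop = FALSE]))
  }
  out
}

#' F1 amplitude of excitatory impulse rate from a time-domain run
#'
#' Convenience wrapper: integrates the network for \code{n_transient}
#' stimulus periods to let transients decay, then \code{n_measure} further
#' periods over which the F1 amplitude of each excitatory neuron's impulse
#' rate is measured.
#'
#' @inheritParams integrate_dynamics
#' @param spec the \code{\link{grating_spec}} being presented.
#' @param n_transient periods discarded (default 8: over a second at the
#'   default 2 Hz, several times the slowest time constant).
#' @param n_measure periods measured (default 2).
#' @return vector of F1 amplitudes, Hz, one per excitatory neuron.
#' @export
integrated_f1 <- function(net, m_state, spec, n_transient = 8, n_measure = 2,
                          dt = net$params$tau / 10) {
  period <- 2 * pi / spec$tf
  # align the step so an integer number of steps fits one period
  steps_per <- ceiling(period / dt)
  dt <- period / steps_per
  t_max <- (n_transient + n_measure) * period - dt
  tr <- integrate_dynamics(net, m_state, make_grating_drive(net, spec),
                           t_max = t_max, dt = dt,
                           record_from = n_transient * period)
  rate <- net$params$k_rect * pmax(tr$exc, 0)
  apply(rate, 2, f1_amplitude, times = tr$times, omega = spec$tf)
}
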