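#' Cortical analysis window
#'
#' Indices of cortical nodes inside the central analysis window. Maps are
#' computed over the whole field but summarised only over a central
#' window, excluding a margin near the field edge where convergence
#' footprints are truncated (at full scale the central 6 x 6 deg of the
#' 10 x 10 deg field).
#'
#' @param net a \code{\link{build_network}} object.
#' @param margin excluded margin on each side, deg (default 2).
#' @return integer indices into the cortical grid.
#' @export
analysis_window <- function(net, margin = 2) {
  half <- net$field_width / 2 - margin
  which(abs(net$cortex$x) <= half + 1e-9 & abs(net$cortex$y) <= half + 1e-9)
}

#' Orientation tuning curves
#'
#' F1 amplitude of impulse rate for gratings drifting in evenly spaced
#' directions, delivered to one eye or both.
#'
#' @param net network.
#' @param m_state modulation state.
#' @param eye "left", "right" or "binocular".
#' @param n_directions number of drift directions (>= 8).
#' @param contrast,sf,tf grating parameters (defaults from the network's
#'   \code{\link{model_params}}).
#' @param neurons optional subset of cortical indices to return.
#' @param n_time samples per period for the steady-state solver.
#' @return list of class \code{binodev_tuning}: \code{directions} (rad),
#'   \code{response} (neurons x directions, Hz), \code{potential_f1}
#'   (mV), \code{neurons}, \code{eye}.
#' @export
orientation_tuning <- function(net, m_state,
                               eye = c("binocular", "left", "right"),
                               n_directions = 16,
                               contrast = net$params$contrast,
                               sf = net$params$sf, tf = net$params$tf,
                               neurons = NULL, n_time = 64) {
  eye <- match.arg(eye)
  if (n_directions < 8) stop("'n_directions' must be at least 8")
  dirs <- direction_set(n_directions)
  eyes_arg <- switch(eye, binocular = "both", left = "left", right = "right")
  specs <- lapply(dirs, function(d) {
    grating_spec(contrast, d, sf, tf, eyes = eyes_arg)
  })
  sr <- steady_response(net, m_state, specs, n_time)
  if (is.null(neurons)) neurons <- seq_len(net$n_cort)
  structure(list(directions = dirs,
                 response = sr$f1_rate[neurons, , drop = FALSE],
                 potential_f1 = sr$f1_potential[neurons, , drop = FALSE],
                 neurons = neurons, eye = eye, contrast = contrast),
            class = "binodev_tuning")
}

# wrap an angle to (-period/2, period/2]
wrap_half <- function(x, period = pi) {
  w <- x %% period
  hi <- which(w > period / 2)
  w[hi] <- w[hi] - period
  w
}

#' Fit a sum of von Mises functions to a direction tuning curve
#'
#' Least-squares fit of
#' \deqn{r(\theta) = r_0 + r_p e^{k(\cos(\theta-\theta_p)-1)}
#'   + r_s e^{k(\cos(\theta-\theta_s)-1)}}
#' with a shared concentration k and preferred/suboptimal direction lobes.
#' Multi-start (the preferred lobe initialised at the curve argmax, the
#' secondary at argmax + 180 deg, two initial bandwidths) guards against
#' lobe-swap local minima; lobes are ordered by amplitude after fitting.
#' The half-width at half-height follows from k:
#' \eqn{\Delta\theta = \arccos(1 + \ln(1/2)/k)}.
#'
#' @param directions drift directions, radians.
#' @param response F1 amplitudes, Hz.
#' @return list of class \code{vm_fit}: \code{r0}, \code{rp}, \code{rs}
#'   (Hz), \code{theta_p}, \code{theta_s} (rad), \code{k},
#'   \code{pref_orientation} (rad, in `[0, pi)`), \code{hwhh_deg},
#'   \code{r2}, \code{degenerate}.
#' @export
fit_von_mises <- function(directions, response) {
  stopifnot(length(directions) == length(response))
  if (length(directions) < 8) stop("need at least 8 directions")
  th <- directions
  r <- response
  rng <- max(r) - min(r)
  if (!is.finite(rng) || rng < 1e-9 || max(r) < 1e-9) {
    return(structure(list(r0 = mean(r), rp = 0, rs = 0, theta_p = NA_real_,
                          theta_s = NA_real_, k = NA_real_,
                          pref_orientation = NA_real_, hwhh_deg = NA_real_,
                          r2 = NA_real_, degenerate = TRUE),
                     class = "vm_fit"))
  }
  vm <- function(pars, th) {
    pars[1] + pars[2] * exp(pars[6] * (cos(th - pars[4]) - 1)) +
      pars[3] * exp(pars[6] * (cos(th - pars[5]) - 1))
  }
  sse <- function(pars) sum((r - vm(pars, th))^2)
  tp0 <- th[which.max(r)]
  ts0 <- tp0 + pi
  rs0 <- max(r[which.min(abs(wrap_half(th - ts0, 2 * pi)))] - min(r), 0)
  best <- NULL
  for (k0 in c(2, 8)) {
    st <- c(min(r), rng, rs0, tp0, ts0, k0)
    ft <- try(stats::optim(st, sse, method = "L-BFGS-B",
                           lower = c(0, 0, 0, -2 * pi, -2 * pi, 0.05),
                           upper = c(Inf, Inf, Inf, 4 * pi, 4 * pi, 200),
                           control = list(maxit = 500)), silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$value < best$value) best <- ft
  }
  if (is.null(best)) {
    return(structure(list(r0 = NA_real_, rp = NA_real_, rs = NA_real_,
                          theta_p = NA_real_, theta_s = NA_real_,
                          k = NA_real_, pref_orientation = NA_real_,
                          hwhh_deg = NA_real_, r2 = NA_real_,
                          degenerate = TRUE),
                     class = "vm_fit"))
  }
  p <- best$par
  if (p[3] > p[2]) p <- p[c(1, 3, 2, 5, 4, 6)]  # order lobes by amplitude
  theta_p <- p[4] %% (2 * pi)
  theta_s <- p[5] %% (2 * pi)
  k <- p[6]
  hw <- if (k >= log(2) / 2) acos(1 + log(0.5) / k) * 180 / pi else NA_real_
  sst <- sum((r - mean(r))^2)
  structure(list(r0 = p[1], rp = p[2], rs = p[3], theta_p = theta_p,
                 theta_s = theta_s, k = k,
                 pref_orientation = theta_p %% pi,
                 hwhh_deg = hw, r2 = 1 - best$value / sst,
                 degenerate = p[2] < 1e-6 * max(r)),
            class = "vm_fit")
}

#' Orientation map over the analysis window
#'
#' Fits the sum-of-von-Mises model to each neuron's tuning curve and
#' returns preferred direction/orientation, bandwidth and amplitude.
#'
#' @param tuning a \code{\link{orientation_tuning}} result.
#' @return data.frame: \code{neuron}, \code{pref_dir} (rad),
#'   \code{pref_ori} (rad in `[0, pi)`), \code{hwhh_deg}, \code{peak}
#'   (max measured F1, Hz), \code{r2}, \code{degenerate}.
#' @export
orientation_map <- function(tuning) {
  stopifnot(inherits(tuning, "binodev_tuning"))
  n <- nrow(tuning$response)
  out <- data.frame(neuron = tuning$neurons,
                    pref_dir = NA_real_, pref_ori = NA_real_,
                    hwhh_deg = NA_real_, peak = NA_real_, r2 = NA_real_,
                    degenerate = NA)
  for (i in seq_len(n)) {
    ft <- fit_von_mises(tuning$directions, tuning$response[i, ])
    out$pref_dir[i] <- ft$theta_p
    out$pref_ori[i] <- ft$pref_orientation
    out$hwhh_deg[i] <- ft$hwhh_deg
    out$peak[i] <- max(tuning$response[i, ])
    out$r2[i] <- ft$r2
    out$degenerate[i] <- ft$degenerate
  }
  out
}

#' Circular correlation coefficient with permutation test
#'
#' Fisher-Lee circular correlation between two cyclic samples. For
#' orientations (period 180 deg) the angles are doubled onto the full
#' circle before the statistic is computed, the standard treatment for
#' axial data. The p-value is obtained by random permutation of the
#' second sample.
#'
#' @param a,b equal-length angle vectors, radians.
#' @param period common period of the data (\code{pi} for orientations,
#'   \code{2*pi} for directions).
#' @param n_perm number of permutations (set 0 to skip the test).
#' @return list: \code{rho_c}, \code{p_value}, \code{n}.
#' @export
circular_correlation <- function(a, b, period = pi, n_perm = 10000) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 10) stop("need at least 10 paired angles")
  if (length(b) != n) stop("'a' and 'b' must have equal length")
  al <- a * 2 * pi / period
  be <- b * 2 * pi / period
  rho_fl <- function(al, be) {
    num <- 0.5 * (Mod(sum(exp(1i * (al - be))))^2 -
                    Mod(sum(exp(1i * (al + be))))^2)
    den <- sqrt(0.5 * (n^2 - Mod(sum(exp(2i * al)))^2) *
                  0.5 * (n^2 - Mod(sum(exp(2i * be)))^2))
    num / den
  }
  rho <- rho_fl(al, be)
  p <- NA_real_
  if (n_perm > 0) {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(rho_fl(al, sample(be))) >= abs(rho) - 1e-15) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  list(rho_c = rho, p_value = p, n = n)
}

#' Interocular orientation-difference statistics
#'
#' Signed angular difference between left- and right-eye preferred
#' orientations on period 180 deg, wrapped to (-90, 90], and the sample
#' standard deviation of the wrapped differences.
#'
#' @param ori_left,ori_right preferred orientations, radians in `[0, pi)`.
#' @return list: \code{diff_deg} (wrapped differences, deg),
#'   \code{sd_deg}.
#' @export
interocular_difference_stats <- function(ori_left, ori_right) {
  ok <- is.finite(ori_left) & is.finite(ori_right)
  d <- wrap_half(ori_left[ok] - ori_right[ok], pi) * 180 / pi
  list(diff_deg = d, sd_deg = stats::sd(d), n = length(d))
}

#' Ocular dominance index and monocularity
#'
#' Each neuron is stimulated monocularly through each eye across all
#' directions; the drifting grating "optimised for the dominant eye" (the
#' direction maximising the stronger eye's response) defines the two
#' responses \code{r_L}, \code{r_R}, and
#' \code{ODI = r_R / (r_L + r_R)}; monocularity is \code{2 |ODI - 0.5|}.
#'
#' @param net network.
#' @param m_state modulation state.
#' @param contrast stimulus contrast (the ocular-dominance analyses use
#'   0.25 by default; 0.3 elsewhere).
#' @param n_directions directions sampled.
#' @param neurons cortical indices to analyse.
#' @param n_time samples per period.
#' @return data.frame: \code{neuron}, \code{r_left}, \code{r_right} (Hz),
#'   \code{odi} in `[0, 1]` (0 = left dominated), \code{monocularity},
#'   \code{undefined} (TRUE when both responses are zero).
#' @export
ocular_dominance <- function(net, m_state, contrast = 0.25,
                             n_directions = 16, neurons = NULL,
                             n_time = 64) {
  tl <- orientation_tuning(net, m_state, "left", n_directions,
                           contrast = contrast, neurons = neurons,
                           n_time = n_time)
  tr <- orientation_tuning(net, m_state, "right", n_directions,
                           contrast = contrast, neurons = neurons,
                           n_time = n_time)
  RL <- tl$response
  RR <- tr$response
  n <- nrow(RL)
  odi <- rep(NA_real_, n)
  rl <- rr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dom <- if (max(RL[i, ]) >= max(RR[i, ])) RL[i, ] else RR[i, ]
    j <- which.max(dom)
    rl[i] <- RL[i, j]
    rr[i] <- RR[i, j]
  }
  undef <- (rl + rr) <= 0
  odi <- ifelse(undef, NA_real_, rr / (rl + rr))
  data.frame(neuron = tl$neurons, r_left = rl, r_right = rr, odi = odi,
             monocularity = ifelse(undef, NA_real_, 2 * abs(odi - 0.5)),
             undefined = undef)
}

#' Monocularity from an ocular dominance index
#'
#' @param odi ocular dominance index in `[0, 1]`.
#' @return \code{2 * abs(odi - 0.5)} in `[0, 1]`.
#' @export
monocularity <- function(odi) 2 * abs(odi - 0.5)

#' Disparity tuning and rectified-cosine fit
#'
#' Binocular responses to optimally oriented gratings as a function of the
#' interocular spatial offset u over one spatial period, fitted with
#' \deqn{r(u) = r_0 + r_p |\cos(\psi (u - u_p) / 2)|}
#' with the spatial frequency \eqn{\psi} fixed at the stimulus value;
#' \eqn{u_p} is the preferred disparity, reported within one period
#' centred on 0. Offsets are sampled on the steady-state solver's grid.
#'
#' @param net network.
#' @param m_state modulation state.
#' @param pref_dir preferred drift direction per analysed neuron (radians;
#'   snapped to the sampled direction set).
#' @param neurons cortical indices, same length as \code{pref_dir}.
#' @param n_offsets interocular offsets spanning one spatial period
#'   (must divide \code{n_time}).
#' @param contrast,sf,tf grating parameters.
#' @param monocularity optional per-neuron monocularity; fits for neurons
#'   with monocularity > 0.95 are flagged unreliable.
#' @param n_time samples per period.
#' @return data.frame: \code{neuron}, \code{u_p} (deg), \code{r0},
#'   \code{rp} (Hz), \code{r2}, \code{unreliable}; plus attributes
#'   \code{offsets} and \code{response} (neurons x offsets matrix).
#' @export
disparity_tuning <- function(net, m_state, pref_dir, neurons,
                             n_offsets = 16, contrast = net$params$contrast,
                             sf = net$params$sf, tf = net$params$tf,
                             monocularity = NULL, n_time = 64) {
  stopifnot(length(pref_dir) == length(neurons))
  period <- 2 * pi / sf
  if (n_time %% n_offsets != 0) stop("'n_offsets' must divide 'n_time'")
  offsets <- (seq_len(n_offsets) - 1 - n_offsets / 2) * period / n_offsets
  shifts <- as.integer(round(n_time * sf * offsets / (2 * pi)))
  resp <- matrix(NA_real_, length(neurons), n_offsets)
  p <- net$params
  for (d in unique(pref_dir)) {
    grp <- which(pref_dir == d)
    sp <- grating_spec(contrast, d, sf, tf)
    HfL <- channel_waveforms(net, sp, "L", n_time)
    HfR <- channel_waveforms(net, sp, "R", n_time)
    AL <- net$A[, net$idx_L, drop = FALSE]
    AR <- net$A[, net$idx_R, drop = FALSE]
    SL <- AL %*% HfL
    SR <- AR %*% HfR
    MA <- m_state$m * net$A
    D <- rowSums(MA)
    FL <- (MA[, net$idx_L, drop = FALSE]) %*% HfL
    FR <- (MA[, net$idx_R, drop = FALSE]) %*% HfR
    for (o in seq_len(n_offsets)) {
      soma <- p$k_gc * (SL + shift_cols(SR, shifts[o])) / net$D_inh
      it <- inhib_term(net, soma, tf)
      p_exc <- p$k_gc * (FL + shift_cols(FR, shifts[o])) / D -
        m_state$m_ie * it
      f1 <- f1_of_rows(p$k_rect * pmax(p_exc, 0))
      resp[grp, o] <- f1[neurons[grp]]
    }
  }
  fits <- lapply(seq_along(neurons), function(i) {
    fit_disparity(offsets, resp[i, ], sf)
  })
  out <- data.frame(
    neuron = neurons,
    u_p = vapply(fits, `[[`, 0, "u_p"),
    r0 = vapply(fits, `[[`, 0, "r0"),
    rp = vapply(fits, `[[`, 0, "rp"),
    r2 = vapply(fits, `[[`, 0, "r2"))
  out$unreliable <- if (is.null(monocularity)) FALSE else
    !is.na(monocularity) & monocularity > 0.95
  attr(out, "offsets") <- offsets
  attr(out, "response") <- resp
  out
}

#' Fit the rectified-cosine disparity model
#'
#' @param u interocular offsets, deg.
#' @param r F1 responses, Hz.
#' @param sf stimulus spatial frequency, rad/deg (held fixed).
#' @return list: \code{r0}, \code{rp}, \code{u_p} (deg, wrapped to one
#'   period centred on 0), \code{r2}.
#' @export
fit_disparity <- function(u, r, sf) {
  period <- 2 * pi / sf
  sse_for <- function(up) {
    b <- abs(cos(sf * (u - up) / 2))
    X <- cbind(1, b)
    cf <- tryCatch(qr.solve(X, r), error = function(e) c(mean(r), 0))
    if (cf[2] < 0) {  # rp >= 0: fall back to the constant model
      cf <- c(mean(r), 0)
    }
    list(sse = sum((r - X %*% cf)^2), cf = cf)
  }
  grid <- seq(-period / 2, period / 2, length.out = 129)
  sses <- vapply(grid, function(g) sse_for(g)$sse, 0)
  g0 <- grid[which.min(sses)]
  stp <- diff(grid[1:2])
  opt <- stats::optimize(function(g) sse_for(g)$sse,
                         lower = g0 - stp, upper = g0 + stp)
  up <- wrap_half(opt$minimum, period)
  fit <- sse_for(opt$minimum)
  sst <- sum((r - mean(r))^2)
  list(r0 = fit$cf[1], rp = fit$cf[2], u_p = up,
       r2 = if (sst > 0) 1 - fit$sse / sst else NA_real_)
}

#' Map a receptive field with sparse noise
#'
#' Presents a light (contrast +1) and a dark (contrast -1) square at each
#' node of a probe grid, monocularly, and records the neuron's generator
#' potential with the time-domain integrator. The response at a location
#' is the maximum over time of the light-minus-dark potential difference.
#'
#' @param net network.
#' @param m_state modulation state.
#' @param neuron cortical index of the analysed excitatory neuron.
#' @param eye "L" or "R".
#' @param extent half-width of the probe grid around the neuron, deg.
#' @param spacing probe grid spacing, deg (default 0.25).
#' @param width square width, deg (default 1).
#' @param duration presentation time, s (default 0.05).
#' @param t_tail extra integration time after offset, s.
#' @param dt integrator step, s.
#' @return list of class \code{binodev_rf}: \code{x}, \code{y} (probe
#'   coordinates), \code{value} (matrix, mV, y varying over rows),
#'   \code{neuron}, \code{eye}.
#' @export
map_receptive_field <- function(net, m_state, neuron, eye = "L",
                                extent = 1.5, spacing = 0.25, width = 1,
                                duration = 0.05, t_tail = 0.25,
                                dt = net$params$tau / 10) {
  cx <- net$cortex$x[neuron]
  cy <- net$cortex$y[neuron]
  xs <- seq(cx - extent, cx + extent, by = spacing)
  ys <- seq(cy - extent, cy + extent, by = spacing)
  r_need <- extent + net$params$r_cort
  if (max(abs(c(xs, ys))) < r_need - net$field_width / 2) {
    warning("probe grid may not cover the neuron's convergence footprint")
  }
  val <- matrix(NA_real_, length(ys), length(xs))
  t_max <- duration + t_tail
  for (ix in seq_along(xs)) {
    for (iy in seq_along(ys)) {
      resp <- lapply(c(1, -1), function(con) {
        spec <- sparse_square_spec(xs[ix], ys[iy], width, con,
                                   onset = 0, duration = duration)
        tr <- integrate_dynamics(net, m_state,
                                 make_sparse_drive(net, spec, eye),
                                 t_max = t_max, dt = dt)
        tr$exc[, neuron]
      })
      val[iy, ix] <- max(resp[[1]] - resp[[2]])
    }
  }
  structure(list(x = xs, y = ys, value = val, neuron = neuron, eye = eye),
            class = "binodev_rf")
}

#' Orientation of a receptive-field map
#'
#' Axis through the centroids of the positive (on) and negative (off)
#' subregions, modulo 180 deg. For a simple-cell-like field this axis
#' runs along the preferred motion direction, perpendicular to the
#' preferred bar orientation.
#'
#' @param rf a \code{\link{map_receptive_field}} result.
#' @return axis angle, radians in `[0, pi)`.
#' @export
rf_axis <- function(rf) {
  v <- rf$value
  gx <- outer(rep(1, length(rf$y)), rf$x)
  gy <- outer(rf$y, rep(1, length(rf$x)))
  pos <- pmax(v, 0)
  neg <- pmax(-v, 0)
  if (sum(pos) == 0 || sum(neg) == 0) return(NA_real_)
  cxp <- sum(gx * pos) / sum(pos)
  cyp <- sum(gy * pos) / sum(pos)
  cxn <- sum(gx * neg) / sum(neg)
  cyn <- sum(gy * neg) / sum(neg)
  atan2(cyp - cyn, cxp - cxn) %% pi
}

#' Periodicity of a feature map
#'
#' Two-dimensional autocorrelation of a demeaned map sampled on the
#' regular cortical grid. Local maxima (3 x 3 neighbourhood) away from
#' the origin with amplitude above twice the far-field RMS are candidate
#' periodicity peaks; the mean radial distance of the nearest ring of
#' peaks (those within 25\% of the closest) estimates the map period,
#' also expressed as cortical distance.
#'
#' @param values map values on the grid: matrix with y over rows, x over
#'   columns, or a vector of length matching \code{nx * ny}.
#' @param spacing grid spacing, deg.
#' @param mm_per_deg cortical magnification, mm/deg.
#' @return list: \code{distance_deg}, \code{distance_mm}, \code{peaks}
#'   (data.frame of retained maxima: dx, dy, value), \code{aperiodic}.
#' @export
map_periodicity <- function(values, spacing, mm_per_deg = 1 / 1.6) {
  v <- as.matrix(values)
  v <- v - mean(v)
  ny <- nrow(v)
  nx <- ncol(v)
  py <- 2 * ny
  px <- 2 * nx
  pad <- matrix(0, py, px)
  pad[1:ny, 1:nx] <- v
  F <- stats::fft(pad)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (px * py)
  # reorder so zero lag is central
  ac <- ac[c((ny + 1):py, 1:ny), c((nx + 1):px, 1:nx)]
  cy0 <- ny + 1
  cx0 <- nx + 1
  lagx <- ((1:px) - cx0) * spacing
  lagy <- ((1:py) - cy0) * spacing
  rad <- sqrt(outer(lagy^2, lagx^2, "+"))
  far <- rad > 0.6 * max(abs(c(lagx, lagy)))
  noise <- sqrt(mean(ac[far]^2))
  peaks <- NULL
  for (i in 2:(py - 1)) {
    for (j in 2:(px - 1)) {
      if (i == cy0 && j == cx0) next
      a <- ac[i, j]
      nb <- ac[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (a >= max(nb) && a > 2 * noise) {
        peaks <- rbind(peaks, c(lagx[j], lagy[i], a))
      }
    }
  }
  if (is.null(peaks)) {
    return(list(distance_deg = NA_real_, distance_mm = NA_real_,
                peaks = NULL, aperiodic = TRUE))
  }
  peaks <- as.data.frame(peaks)
  names(peaks) <- c("dx", "dy", "value")
  peaks$dist <- sqrt(peaks$dx^2 + peaks$dy^2)
  peaks <- peaks[peaks$dist > 0, , drop = FALSE]
  if (!nrow(peaks)) {
    return(list(distance_deg = NA_real_, distance_mm = NA_real_,
                peaks = NULL, aperiodic = TRUE))
  }
  dmin <- min(peaks$dist)
  ring <- peaks[peaks$dist <= 1.25 * dmin, , drop = FALSE]
  d <- mean(ring$dist)
  list(distance_deg = d, distance_mm = deg_to_cortical_mm(d, mm_per_deg),
       peaks = peaks, aperiodic = FALSE)
}

#' Convert visual-field distance to cortical distance
#'
#' Linear conversion using the cortical magnification at the modelled
#' eccentricity (11 deg temporal): 1.6 deg of visual field corresponds to
#' 1.0 mm of cortex.
#'
#' @param distance_deg distance, deg.
#' @param mm_per_deg magnification, mm/deg (default 1/1.6).
#' @return distance in mm.
#' @export
deg_to_cortical_mm <- function(distance_deg, mm_per_deg = 1 / 1.6) {
  distance_deg * mm_per_deg
}

#' Contrast sensitivity of excitatory cells
#'
#' Generator-potential modulation amplitude per unit contrast, measured
#' monocularly through each neuron's dominant eye at its optimal
#' direction, at a contrast low enough that the cascade is in its linear
#' regime (default 0.04, below the ganglion rectification knee).
#'
#' @param net network.
#' @param m_state modulation state.
#' @param dominant_eye per-neuron dominant eye ("L"/"R").
#' @param pref_dir per-neuron optimal drift direction, radians.
#' @param neurons cortical indices, matching the two vectors above.
#' @param contrast probe contrast.
#' @param n_time samples per period.
#' @return vector of sensitivities, mV per contrast-unit.
#' @export
contrast_sensitivity <- function(net, m_state, dominant_eye, pref_dir,
                                 neurons, contrast = 0.04, n_time = 64) {
  sens <- rep(NA_real_, length(neurons))
  key <- paste(dominant_eye, signif(pref_dir, 12))
  for (kk in unique(key)) {
    grp <- which(key == kk)
    eye <- dominant_eye[grp[1]]
    sp <- grating_spec(contrast, pref_dir[grp[1]], net$params$sf,
                       net$params$tf,
                       eyes = if (eye == "L") "left" else "right")
    sr <- steady_response(net, m_state, sp, n_time)
    sens[grp] <- sr$f1_potential[neurons[grp], 1] / contrast
  }
  sens
}
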