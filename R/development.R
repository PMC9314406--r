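#' Development schedule configuration
#'
#' Parameters of the two-phase Hebbian development procedure. Full-scale
#' defaults follow the modelled schedule: each channel is selected about 5
#' times per phase-equivalent, giving 50,000 monocular cycles
#' (round(10,202 x 5)) and 75,000 binocular cycles; 16 drift directions;
#' 5 interocular offsets evenly spaced in `[-0.5, 0.5]` deg (phase 2 only);
#' modulation increment 0.2 clamped to `[0, 2]`.
#'
#' @param n_cycles_phase1,n_cycles_phase2 cycle counts for the monocular
#'   and binocular phases.
#' @param dm modulation increment per cycle (default 0.2).
#' @param n_directions number of evenly spaced drift directions per cycle.
#' @param n_offsets number of interocular offsets used on every phase-2
#'   cycle.
#' @param offset_range half-range of the offsets, deg.
#' @param contrast stimulus contrast during development.
#' @param sf,tf grating spatial (rad/deg) and temporal (rad/s) frequency.
#' @param measure response measure driving accept/revert decisions.
#'   \code{"potential"} (default): the F1 amplitude of the excitatory
#'   generator potential — a graded, depolarisation-based Hebbian signal
#'   that keeps plasticity alive while the inhibitory ramp holds a neuron
#'   below spike threshold. \code{"peak"}: the maximum of the generator
#'   potential over the cycle (proportional to peak impulse rate whenever
#'   the neuron fires). \code{"f1"}: fundamental Fourier amplitude of
#'   impulse rate (the measure reported by the analyses).
#' @param normalisation whether the accept test sees the weight
#'   normaliser updated with the provisional increment (\code{"tracked"},
#'   default) or held at its pre-increment value (\code{"frozen"}: the
#'   test then isolates the channel's own contribution, giving bi-stable
#'   per-synapse decisions).
#' @param baseline comparison baseline for the accept/revert rule.
#'   \code{"increment"} (default): the ensemble is evaluated on the
#'   incoming state and again with the provisional increment, and the
#'   increment is kept where it raised the neuron's maximum response —
#'   the comparison isolates the increment's own effect, is unaffected by
#'   the phase-1 inhibitory ramp, and drives each synapse monotonically
#'   towards 0 or 2. \code{"cycle"}: compare against the response
#'   measured on the previous cycle of the same stimulus condition
#'   (per-eye in phase 1). \code{"accepted"}: a running maximum updated
#'   only on acceptance. The cached variants are noisier because a cached
#'   baseline reflects weights that later cycles (or the same cycle's
#'   revert) have already changed.
#' @param n_time samples per stimulus period for the steady-state solver.
#'   The offsets must land on this grid:
#'   \code{n_time * sf * offset / (2*pi)} integer for every offset.
#' @param refresh_every cycles between full recomputations of the cached
#'   input numerators (numerical hygiene for the rank-1 update scheme).
#' @param log_every cycles between entries of the development log.
#' @return list of class \code{binodev_devconfig}.
#' @export
development_config <- function(n_cycles_phase1 = 50000,
                               n_cycles_phase2 = 75000,
                               dm = 0.2, n_directions = 16, n_offsets = 5,
                               offset_range = 0.5, contrast = 0.3,
                               sf = 2 * pi * 0.5, tf = 2 * pi * 2,
                               measure = c("potential", "peak", "f1"),
                               baseline = c("increment", "cycle", "accepted"),
                               normalisation = c("tracked", "frozen"),
                               n_time = 64,
                               refresh_every = 2000, log_every = 100) {
  measure <- match.arg(measure)
  baseline <- match.arg(baseline)
  normalisation <- match.arg(normalisation)
  if (dm <= 0) stop("'dm' must be positive")
  if (n_directions < 1 || n_directions %% 2 != 0) {
    stop("'n_directions' must be a positive even count")
  }
  offsets <- offset_set(n_offsets, offset_range)
  if (max(abs(offsets + rev(offsets))) > 1e-12) {
    stop("offsets must be symmetric about 0")
  }
  shifts <- n_time * sf * offsets / (2 * pi)
  if (max(abs(shifts - round(shifts))) > 1e-9) {
    stop("interocular offsets must align with the time grid: ",
         "n_time * sf * offset / (2*pi) must be an integer")
  }
  structure(list(
    n_cycles_phase1 = as.integer(n_cycles_phase1),
    n_cycles_phase2 = as.integer(n_cycles_phase2),
    dm = dm, n_directions = as.integer(n_directions),
    offsets = offsets, contrast = contrast, sf = sf, tf = tf,
    measure = measure, baseline = baseline, normalisation = normalisation,
    n_time = as.integer(n_time),
    refresh_every = as.integer(refresh_every),
    log_every = as.integer(log_every)
  ), class = "binodev_devconfig")
}

#' Uniform random channel selection
#'
#' On each development cycle one subcortical channel is selected uniformly
#' from the channels of both eyes (phase 1 restricts the stimulation, not
#' the selection).
#'
#' @param n_channels number of channels.
#' @param n number of draws.
#' @return integer channel ids.
#' @export
select_channel <- function(n_channels, n = 1) {
  if (n_channels < 1) stop("empty channel set")
  sample.int(n_channels, n, replace = TRUE)
}

#' Modulation update rule
#'
#' The per-synapse accept/revert rule: the factor is provisionally
#' incremented by \code{dm}; if the neuron's maximum response exceeded its
#' cached previous maximum the increment is retained, otherwise the factor
#' is set to its previous value minus \code{dm}. Both moves clamp to
#' `[0, 2]`.
#'
#' @param prev modulation factor(s) before the cycle.
#' @param accepted logical: did the neuron's response increase?
#' @param dm increment (default 0.2).
#' @return updated modulation factor(s).
#' @examples
#' update_modulation(1.0, TRUE)    # 1.2
#' update_modulation(1.9, TRUE)    # 2.0 (clamped)
#' update_modulation(0.1, FALSE)   # 0.0 (clamped)
#' @export
update_modulation <- function(prev, accepted, dm = 0.2) {
  ifelse(accepted, pmin(prev + dm, 2), pmax(prev - dm, 0))
}

shift_cols <- function(X, s) {
  N <- ncol(X)
  X[, ((seq_len(N) - 1 - s) %% N) + 1, drop = FALSE]
}

# Inhibitory-to-excitatory drive term for a given inhibitory-soma
# waveform set, computed with unit m_ie (it scales linearly with m_ie).
inhib_term <- function(net, p_soma, omega) {
  p <- net$params
  p_inh <- fft_filter_rows(pmax(p_soma, 0), p$tau_inh, omega)
  g_ie <- fft_filter_rows(pmax(p_inh, 0), p$tau, omega)
  net$W_ie %*% g_ie
}

# Precompute everything the development loop needs: per-direction
# geniculate waveforms for each eye and the inhibitory drive term for
# every stimulus condition (monocular per eye; binocular per offset).
# Inhibitory geniculocortical synapses do not develop (modulation 1), so
# these terms are constant throughout development.
precompute_development <- function(net, cfg) {
  p <- net$params
  dirs <- direction_set(cfg$n_directions)
  N <- cfg$n_time
  nL <- length(net$idx_L)
  nR <- length(net$idx_R)
  nx <- net$n_cort
  nd <- length(dirs)
  no <- length(cfg$offsets)
  shifts <- as.integer(round(N * cfg$sf * cfg$offsets / (2 * pi)))
  AL <- net$A[, net$idx_L, drop = FALSE]
  AR <- net$A[, net$idx_R, drop = FALSE]
  DLi <- rowSums(AL)
  DRi <- rowSums(AR)
  HfL <- array(0, c(nL, N, nd))
  HfR <- array(0, c(nR, N, nd))
  ITmL <- array(0, c(nx, N, nd))
  ITmR <- array(0, c(nx, N, nd))
  ITb <- array(0, c(nx, N, nd * no))
  for (d in seq_len(nd)) {
    sp <- grating_spec(cfg$contrast, dirs[d], cfg$sf, cfg$tf)
    HfL[, , d] <- channel_waveforms(net, sp, "L", N)
    HfR[, , d] <- channel_waveforms(net, sp, "R", N)
    SL <- AL %*% HfL[, , d]
    SR <- AR %*% HfR[, , d]
    # monocular: the silent eye's channels rest at p_rest
    ITmL[, , d] <- inhib_term(
      net, p$k_gc * (SL + p$p_rest * DRi) / net$D_inh, cfg$tf)
    ITmR[, , d] <- inhib_term(
      net, p$k_gc * (SR + p$p_rest * DLi) / net$D_inh, cfg$tf)
    for (o in seq_len(no)) {
      soma <- p$k_gc * (SL + shift_cols(SR, shifts[o])) / net$D_inh
      ITb[, , (d - 1) * no + o] <- inhib_term(net, soma, cfg$tf)
    }
  }
  list(dirs = dirs, shifts = shifts, HfL = HfL, HfR = HfR,
       ITmL = ITmL, ITmR = ITmR, ITb = ITb)
}

# m_ie schedule: ramps linearly from 1 to k_ie over phase 1 (reaching k_ie
# on the final phase-1 cycle), then stays at k_ie throughout phase 2.
m_ie_schedule <- function(params, cfg, phase, cycles) {
  if (phase == 1) {
    1 + (params$k_ie - 1) * cycles / cfg$n_cycles_phase1
  } else {
    rep(params$k_ie, length(cycles))
  }
}

#' Run the Hebbian development procedure
#'
#' Runs the monocular (phase 1) and/or binocular (phase 2) development
#' phases. On each cycle one channel is selected uniformly from both
#' eyes and the modulation factors of its synapses onto every cortical
#' excitatory neuron are provisionally incremented by \code{dm}; the model
#' is stimulated with drifting gratings (phase 1: the selected channel's
#' eye only, all directions; phase 2: both eyes, all directions and all
#' interocular offsets) and each neuron independently keeps the increment
#' if its maximum response exceeded its cached previous maximum, otherwise
#' reverts to its previous value minus \code{dm} (clamped to `[0, 2]`; the
#' cached maximum is updated only on acceptance). The
#' inhibitory-to-excitatory modulation ramps linearly from 1 to
#' \code{k_ie} during phase 1 and is held at \code{k_ie} thereafter.
#'
#' The whole run is reproducible from \code{seed}: the channel-selection
#' sequence is drawn from a dedicated substream, so runs resumed from a
#' checkpoint continue bit-identically.
#'
#' @param net a \code{\link{build_network}} object.
#' @param config a \code{\link{development_config}}.
#' @param seed master integer seed.
#' @param phases \code{c(1, 2)} (default), \code{1} or \code{2}.
#' @param init_state modulation state to start from (required when
#'   \code{phases} is \code{2}; default: fresh state, all factors 1).
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param checkpoint_every cycles between checkpoints (rounded up to a
#'   multiple of \code{config$refresh_every}).
#' @param verbose print per-phase progress.
#' @return list of class \code{binodev_development} with elements
#'   \code{state1} (modulation state at phase-1 end), \code{state} (final
#'   state), \code{best1}/\code{best} (cached per-neuron maximum
#'   responses), \code{log} (data.frame: cycle, phase, mean and max cached
#'   response, acceptance fraction), \code{config}, \code{seed}.
#' @export
develop <- function(net, config = development_config(), seed = 1,
                    phases = c(1, 2), init_state = NULL,
                    checkpoint_dir = NULL, checkpoint_every = NULL,
                    verbose = FALSE) {
  cfg <- config
  p <- net$params
  if (identical(phases, 2) || identical(phases, 2L)) {
    if (is.null(init_state)) {
      stop("phase 2 requires 'init_state' (the phase-1 output); ",
           "run phases = c(1, 2) or supply a state")
    }
  }
  state <- init_state
  if (is.null(state)) state <- new_modulation_state(net)
  pre <- precompute_development(net, cfg)
  set.seed(seed_stream(seed, "selection"))
  n_tot <- cfg$n_cycles_phase1 + cfg$n_cycles_phase2
  sel_all <- sample.int(net$n_chan, n_tot, replace = TRUE)
  eye_vec <- as.integer(net$channels$eye == "R")
  local_vec <- integer(net$n_chan)
  local_vec[net$idx_L] <- seq_along(net$idx_L) - 1L
  local_vec[net$idx_R] <- seq_along(net$idx_R) - 1L

  run_phase <- function(phase, m, cycles) {
    # per-condition baselines (phase 1: one column per eye); sentinel -1
    # triggers a cycle-0 evaluation of the ensemble inside the loop
    best <- matrix(-1, net$n_cort, 2)
    sel <- sel_all[cycles]
    logs <- list()
    seg_len <- length(cycles)
    if (!is.null(checkpoint_dir)) {
      ce <- checkpoint_every
      if (is.null(ce)) ce <- 10L * cfg$refresh_every
      seg_len <- max(cfg$refresh_every,
                     ceiling(ce / cfg$refresh_every) * cfg$refresh_every)
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    }
    done <- 0L
    n_phase <- length(cycles)
    phase_cycle_idx <- if (phase == 1) seq_len(n_phase) else
      seq_len(n_phase)  # cycle index within the phase
    while (done < n_phase) {
      take <- seq.int(done + 1L, min(done + seg_len, n_phase))
      mie <- m_ie_schedule(p, cfg, phase, phase_cycle_idx[take])
      res <- dev_loop(
        m, net$A, eye_vec, local_vec, pre$HfL, pre$HfR,
        pre$ITmL, pre$ITmR, pre$ITb, pre$shifts, best,
        as.integer(sel[take]) - 1L, as.integer(phase), mie,
        p$k_gc, p$k_rect, p$p_rest, cfg$dm,
        match(cfg$measure, c("f1", "peak", "potential")) - 1L,
        match(cfg$baseline, c("increment", "cycle", "accepted")) - 1L,
        as.integer(cfg$normalisation == "frozen"),
        cfg$refresh_every,
        cfg$log_every, net$idx_L - 1L, net$idx_R - 1L,
        as.integer(cycles[1] - 1L + done))
      m <- res$m
      best <- res$best
      logs[[length(logs) + 1L]] <- res$log
      done <- done + length(take)
      if (!is.null(checkpoint_dir) && done < n_phase) {
        saveRDS(list(m = m, best = best, phase = phase, done = done,
                     seed = seed, config = cfg),
                file.path(checkpoint_dir,
                          sprintf("checkpoint_p%d_c%07d.rds", phase, done)))
      }
      if (verbose) {
        message(sprintf("phase %d: %d / %d cycles (mean cached response %.3f Hz)",
                        phase, done, n_phase,
                        if (phase == 1) mean(best) else mean(best[, 1])))
      }
    }
    lg <- do.call(rbind, logs)
    if (is.null(lg)) lg <- matrix(numeric(0), 0, 4)
    colnames(lg) <- c("cycle", "mean_best", "max_best", "accept_frac")
    lg <- as.data.frame(lg)
    lg$phase <- rep(phase, nrow(lg))
    list(m = m, best = best, log = lg)
  }

  out <- list(config = cfg, seed = seed)
  logs <- list()
  if (1 %in% phases) {
    r1 <- run_phase(1, state$m, seq_len(cfg$n_cycles_phase1))
    state <- structure(list(m = r1$m, m_ie = p$k_ie),
                       class = "binodev_modulation")
    out$state1 <- state
    out$best1 <- r1$best  # columns: left-eye, right-eye baselines
    logs[[length(logs) + 1L]] <- r1$log
  } else {
    out$state1 <- state
  }
  if (2 %in% phases) {
    cyc2 <- cfg$n_cycles_phase1 + seq_len(cfg$n_cycles_phase2)
    st <- out$state1
    st$m_ie <- p$k_ie
    r2 <- run_phase(2, st$m, cyc2)
    state <- structure(list(m = r2$m, m_ie = p$k_ie),
                       class = "binodev_modulation")
    out$best <- r2$best[, 1]
    logs[[length(logs) + 1L]] <- r2$log
  }
  out$state <- state
  out$log <- do.call(rbind, logs)
  class(out) <- "binodev_development"
  out
}

#' @export
print.binodev_development <- function(x, ...) {
  cat(sprintf("binodev development run (seed %d): %d + %d cycles\n",
              x$seed, x$config$n_cycles_phase1, x$config$n_cycles_phase2))
  if (!is.null(x$best)) {
    cat(sprintf("  final cached responses: mean %.2f Hz, max %.2f Hz\n",
                mean(x$best), max(x$best)))
  }
  invisible(x)
}

#' Resume a development run from a checkpoint
#'
#' Continues a checkpointed \code{\link{develop}} run. The channel
#' selection sequence is regenerated from the stored master seed, so the
#' continuation is bit-identical to an uninterrupted run.
#'
#' @param net the network the checkpoint was created with.
#' @param checkpoint path to a checkpoint file, or the loaded list.
#' @param ... passed on to \code{\link{develop}} (e.g. \code{verbose}).
#' @return as \code{\link{develop}}.
#' @export
resume_develop <- function(net, checkpoint, ...) {
  ck <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  cfg <- ck$config
  # rebuild: rerun remaining cycles of the checkpointed phase, then any
  # later phase
  state <- structure(list(m = ck$m,
                          m_ie = if (ck$phase == 1)
                            m_ie_schedule(net$params, cfg, 1, ck$done)
                          else net$params$k_ie),
                     class = "binodev_modulation")
  continue_develop(net, cfg, ck$seed, ck$phase, ck$done, state, ck$best, ...)
}

# Internal: run the remainder of a phase (from cycle `done`) plus any
# following phase. Kept separate from develop() so resume can inject the
# cached best-response vector.
continue_develop <- function(net, cfg, seed, phase, done, state, best,
                             verbose = FALSE) {
  p <- net$params
  pre <- precompute_development(net, cfg)
  set.seed(seed_stream(seed, "selection"))
  n_tot <- cfg$n_cycles_phase1 + cfg$n_cycles_phase2
  sel_all <- sample.int(net$n_chan, n_tot, replace = TRUE)
  eye_vec <- as.integer(net$channels$eye == "R")
  local_vec <- integer(net$n_chan)
  local_vec[net$idx_L] <- seq_along(net$idx_L) - 1L
  local_vec[net$idx_R] <- seq_along(net$idx_R) - 1L

  out <- list(config = cfg, seed = seed)
  logs <- list()
  m <- state$m
  if (phase == 1) {
    cyc <- seq.int(done + 1L, cfg$n_cycles_phase1)
    mie <- m_ie_schedule(p, cfg, 1, cyc)
    res <- dev_loop(m, net$A, eye_vec, local_vec, pre$HfL, pre$HfR,
                    pre$ITmL, pre$ITmR, pre$ITb, pre$shifts, best,
                    as.integer(sel_all[cyc]) - 1L, 1L, mie,
                    p$k_gc, p$k_rect, p$p_rest, cfg$dm,
                    match(cfg$measure, c("f1", "peak", "potential")) - 1L,
                    match(cfg$baseline, c("increment", "cycle", "accepted")) - 1L,
                    as.integer(cfg$normalisation == "frozen"),
                    cfg$refresh_every,
                    cfg$log_every, net$idx_L - 1L, net$idx_R - 1L,
                    as.integer(done))
    m <- res$m
    out$best1 <- res$best
    lg <- as.data.frame(res$log)
    colnames(lg) <- c("cycle", "mean_best", "max_best", "accept_frac")
    logs[[1]] <- cbind(lg, phase = 1)
    out$state1 <- structure(list(m = m, m_ie = p$k_ie),
                            class = "binodev_modulation")
    phase2_done <- 0L
  } else {
    out$state1 <- NULL
    phase2_done <- done
  }
  cyc2_idx <- seq.int(phase2_done + 1L, cfg$n_cycles_phase2)
  cyc2 <- cfg$n_cycles_phase1 + cyc2_idx
  best2 <- if (phase == 2) best else matrix(-1, net$n_cort, 2)
  res <- dev_loop(m, net$A, eye_vec, local_vec, pre$HfL, pre$HfR,
                  pre$ITmL, pre$ITmR, pre$ITb, pre$shifts, best2,
                  as.integer(sel_all[cyc2]) - 1L, 2L,
                  m_ie_schedule(p, cfg, 2, cyc2_idx),
                  p$k_gc, p$k_rect, p$p_rest, cfg$dm,
                  match(cfg$measure, c("f1", "peak", "potential")) - 1L,
                  match(cfg$baseline, c("increment", "cycle", "accepted")) - 1L,
                  as.integer(cfg$normalisation == "frozen"),
                  cfg$refresh_every,
                  cfg$log_every, net$idx_L - 1L, net$idx_R - 1L,
                  as.integer(cfg$n_cycles_phase1 + phase2_done))
  out$state <- structure(list(m = res$m, m_ie = p$k_ie),
                         class = "binodev_modulation")
  out$best <- res$best[, 1]
  lg <- as.data.frame(res$log)
  colnames(lg) <- c("cycle", "mean_best", "max_best", "accept_frac")
  logs[[length(logs) + 1L]] <- cbind(lg, phase = 2)
  out$log <- do.call(rbind, logs)
  class(out) <- "binodev_development"
  out
}

# ---- pure-R reference implementation of one development cycle --------------

# Evaluate each excitatory neuron's maximum response over the development
# stimulus ensemble, recomputing everything from scratch (no caches).
# Used to cross-check the compiled incremental loop.
eval_responses_r <- function(net, pre, m, phase, eye_stim, m_ie, cfg,
                             m_den = m) {
  p <- net$params
  N <- cfg$n_time
  MA_L <- (m * net$A)[, net$idx_L, drop = FALSE]
  MA_R <- (m * net$A)[, net$idx_R, drop = FALSE]
  DL <- rowSums((m_den * net$A)[, net$idx_L, drop = FALSE])
  DR <- rowSums((m_den * net$A)[, net$idx_R, drop = FALSE])
  Dtot <- DL + DR
  nd <- length(pre$dirs)
  resp <- rep(0, net$n_cort)
  score <- function(P, IT) {
    E <- p$k_gc * P / Dtot - m_ie * IT
    switch(cfg$measure,
           f1 = p$k_rect * f1_of_rows(pmax(E, 0)),
           peak = apply(E, 1, max),
           potential = f1_of_rows(E))
  }
  for (d in seq_len(nd)) {
    if (phase == 1) {
      if (eye_stim == "L") {
        P <- MA_L %*% pre$HfL[, , d] + p$p_rest * DR
        resp <- pmax(resp, score(P, pre$ITmL[, , d]))
      } else {
        P <- MA_R %*% pre$HfR[, , d] + p$p_rest * DL
        resp <- pmax(resp, score(P, pre$ITmR[, , d]))
      }
    } else {
      FL <- MA_L %*% pre$HfL[, , d]
      FR <- MA_R %*% pre$HfR[, , d]
      for (o in seq_along(cfg$offsets)) {
        P <- FL + shift_cols(FR, pre$shifts[o])
        resp <- pmax(resp, score(P, pre$ITb[, , (d - 1) * length(cfg$offsets) + o]))
      }
    }
  }
  resp
}

#' One development cycle (reference implementation)
#'
#' Applies the accept/revert rule for a single selected channel, evaluating
#' responses from scratch. This is the slow reference path; \code{develop}
#' runs the same rule through an incremental compiled loop and the two are
#' required to agree in the test suite.
#'
#' @param net network.
#' @param pre output of the internal development precomputation (see
#'   \code{\link{develop}}); pass \code{NULL} to compute it here.
#' @param state list with \code{m} (modulation matrix) and \code{best}
#'   (cached per-neuron maximum responses: an n x 2 matrix in phase 1,
#'   one column per stimulated eye, a vector in phase 2; required — run
#'   an evaluation pass first for cycle 0).
#' @param channel_id selected channel (1-based).
#' @param phase 1 (monocular) or 2 (binocular).
#' @param m_ie current inhibitory-to-excitatory modulation.
#' @param config a \code{\link{development_config}}.
#' @return updated \code{state}.
#' @export
development_cycle <- function(net, pre, state, channel_id, phase, m_ie,
                              config) {
  cfg <- config
  if (is.null(pre)) pre <- precompute_development(net, cfg)
  if (cfg$baseline != "increment" && is.null(state$best)) {
    stop("uninitialised response cache: evaluate the stimulus ensemble ",
         "once (cycle 0) before running cycles")
  }
  m0 <- state$m
  m <- m0
  prev <- m[, channel_id]
  eye_stim <- net$channels$eye[channel_id]
  if (cfg$baseline == "increment") {
    base <- eval_responses_r(net, pre, m, phase, eye_stim, m_ie, cfg)
  } else {
    base <- if (phase == 1) {
      state$best[, if (eye_stim == "L") 1 else 2]
    } else {
      state$best
    }
  }
  m[, channel_id] <- pmin(prev + cfg$dm, 2)
  m_den <- if (cfg$normalisation == "frozen") m0 else m
  resp <- eval_responses_r(net, pre, m, phase, eye_stim, m_ie, cfg, m_den)
  accepted <- resp > base
  tie <- resp == base
  m[, channel_id] <- ifelse(tie, prev,
                            update_modulation(prev, accepted, cfg$dm))
  state$m <- m
  newbase <- switch(cfg$baseline,
                    increment = resp,
                    cycle = resp,
                    accepted = ifelse(accepted, resp, base))
  if (phase == 1) {
    if (is.null(state$best)) state$best <- matrix(0, length(newbase), 2)
    state$best[, if (eye_stim == "L") 1 else 2] <- newbase
  } else {
    state$best <- newbase
  }
  state
}
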