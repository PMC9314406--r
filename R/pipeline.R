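#' Scale presets
#'
#' Ready-made study configurations. \code{"full"} is the published scale:
#' a 10 x 10 deg field (10,202 channels), 16 directions, 5 offsets,
#' 50,000 + 75,000 cycles, central 6 x 6 deg analysis window. Full scale
#' takes hours on one core, so two reduced presets preserve the
#' channel-selection statistics (about 5 selections per channel in phase
#' 1, 7.5 in phase 2) at smaller fields: \code{"scaled"} (4.8 deg field,
#' 2,402 channels, 12,010 + 18,015 cycles, central 2 x 2 deg window) for
#' quantitative summaries, and \code{"desk"} (2.4 deg field, 626
#' channels, 8 directions, 3,130 + 4,695 cycles) for quick property
#' checks. \code{"test"} is a minimal geometry for unit tests.
#'
#' @param name preset name.
#' @return a run configuration list (see \code{\link{load_config}}).
#' @export
scale_preset <- function(name = c("full", "scaled", "desk", "test")) {
  name <- match.arg(name)
  base <- list(
    preset = name,
    field_width = 10, spacing = 0.2, jitter_sd = 0.1,
    params = list(),
    development = list(n_cycles_phase1 = 50000, n_cycles_phase2 = 75000,
                       n_directions = 16, n_offsets = 5, offset_range = 0.5,
                       contrast = 0.3, measure = "potential"),
    analysis = list(margin = 2, n_directions = 16, n_perm = 10000,
                    odi_contrast = 0.25, disparity_offsets = 16),
    seed = 1
  )
  n_chan_for <- function(w, s) {
    2 * ((floor(w / s + 1e-9) + 1)^2 + floor(w / s + 1e-9)^2)
  }
  switch(name,
    full = base,
    scaled = {
      base$field_width <- 4.8
      nc <- n_chan_for(4.8, 0.2)
      base$development$n_cycles_phase1 <- round(nc * 5)
      base$development$n_cycles_phase2 <- round(nc * 7.5)
      base$analysis$margin <- 1.4
      base
    },
    desk = {
      base$field_width <- 2.4
      nc <- n_chan_for(2.4, 0.2)
      base$development$n_cycles_phase1 <- round(nc * 5)
      base$development$n_cycles_phase2 <- round(nc * 7.5)
      base$development$n_directions <- 8
      base$analysis$margin <- 0.8
      base$analysis$n_perm <- 2000
      base
    },
    test = {
      base$field_width <- 1.6
      base$development$n_cycles_phase1 <- 300
      base$development$n_cycles_phase2 <- 450
      base$development$n_directions <- 8
      base$analysis$margin <- 0.5
      base$analysis$n_perm <- 500
      base
    })
}

config_template <- function() scale_preset("full")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills unspecified fields with the
#' full-scale defaults (or a named preset's), and validates it. Unknown
#' keys and out-of-range values are rejected with the offending field
#' names.
#'
#' @param path YAML file; an empty file yields the full-scale defaults.
#' @return validated configuration list of class \code{binodev_config}.
#' @export
load_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param x a (partial) configuration list.
#' @export
as_run_config <- function(x = list()) {
  cfg <- if (!is.null(x$preset)) scale_preset(x$preset) else config_template()
  merge_into <- function(base, over, path = "") {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) {
      stop("unknown configuration key(s): ",
           paste0(path, bad, collapse = ", "))
    }
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && nm != "params") {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]],
                                 paste0(path, nm, "."))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  x$preset <- NULL
  cfg <- merge_into(cfg, x)
  validate_config(cfg)
  structure(cfg, class = c("binodev_config", "list"))
}

validate_config <- function(cfg) {
  if (cfg$field_width <= 0) stop("config error: field_width must be positive")
  if (cfg$spacing <= 0) stop("config error: spacing must be positive")
  if (cfg$jitter_sd < 0) stop("config error: jitter_sd must be non-negative")
  if (cfg$analysis$margin < 0 ||
      2 * cfg$analysis$margin >= cfg$field_width) {
    stop("config error: analysis margin must leave a non-empty window")
  }
  # parameter overrides validated by model_params
  do.call(model_params, cfg$params)
  dv <- cfg$development
  do.call(development_config,
          c(dv[intersect(names(dv), names(formals(development_config)))]))
  invisible(cfg)
}

config_params <- function(cfg) do.call(model_params, cfg$params)

config_devconfig <- function(cfg) {
  dv <- cfg$development
  do.call(development_config,
          dv[intersect(names(dv), names(formals(development_config)))])
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Build a small deterministic model bundle
#'
#' Constructs the geometry and network for a named preset; used for
#' fixtures in tests and examples.
#'
#' @param preset preset name (see \code{\link{scale_preset}}).
#' @param seed master seed.
#' @return list: \code{config}, \code{net}, \code{params}.
#' @export
make_fixture <- function(preset = "test", seed = 1) {
  cfg <- scale_preset(preset)
  cfg$seed <- seed
  params <- config_params(cfg)
  ch <- make_channel_mosaic(cfg$field_width, cfg$spacing, cfg$jitter_sd,
                            seed = seed)
  net <- build_network(ch, params)
  list(config = cfg, net = net, params = params)
}

# Pearson correlation with a one-sided (positive) permutation test.
pearson_permutation <- function(x, y, n_perm = 10000) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  obs <- stats::cor(x, y)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    if (stats::cor(x, sample(y)) >= obs - 1e-15) cnt <- cnt + 1L
  }
  list(rho = obs, p_value = (cnt + 1) / (n_perm + 1), n = length(x))
}

# circular correlation that degrades to NA when too few map fits exist
safe_circular <- function(a, b, period = pi, n_perm = 0) {
  tryCatch(circular_correlation(a, b, period, n_perm),
           error = function(e) list(rho_c = NA_real_, p_value = NA_real_,
                                    n = sum(is.finite(a) & is.finite(b))))
}

#' Analyse a developed model
#'
#' Runs the standard battery on a \code{\link{develop}} result: per-eye
#' and binocular orientation maps at the end of each phase, interocular
#' congruence statistics (circular correlation, wrapped-difference SD),
#' tuning bandwidths, ocular dominance and monocularity, disparity tuning
#' and its spread, disparity-map periodicity, and contrast sensitivity.
#' All statistics are computed over the central analysis window.
#'
#' @param net network.
#' @param dev a \code{\link{develop}} result (phases 1 and 2).
#' @param margin analysis-window margin, deg.
#' @param n_directions directions for the analysis tuning curves.
#' @param n_perm permutations for the significance tests.
#' @param odi_contrast contrast for the ocular-dominance analysis.
#' @param disparity_offsets offsets spanning one period for disparity
#'   tuning.
#' @param seed seed for the permutation tests.
#' @param n_time samples per period.
#' @return list of class \code{binodev_analysis}; see the summary element
#'   for the headline statistics.
#' @export
analyze_development <- function(net, dev, margin = 2, n_directions = 16,
                                n_perm = 10000, odi_contrast = 0.25,
                                disparity_offsets = 16, seed = 1,
                                n_time = 64) {
  set.seed(seed_stream(seed, "analysis"))
  win <- analysis_window(net, margin)
  dirs <- direction_set(n_directions)
  p <- net$params

  tune <- function(state, eye) {
    orientation_tuning(net, state, eye, n_directions, neurons = win,
                       n_time = n_time)
  }
  # ---- phase-1 end: monocular maps --------------------------------------
  tL1 <- tune(dev$state1, "left")
  tR1 <- tune(dev$state1, "right")
  mapL1 <- orientation_map(tL1)
  mapR1 <- orientation_map(tR1)
  mismatch1 <- abs(wrap_half(mapL1$pref_ori - mapR1$pref_ori, pi)) * 180 / pi
  rho1 <- safe_circular(mapL1$pref_ori, mapR1$pref_ori, pi, n_perm)
  dom1_left <- mapL1$peak >= mapR1$peak
  hwhh1 <- ifelse(dom1_left, mapL1$hwhh_deg, mapR1$hwhh_deg)

  # ---- end of development ----------------------------------------------
  tL2 <- tune(dev$state, "left")
  tR2 <- tune(dev$state, "right")
  tB2 <- tune(dev$state, "binocular")
  mapL2 <- orientation_map(tL2)
  mapR2 <- orientation_map(tR2)
  mapB2 <- orientation_map(tB2)
  rho2 <- safe_circular(mapL2$pref_ori, mapR2$pref_ori, pi, n_perm)
  rhoBL <- safe_circular(mapB2$pref_ori, mapL2$pref_ori, pi, n_perm)
  iod <- interocular_difference_stats(mapL2$pref_ori, mapR2$pref_ori)
  dom2_left <- mapL2$peak >= mapR2$peak
  hwhh2 <- ifelse(dom2_left, mapL2$hwhh_deg, mapR2$hwhh_deg)

  od <- ocular_dominance(net, dev$state, odi_contrast, n_directions,
                         neurons = win, n_time = n_time)
  od_dev <- ocular_dominance(net, dev$state, p$contrast, n_directions,
                             neurons = win, n_time = n_time)
  cor_mm <- pearson_permutation(mismatch1, od$monocularity, n_perm)

  # preferred binocular direction (sampled set) for disparity/sensitivity
  pref_dir_idx <- apply(tB2$response, 1, which.max)
  pref_dir <- dirs[pref_dir_idx]
  disp <- disparity_tuning(net, dev$state, pref_dir, win,
                           n_offsets = disparity_offsets,
                           monocularity = od$monocularity, n_time = n_time)
  disp_ok <- !disp$unreliable & is.finite(disp$u_p)
  sd_disp <- if (sum(disp_ok) >= 2) stats::sd(disp$u_p[disp_ok]) else NA_real_

  # disparity map periodicity over the window grid
  nside <- round(sqrt(length(win)))
  per <- if (nside^2 == length(win)) {
    map_periodicity(matrix(disp$u_p, nside, nside),
                    p$cortical_spacing, p$mm_per_deg)
  } else {
    list(distance_deg = NA_real_, distance_mm = NA_real_, aperiodic = NA)
  }

  dom_eye <- ifelse(dom2_left, "L", "R")
  opt_dir <- dirs[ifelse(dom2_left,
                         apply(tL2$response, 1, which.max),
                         apply(tR2$response, 1, which.max))]
  sens <- contrast_sensitivity(net, dev$state, dom_eye, opt_dir, win,
                               n_time = n_time)
  dom_peak <- ifelse(dom2_left, mapL2$peak, mapR2$peak)
  responsive <- dom_peak >= stats::median(dom_peak)

  summary <- list(
    n_window = length(win),
    rho_c_phase1 = rho1$rho_c, p_phase1 = rho1$p_value,
    rho_c_end = rho2$rho_c, p_end = rho2$p_value,
    rho_c_binoc_left = rhoBL$rho_c,
    sd_ori_diff_deg = iod$sd_deg,
    hwhh_phase1_deg = mean(hwhh1, na.rm = TRUE),
    hwhh_end_deg = mean(hwhh2, na.rm = TRUE),
    mean_monocularity = mean(od$monocularity, na.rm = TRUE),
    cor_monocularity_mismatch = cor_mm$rho,
    p_monocularity_mismatch = cor_mm$p_value,
    sd_disparity_deg = sd_disp,
    disparity_period_deg = per$distance_deg,
    disparity_period_mm = per$distance_mm,
    sensitivity_mv_per_cu = mean(sens[responsive], na.rm = TRUE)
  )

  structure(list(
    window = win, directions = dirs,
    phase1 = list(map_left = mapL1, map_right = mapR1,
                  mismatch_deg = mismatch1, rho = rho1, hwhh_deg = hwhh1),
    final = list(map_left = mapL2, map_right = mapR2, map_binoc = mapB2,
                 rho = rho2, rho_binoc_left = rhoBL, iod = iod,
                 hwhh_deg = hwhh2, odi = od, odi_dev_contrast = od_dev,
                 disparity = disp, periodicity = per,
                 sensitivity = sens, responsive = responsive,
                 pref_dir = pref_dir),
    summary = summary
  ), class = "binodev_analysis")
}

#' @export
print.binodev_analysis <- function(x, ...) {
  s <- x$summary
  cat("binodev analysis (", s$n_window, " neurons in window)\n", sep = "")
  cat(sprintf("  interocular orientation correlation: %.3f (phase 1) -> %.3f (end)\n",
              s$rho_c_phase1, s$rho_c_end))
  cat(sprintf("  orientation difference SD: %.1f deg\n", s$sd_ori_diff_deg))
  cat(sprintf("  HWHH bandwidth: %.1f deg (phase 1), %.1f deg (end)\n",
              s$hwhh_phase1_deg, s$hwhh_end_deg))
  cat(sprintf("  preferred disparity SD: %.3f deg\n", s$sd_disparity_deg))
  cat(sprintf("  monocularity~mismatch correlation: %.3f (p = %.2g)\n",
              s$cor_monocularity_mismatch, s$p_monocularity_mismatch))
  cat(sprintf("  contrast sensitivity: %.1f mV/contrast-unit\n",
              s$sensitivity_mv_per_cu))
  invisible(x)
}

#' Run the full pipeline
#'
#' Geometry, two-phase development, and the analysis battery, from a run
#' configuration. When \code{out_dir} is given, writes the configuration
#' (with its hash), geometry and map CSVs, the development log and a
#' summary JSON; re-running with the same configuration and seed
#' reproduces every summary byte.
#'
#' @param config a configuration list (\code{\link{scale_preset}},
#'   \code{\link{load_config}} or \code{\link{as_run_config}}).
#' @param out_dir optional output directory.
#' @param seed master seed (defaults to the configuration's).
#' @param verbose progress messages.
#' @return list of class \code{binodev_run}: \code{net}, \code{dev},
#'   \code{analysis}, \code{summary}, \code{config}, \code{seed}.
#' @export
run_pipeline <- function(config = scale_preset("desk"), out_dir = NULL,
                         seed = NULL, verbose = FALSE) {
  cfg <- as_run_config(unclass(config))
  if (is.null(seed)) seed <- cfg$seed
  params <- config_params(cfg)
  ch <- make_channel_mosaic(cfg$field_width, cfg$spacing, cfg$jitter_sd,
                            seed = seed)
  net <- build_network(ch, params)
  devcfg <- config_devconfig(cfg)
  if (verbose) message("developing (", devcfg$n_cycles_phase1, " + ",
                       devcfg$n_cycles_phase2, " cycles)...")
  dev <- develop(net, devcfg, seed = seed, verbose = verbose)
  if (verbose) message("analysing...")
  an <- analyze_development(
    net, dev, margin = cfg$analysis$margin,
    n_directions = cfg$analysis$n_directions,
    n_perm = cfg$analysis$n_perm,
    odi_contrast = cfg$analysis$odi_contrast,
    disparity_offsets = cfg$analysis$disparity_offsets, seed = seed)
  out <- structure(list(net = net, dev = dev, analysis = an,
                        summary = an$summary, config = cfg, seed = seed),
                   class = "binodev_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  an <- run$analysis
  win <- an$window
  net <- run$net
  write_geometry_csv(net$channels, file.path(out_dir, "geometry.csv"))
  maps <- data.frame(
    neuron = win, x_deg = net$cortex$x[win], y_deg = net$cortex$y[win],
    ori_left_deg = an$final$map_left$pref_ori * 180 / pi,
    ori_right_deg = an$final$map_right$pref_ori * 180 / pi,
    ori_binoc_deg = an$final$map_binoc$pref_ori * 180 / pi,
    hwhh_deg = an$final$hwhh_deg,
    odi = an$final$odi$odi,
    monocularity = an$final$odi$monocularity,
    disparity_deg = an$final$disparity$u_p)
  utils::write.csv(maps, file.path(out_dir, "maps.csv"), row.names = FALSE)
  utils::write.csv(run$dev$log, file.path(out_dir, "devlog.csv"),
                   row.names = FALSE)
  summary <- c(list(seed = run$seed, config_hash = config_hash(cfg)),
               run$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.binodev_run <- function(x, ...) {
  cat("binodev pipeline run, seed ", x$seed, " (preset ",
      x$config$preset %||% "custom", ")\n", sep = "")
  print(x$analysis)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
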