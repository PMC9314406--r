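#' Model parameters
#'
#' Constructs the full parameter set of the model with published defaults
#' for the cat X-cell pathway under photopic conditions. All values can be
#' overridden by name.
#'
#' @details
#' The parameters and their units are:
#' \describe{
#'   \item{k_gc}{Geniculocortical gain (dimensionless), default 7.}
#'   \item{k_ie}{Inhibitory-excitatory gain (dimensionless), default 1.66.
#'     Sets the resting hyperpolarisation of excitatory cells,
#'     \code{k_gc * p_rest * (1 - k_ie)} (about -9 mV).}
#'   \item{k_rect}{Rectification constant converting generator potential to
#'     impulse rate, Hz/mV, default 7.2.}
#'   \item{k_sens}{Contrast sensitivity of the subcortical drive,
#'     mV/contrast-unit, default 62.}
#'   \item{p_rest}{Resting generator potential of ganglion cells, mV,
#'     default 1.9.}
#'   \item{tau}{Integration time constant of cones, inhibitory somas and
#'     excitatory cells, s, default 0.01.}
#'   \item{delta}{Half the on/off time-constant difference, s, default
#'     5e-4: off-centre stages integrate with \code{tau - delta} = 9.5 ms,
#'     on-centre with \code{tau + delta} = 10.5 ms, reproducing the ~1 ms
#'     latency advantage of off-dominated cortical responses.}
#'   \item{tau_inh}{Time constant of the inhibitory axon compartment, s,
#'     default 0.1.}
#'   \item{r_sub}{Radius of the subcortical convergence function, deg,
#'     default 0.4.}
#'   \item{r_cort}{Radius of cortical convergence (geniculocortical and
#'     inhibitory-to-excitatory), deg, default 0.95.}
#'   \item{contrast}{Default grating contrast (contrast-units), 0.3.}
#'   \item{sf}{Default grating spatial frequency, rad/deg,
#'     \code{2*pi*0.5} (0.5 cycles/deg).}
#'   \item{tf}{Default grating temporal frequency, rad/s, \code{2*pi*2}
#'     (2 Hz).}
#'   \item{cortical_spacing}{Cortical grid spacing, deg, default 0.2.}
#'   \item{mm_per_deg}{Cortical magnification used to express visual-field
#'     distance as cortical distance, mm/deg, default 0.625 (appropriate
#'     for the modelled eccentricity, 11 deg temporal).}
#' }
#'
#' @param ... named overrides of the defaults listed above.
#' @return An object of class \code{binodev_params} (a named list).
#' @examples
#' p <- model_params()
#' p$k_gc * p$p_rest * (1 - p$k_ie)  # resting excitatory potential, mV
#' @export
model_params <- function(...) {
  p <- list(
    k_gc  = 7,
    k_ie  = 1.66,
    k_rect = 7.2,
    k_sens = 62,
    p_rest = 1.9,
    tau    = 0.01,
    delta  = 5e-4,
    tau_inh = 0.1,
    r_sub  = 0.4,
    r_cort = 0.95,
    contrast = 0.3,
    sf = 2 * pi * 0.5,
    tf = 2 * pi * 2,
    cortical_spacing = 0.2,
    mm_per_deg = 1 / 1.6
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "binodev_params")
}

validate_params <- function(p) {
  pos <- c("k_gc", "k_ie", "k_rect", "k_sens", "p_rest", "tau", "tau_inh",
           "r_sub", "r_cort", "sf", "tf", "cortical_spacing", "mm_per_deg")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a positive finite scalar")
    }
  }
  if (!is.numeric(p$delta) || p$delta < 0) {
    stop("parameter 'delta' must be non-negative")
  }
  if (p$tau - p$delta <= 0) {
    stop("'tau - delta' must be positive (off-centre time constant)")
  }
  if (p$contrast < 0) stop("'contrast' must be non-negative")
  invisible(p)
}

#' @export
print.binodev_params <- function(x, ...) {
  cat("Model parameters (binodev):\n")
  for (nm in names(x)) cat(sprintf("  %-17s %g\n", nm, x[[nm]]))
  invisible(x)
}

# On/off subcortical time constants as a per-channel vector.
tau_n_for <- function(params, sign) {
  ifelse(sign == "off", params$tau - params$delta, params$tau + params$delta)
}

# Closed-form resting generator potentials of every stage (zero-contrast
# fixed point of the cascade with row-stochastic weights).
#' Resting fixed point of the network
#'
#' Closed-form generator potentials of every processing stage for a
#' zero-contrast stimulus, against which the time-domain integrator can be
#' checked. With row-stochastic weights each stage rests at its presynaptic
#' resting value: ganglion and geniculate cells rest at \code{p_rest}, the
#' inhibitory pathway at \code{k_gc * p_rest}, and the excitatory cell at
#' \code{k_gc * p_rest * (1 - m_ie)}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param m_ie inhibitory-to-excitatory modulation factor (1 at the start of
#'   development, \code{params$k_ie} from the end of the monocular phase).
#' @return Named list of resting potentials (mV) per stage.
#' @export
resting_state <- function(params, m_ie = params$k_ie) {
  list(
    cone = 0,
    bipolar = 0,
    ganglion = params$p_rest,
    geniculate = params$p_rest,
    soma = params$k_gc * params$p_rest,
    inh_axon = params$k_gc * params$p_rest,
    excitatory = params$k_gc * params$p_rest * (1 - m_ie)
  )
}
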