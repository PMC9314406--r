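#' Stimuli: drifting gratings and sparse-noise squares
#'
#' Stimuli enter the model through the subcortical driving function, the
#' cross-correlation of a unit-integral Gaussian convergence kernel of
#' radius \code{r_sub} with the stimulus. For drifting gratings the
#' cross-correlation has a closed form; for sparse-noise squares it is a
#' separable product of error-function differences. Both closed forms are
#' checked against brute-force quadrature in the test suite.
#'
#' @name stimuli
NULL

#' Drifting-grating specification
#'
#' @param contrast grating contrast (contrast-units). A disabled eye is
#'   expressed as contrast 0.
#' @param direction drift direction, radians in `[0, 2*pi)`.
#' @param sf spatial frequency, rad/deg.
#' @param tf temporal frequency, rad/s.
#' @param offset_right spatial offset of the right eye's grating along the
#'   motion axis, deg (simulated fixation offset; the left eye is never
#'   shifted).
#' @param eyes which eyes are stimulated: "both", "left" or "right".
#' @return A \code{grating_spec} list.
#' @export
grating_spec <- function(contrast = 0.3, direction = 0,
                         sf = 2 * pi * 0.5, tf = 2 * pi * 2,
                         offset_right = 0, eyes = c("both", "left", "right")) {
  eyes <- match.arg(eyes)
  if (sf < 0) stop("'sf' must be non-negative")
  if (contrast < 0) stop("'contrast' must be non-negative")
  structure(list(contrast = contrast, direction = direction %% (2 * pi),
                 sf = sf, tf = tf, offset_right = offset_right, eyes = eyes),
            class = "grating_spec")
}

#' Sparse-noise square specification
#'
#' @param x,y centre of the square, deg.
#' @param width side of the square, deg (receptive fields are mapped with
#'   1 deg squares).
#' @param contrast +1 (light) or -1 (dark).
#' @param onset,duration presentation window, s (default duration 0.05 s).
#' @return A \code{sparse_square_spec} list.
#' @export
sparse_square_spec <- function(x = 0, y = 0, width = 1, contrast = 1,
                               onset = 0, duration = 0.05) {
  if (width <= 0) stop("'width' must be positive")
  if (duration <= 0) stop("'duration' must be positive")
  structure(list(x = x, y = y, width = width, contrast = contrast,
                 onset = onset, duration = duration),
            class = "sparse_square_spec")
}

#' Rotate field coordinates onto the grating motion axis
#'
#' Rigid rotation taking (x, y) to (u, v), where u is distance along the
#' direction of motion.
#'
#' @param x,y visual-field coordinates, deg (vectorised).
#' @param direction drift direction, radians.
#' @return list with components \code{u} and \code{v}, deg.
#' @examples
#' rotate_to_motion_axis(1, 0, pi / 2)  # u = 0, v = -1
#' @export
rotate_to_motion_axis <- function(x, y, direction) {
  list(u = cos(direction) * x + sin(direction) * y,
       v = -sin(direction) * x + cos(direction) * y)
}

# erf via the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Grating driving function (closed form)
#'
#' Subcortical drive at a channel located at (x, y): the Gaussian kernel
#' attenuates the grating by \code{exp(-r_sub^2 sf^2 / 4)} and preserves
#' its phase, giving
#' \code{contrast * exp(-r_sub^2 sf^2/4) * cos(sf*(u + offset) - tf*t)}
#' with u the coordinate along the motion axis. A disabled eye returns 0.
#'
#' @param spec a \code{\link{grating_spec}}.
#' @param x,y channel location, deg (vectorised).
#' @param t time, s (scalar or vector; recycled against positions).
#' @param r_sub subcortical convergence radius, deg.
#' @param eye "L" or "R": selects the per-eye enable flag and offset.
#' @return drive in contrast-units.
#' @export
grating_drive <- function(spec, x, y, t, r_sub, eye = "L") {
  stopifnot(inherits(spec, "grating_spec"), r_sub > 0)
  if ((eye == "L" && spec$eyes == "right") ||
      (eye == "R" && spec$eyes == "left")) {
    return(rep(0, max(length(x), length(t))))
  }
  off <- if (eye == "R") spec$offset_right else 0
  u <- rotate_to_motion_axis(x, y, spec$direction)$u + off
  spec$contrast * exp(-r_sub^2 * spec$sf^2 / 4) *
    cos(spec$sf * u - spec$tf * t)
}

#' Sparse-square driving function (closed form)
#'
#' Cross-correlation of the unit-integral Gaussian kernel with a square of
#' uniform contrast: a separable product of error-function differences,
#' non-zero only within the presentation window.
#'
#' @param spec a \code{\link{sparse_square_spec}}.
#' @inheritParams grating_drive
#' @return drive in contrast-units.
#' @export
sparse_drive <- function(spec, x, y, t, r_sub) {
  stopifnot(inherits(spec, "sparse_square_spec"), r_sub > 0)
  g <- function(a) {
    0.5 * (erf((a + spec$width / 2) / r_sub) -
             erf((a - spec$width / 2) / r_sub))
  }
  spatial <- spec$contrast * g(spec$x - x) * g(spec$y - y)
  inside <- as.numeric(t >= spec$onset & t < spec$onset + spec$duration)
  spatial * inside
}

#' Evenly spaced drift directions
#'
#' @param n number of directions (covering the full 360 deg range).
#' @return directions in radians.
#' @export
direction_set <- function(n = 16) {
  if (n < 1) stop("'n' must be at least 1")
  (seq_len(n) - 1) * 2 * pi / n
}

#' Evenly spaced interocular fixation offsets
#'
#' @param n number of offsets (default 5).
#' @param range half-range, deg (offsets span `[-range, range]`).
#' @return offsets in deg, symmetric about 0.
#' @export
offset_set <- function(n = 5, range = 0.5) {
  if (n < 1) stop("'n' must be at least 1")
  if (n == 1) return(0)
  seq(-range, range, length.out = n)
}
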