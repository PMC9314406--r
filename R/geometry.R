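#' Subcortical channel mosaics and the cortical grid
#'
#' The retino-geniculate input to the model is a set of channels, each with
#' a single visual-field location shared by its cone, bipolar, ganglion and
#' geniculate cells. Off-centre channels sit on a square lattice centred in
#' the field; on-centre channels sit on a second lattice shifted by half a
#' spacing in x and y, so that its four innermost nodes are equidistant
#' from the field centre. Both lattices are jittered with independent
#' zero-mean Gaussian deviates, and the two eyes use distinct random
#' substreams so their mosaics are statistically independent.
#'
#' Coordinates are degrees of visual field, centre at (0,0), x rightward,
#' y upward. Jittered positions that fall outside the nominal field are
#' retained: the analysis window excludes the field margin anyway.
#'
#' @name channel_geometry
NULL

lattice_1d <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

lattice_xy <- function(n_side, spacing) {
  g <- lattice_1d(n_side, spacing)
  list(x = rep(g, times = n_side), y = rep(g, each = n_side))
}

check_grid_args <- function(field_width, spacing, jitter_sd = 0) {
  if (!is.numeric(field_width) || field_width <= 0) {
    stop("'field_width' must be positive")
  }
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be positive")
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    stop("'jitter_sd' must be non-negative")
  }
}

#' Place off-centre channels
#'
#' Off-centre channels form a \code{(floor(field_width/spacing)+1)^2}
#' square lattice centred on the field centre; each coordinate is then
#' perturbed by an independent Gaussian deviate of standard deviation
#' \code{jitter_sd}. Uses the current RNG state unless \code{seed} is
#' given.
#'
#' @param field_width width of the square visual field, deg.
#' @param spacing lattice spacing, deg.
#' @param jitter_sd SD of the positional jitter, deg.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns \code{x}, \code{y} (deg).
#' @examples
#' nrow(place_off_grid(10, 0.2, 0))  # 51 x 51 = 2601
#' @export
place_off_grid <- function(field_width, spacing, jitter_sd = 0, seed = NULL) {
  check_grid_args(field_width, spacing, jitter_sd)
  if (!is.null(seed)) set.seed(seed)
  n_side <- floor(field_width / spacing + 1e-9) + 1L
  g <- lattice_xy(n_side, spacing)
  n <- n_side^2
  data.frame(
    x = g$x + rnorm(n, 0, jitter_sd),
    y = g$y + rnorm(n, 0, jitter_sd)
  )
}

#' Place on-centre channels
#'
#' On-centre channels form a second lattice displaced by half a spacing in
#' both x and y relative to the off lattice, so that its four innermost
#' nodes are equally distant from the middle of the field. With the
#' default full-scale geometry this yields a
#' \code{floor(field_width/spacing)^2} lattice. Jitter as in
#' \code{\link{place_off_grid}}.
#'
#' @inheritParams place_off_grid
#' @return data.frame with columns \code{x}, \code{y} (deg).
#' @examples
#' nrow(place_on_grid(10, 0.2, 0))  # 50 x 50 = 2500
#' @export
place_on_grid <- function(field_width, spacing, jitter_sd = 0, seed = NULL) {
  check_grid_args(field_width, spacing, jitter_sd)
  if (!is.null(seed)) set.seed(seed)
  n_side <- floor(field_width / spacing + 1e-9)
  if (n_side < 1L) stop("'spacing' exceeds 'field_width': empty on-lattice")
  g <- lattice_xy(n_side, spacing)
  n <- n_side^2
  data.frame(
    x = g$x + rnorm(n, 0, jitter_sd),
    y = g$y + rnorm(n, 0, jitter_sd)
  )
}

# Fixed offsets fanning one master seed into named substreams, so a single
# integer reproduces the whole mosaic and the development sequence.
seed_stream <- function(seed, stream = c("geometry_L", "geometry_R",
                                         "selection", "analysis")) {
  stream <- match.arg(stream)
  off <- c(geometry_L = 1000003L, geometry_R = 2000003L,
           selection = 3000003L, analysis = 4000003L)[[stream]]
  as.integer(seed) + off
}

#' Generate the two-eye channel mosaic
#'
#' Builds the complete subcortical channel array for both eyes. Each eye's
#' jitter is drawn from its own substream derived from \code{seed} by a
#' fixed offset, so the left- and right-eye mosaics are independent but
#' jointly reproducible from one integer.
#'
#' @inheritParams place_off_grid
#' @param seed master integer seed.
#' @return data.frame of class \code{binodev_mosaic} with columns
#'   \code{eye} ("L"/"R"), \code{sign} ("off"/"on"), \code{x}, \code{y}
#'   (deg) and \code{channel_id}.
#' @examples
#' ch <- make_channel_mosaic(2, 0.2, 0.05, seed = 1)
#' table(ch$eye, ch$sign)
#' @export
make_channel_mosaic <- function(field_width = 10, spacing = 0.2,
                                jitter_sd = 0.1, seed = 1) {
  one_eye <- function(eye_seed, eye) {
    set.seed(eye_seed)
    off <- place_off_grid(field_width, spacing, jitter_sd)
    on <- place_on_grid(field_width, spacing, jitter_sd)
    data.frame(
      eye = eye,
      sign = rep(c("off", "on"), c(nrow(off), nrow(on))),
      x = c(off$x, on$x),
      y = c(off$y, on$y)
    )
  }
  ch <- rbind(one_eye(seed_stream(seed, "geometry_L"), "L"),
              one_eye(seed_stream(seed, "geometry_R"), "R"))
  ch$channel_id <- seq_len(nrow(ch))
  attr(ch, "field_width") <- field_width
  attr(ch, "spacing") <- spacing
  attr(ch, "jitter_sd") <- jitter_sd
  attr(ch, "seed") <- seed
  class(ch) <- c("binodev_mosaic", "data.frame")
  ch
}

#' Cortical cell grid
#'
#' Cortical neurons occupy the nodes of an unperturbed square grid centred
#' in the field, \code{(floor(field_width/spacing)+1)^2} nodes (so a
#' spacing equal to the field width gives a 2 x 2 grid). Each node hosts
#' one excitatory and one inhibitory neuron; the returned frame lists the
#' node positions once.
#'
#' @inheritParams place_off_grid
#' @param r_cort cortical convergence radius, deg; a warning is issued if
#'   the grid is too coarse relative to it (\code{spacing > r_cort/2}).
#' @return data.frame with columns \code{x}, \code{y} (deg).
#' @examples
#' nrow(cortical_grid(10, 0.2))  # 2601 nodes
#' @export
cortical_grid <- function(field_width, spacing = 0.2, r_cort = 0.95) {
  check_grid_args(field_width, spacing)
  if (spacing > r_cort / 2) {
    warning("cortical grid spacing exceeds r_cort/2; the grid undersamples ",
            "the convergence function")
  }
  n_side <- floor(field_width / spacing + 1e-9) + 1L
  g <- lattice_xy(n_side, spacing)
  data.frame(x = g$x, y = g$y)
}

#' @export
print.binodev_mosaic <- function(x, ...) {
  cat(sprintf("Channel mosaic: %d channels, %g x %g deg field\n",
              nrow(x), attr(x, "field_width"), attr(x, "field_width")))
  print(table(eye = x$eye, sign = x$sign))
  invisible(x)
}

#' Write a channel mosaic or cortical grid to CSV
#'
#' @param x a \code{binodev_mosaic} or cortical grid data.frame.
#' @param path output file path.
#' @export
write_geometry_csv <- function(x, path) {
  cols <- intersect(c("eye", "sign", "x", "y", "channel_id"), names(x))
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE)
  invisible(path)
}
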