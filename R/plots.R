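#' Polar plot of a direction tuning curve
#'
#' @param x a \code{\link{orientation_tuning}} result.
#' @param neuron row index into the tuning matrix.
#' @param ... passed to \code{plot}.
#' @export
plot.binodev_tuning <- function(x, neuron = 1, ...) {
  r <- x$response[neuron, ]
  th <- c(x$directions, x$directions[1])
  r <- c(r, r[1])
  graphics::plot(r * cos(th), r * sin(th), type = "o", asp = 1,
                 xlab = "F1 (Hz)", ylab = "F1 (Hz)",
                 main = sprintf("neuron %d, %s eye(s)",
                                x$neurons[neuron], x$eye), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
}

#' Image of a receptive-field map
#'
#' @param x a \code{\link{map_receptive_field}} result.
#' @param ... passed to \code{image}.
#' @export
plot.binodev_rf <- function(x, ...) {
  graphics::image(x$x, x$y, t(x$value), asp = 1,
                  xlab = "x (deg)", ylab = "y (deg)",
                  main = sprintf("RF, neuron %d, eye %s", x$neuron, x$eye),
                  ...)
}
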