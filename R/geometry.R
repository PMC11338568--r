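#' Corridor geometry
#'
#' Describes the experimental corridor in metres. The corridor long axis is x;
#' the measurement area occupies `x` in `[0, meas_length]`, `y` in
#' `[0, meas_width]`. Rightward-moving pedestrians travel toward increasing x
#' and enter the measurement area at `x = 0`. A buffer zone of
#' `buffer_length` and a waiting area of `waiting_length` lie beyond each end
#' of the measurement area. The central window (used for lane counting) is a
#' `central_window[1] x central_window[2]` rectangle centred in the
#' measurement area.
#'
#' @param meas_length Length of the measurement area along x (m).
#' @param meas_width Corridor width along y (m).
#' @param central_window Numeric length-2: extent (x, y) of the central
#'   counting window (m); must fit inside the measurement area.
#' @param buffer_length Length of each buffer zone (m).
#' @param waiting_length Length of each waiting area (m).
#' @return An object of class `corridor_geometry`.
#' @examples
#' geom <- corridor_geometry()
#' geom$meas_length
#' @export
corridor_geometry <- function(meas_length = 10, meas_width = 3,
                              central_window = c(3, 3),
                              buffer_length = 1.2, waiting_length = 8.4) {
  stopifnot(length(central_window) == 2)
  vals <- c(meas_length, meas_width, central_window, buffer_length, waiting_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all corridor dimensions must be finite and > 0")
  if (central_window[1] > meas_length || central_window[2] > meas_width)
    stop("central window must fit inside the measurement area")
  structure(list(meas_length = meas_length, meas_width = meas_width,
                 central_window = central_window,
                 buffer_length = buffer_length,
                 waiting_length = waiting_length),
            class = "corridor_geometry")
}

#' @export
print.corridor_geometry <- function(x, ...) {
  cat(sprintf("corridor: measurement %g x %g m, central window %g x %g m,\n",
              x$meas_length, x$meas_width,
              x$central_window[1], x$central_window[2]))
  cat(sprintf("  buffer %g m, waiting area %g m at each end\n",
              x$buffer_length, x$waiting_length))
  invisible(x)
}

# x-range of the central counting window
central_window_x <- function(geometry) {
  cx <- geometry$meas_length / 2
  c(cx - geometry$central_window[1] / 2, cx + geometry$central_window[1] / 2)
}

# y-range of the central counting window
central_window_y <- function(geometry) {
  cy <- geometry$meas_width / 2
  c(cy - geometry$central_window[2] / 2, cy + geometry$central_window[2] / 2)
}

# is (x, y) inside the measurement area?
in_measurement_area <- function(x, y, geometry) {
  x >= 0 & x <= geometry$meas_length & y >= 0 & y <= geometry$meas_width
}

# is (x, y) inside the central window?
in_central_window <- function(x, y, geometry) {
  wx <- central_window_x(geometry); wy <- central_window_y(geometry)
  x >= wx[1] & x <= wx[2] & y >= wy[1] & y <= wy[2]
}
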