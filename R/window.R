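#' Square observation window
#'
#' The study region is a square `[0, side_length]^2` with the origin at
#' (0, 0). All coordinates are in miles, areas in square miles. The default
#' geometry used throughout the package is a square of 3,000,000 mi^2
#' (side `sqrt(3e6)` ~ 1732.05 mi), roughly the area of the continental US.
#'
#' @param side_length Side of the square in miles; must be a single positive
#'   finite number.
#' @return An object of class `kdiff_window` with elements `side_length` and
#'   `area` (`side_length^2`).
#' @examples
#' w <- square_window(sqrt(3e6))
#' w$area
#' @export
square_window <- function(side_length) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0) {
    stop("`side_length` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(side_length = as.numeric(side_length),
         area = as.numeric(side_length)^2),
    class = "kdiff_window"
  )
}

#' @export
print.kdiff_window <- function(x, ...) {
  cat(sprintf("square window [0, %.4f]^2 mi (area %.1f mi^2)\n",
              x$side_length, x$area))
  invisible(x)
}

#' Distance from points to the window boundary
#'
#' Used by the border (reduced-sample) edge correction: a point is an
#' eligible center at range `h` only when its boundary distance exceeds `h`.
#'
#' @param window A [square_window()].
#' @param x,y Coordinate vectors (miles), inside the window.
#' @return Numeric vector of distances to the nearest edge.
#' @export
boundary_distance <- function(window, x, y) {
  stopifnot(inherits(window, "kdiff_window"))
  s <- window$side_length
  pmin(x, y, s - x, s - y)
}

#' @keywords internal
in_window <- function(window, x, y) {
  s <- window$side_length
  x >= 0 & x <= s & y >= 0 & y <= s
}
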