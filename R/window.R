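#' Rectangular observation window
#'
#' Construct a rectangular plot window \code{[0, Lx] x [0, Ly]} with the
#' origin at the south-west corner, coordinates in metres.
#'
#' @param Lx east-west extent (m).
#' @param Ly north-south extent (m).
#' @return An object of class \code{plot_window} with fields \code{Lx},
#'   \code{Ly} and \code{area}.
#' @export
plot_window <- function(Lx, Ly) {
  stopifnot(is.numeric(Lx), is.numeric(Ly), length(Lx) == 1, length(Ly) == 1)
  if (!is.finite(Lx) || !is.finite(Ly) || Lx <= 0 || Ly <= 0)
    stop("window extents must be positive and finite", call. = FALSE)
  structure(list(Lx = as.numeric(Lx), Ly = as.numeric(Ly),
                 area = as.numeric(Lx) * as.numeric(Ly)),
            class = "plot_window")
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("rectangular window [0, %g] x [0, %g] m (area %g m^2)\n",
              x$Lx, x$Ly, x$area))
  invisible(x)
}

#' Planar point pattern in a rectangular window
#'
#' @param x,y point coordinates (m), equal length.
#' @param window a \code{\link{plot_window}}.
#' @param check verify that all points lie inside the window.
#' @return An object of class \code{point_pattern}: list with \code{x},
#'   \code{y}, \code{n}, \code{window} and overall intensity
#'   \code{lambda = n / area} (points per m^2).
#' @export
point_pattern <- function(x, y, window, check = TRUE) {
  stopifnot(inherits(window, "plot_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (check && length(x)) {
    bad <- x < 0 | x > window$Lx | y < 0 | y > window$Ly | !is.finite(x) | !is.finite(y)
    if (any(bad))
      stop(sprintf("%d point(s) outside the window", sum(bad)), call. = FALSE)
  }
  structure(list(x = x, y = y, n = length(x), window = window,
                 lambda = length(x) / window$area),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in [0, %g] x [0, %g] m (lambda = %.3g /m^2)\n",
              x$n, x$window$Lx, x$window$Ly, x$lambda))
  invisible(x)
}
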