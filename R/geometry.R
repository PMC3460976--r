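## Exact disc/annulus -- rectangle intersection areas.
##
## All edge correction in the pcf estimators goes through these closed forms;
## they are checked against Monte-Carlo area estimates in the test suite.

## Area of {x^2 + y^2 <= r^2} intersected with [0, w] x [0, h], w, h >= 0.
## Vectorised over all arguments (recycled to a common length).
disc_quadrant_area <- function(w, h, r) {
  n <- max(length(w), length(h), length(r))
  w <- rep_len(pmax(w, 0), n)
  h <- rep_len(pmax(h, 0), n)
  r <- rep_len(pmax(r, 0), n)
  w <- pmin(w, r)
  h <- pmin(h, r)
  out <- w * h
  idx <- which(w * w + h * h > r * r & r > 0)
  if (length(idx)) {
    wi <- w[idx]; hi <- h[idx]; ri <- r[idx]
    yw <- sqrt(pmax(ri * ri - wi * wi, 0))
    ## antiderivative of sqrt(r^2 - y^2)
    Fint <- function(y, r) 0.5 * (y * sqrt(pmax(r * r - y * y, 0)) +
                                    r * r * asin(pmin(1, pmax(-1, y / r))))
    out[idx] <- wi * yw + Fint(hi, ri) - Fint(yw, ri)
  }
  out
}

#' Area of a disc clipped to a rectangular window
#'
#' Exact area of the disc of radius \code{r} centred at \code{(cx, cy)}
#' intersected with the window \code{[0, Lx] x [0, Ly]}, by signed
#' decomposition into quadrant rectangles (closed-form circular-segment
#' geometry; no numerical integration). Vectorised over centres and radii.
#'
#' @param cx,cy disc centre coordinates (m).
#' @param r disc radius (m), \code{r >= 0}.
#' @param window a \code{\link{plot_window}}.
#' @return numeric vector of areas (m^2).
#' @export
disc_rect_area <- function(cx, cy, r, window) {
  stopifnot(inherits(window, "plot_window"))
  G <- function(x, y, r) sign(x) * sign(y) * disc_quadrant_area(abs(x), abs(y), r)
  G(window$Lx - cx, window$Ly - cy, r) -
    G(-cx, window$Ly - cy, r) -
    G(window$Lx - cx, -cy, r) +
    G(-cx, -cy, r)
}

#' Edge-corrected annulus area inside a rectangular window
#'
#' Area of the ring \code{r - w/2 <= |u - center| < r + w/2} clipped to the
#' window, used to edge-correct ring counts in the pair-correlation
#' estimators. Exact (closed-form disc-rectangle geometry).
#'
#' @param cx,cy ring centre coordinates (m); must lie inside the window.
#' @param r ring radius (m).
#' @param w ring width (m); requires \code{r - w/2 >= 0}.
#' @param window a \code{\link{plot_window}}.
#' @return numeric vector of areas (m^2).
#' @export
annulus_area_in_window <- function(cx, cy, r, w, window) {
  stopifnot(inherits(window, "plot_window"))
  if (any(r - w / 2 < -1e-12))
    stop("inner radius r - w/2 must be nonnegative", call. = FALSE)
  if (any(cx < 0 | cx > window$Lx | cy < 0 | cy > window$Ly))
    stop("annulus centre outside the window", call. = FALSE)
  disc_rect_area(cx, cy, r + w / 2, window) -
    disc_rect_area(cx, cy, pmax(r - w / 2, 0), window)
}
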