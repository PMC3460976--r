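#' Closed-form Thomas-process pair-correlation function
#'
#' \code{g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 rho)} for a
#' Thomas cluster process with parent intensity \code{rho} (per m^2) and
#' Gaussian offspring dispersion \code{sigma} (m).
#'
#' @param r distances (m).
#' @param sigma offspring dispersion (m).
#' @param rho parent intensity (per m^2).
#' @export
thomas_pcf <- function(r, sigma, rho) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * rho)
}

#' Least-squares Thomas-process fit to an estimated pcf
#'
#' Minimum-contrast recovery of \code{sigma} and \code{rho} from a
#' pair-correlation estimate, by Nelder-Mead on log-parameters (robust to
#' the very different scales of the two parameters).
#'
#' @param g estimated pair-correlation values per bin (NAs dropped).
#' @param bins the \code{\link{distance_bins}} of the estimate.
#' @param init optional starting values \code{c(sigma, rho)}.
#' @return list with \code{sigma}, \code{rho}, \code{value} (residual sum
#'   of squares).
#' @export
fit_thomas_pcf <- function(g, bins, init = NULL) {
  ok <- is.finite(g)
  r <- bins$centers[ok]; gv <- g[ok]
  if (is.null(init)) {
    amp <- max(gv[1] - 1, 0.5)
    sig0 <- max(r[which(gv - 1 < amp / 2)[1]] %||% 5, 1) / 1.177  # half-decay
    init <- c(sig0, 1 / (4 * pi * sig0^2 * amp))
  }
  obj <- function(lp) {
    s <- exp(lp[1]); rho <- exp(lp[2])
    sum((gv - thomas_pcf(r, s, rho))^2)
  }
  o <- stats::optim(log(init), obj, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-10))
  list(sigma = exp(o$par[1]), rho = exp(o$par[2]), value = o$value)
}
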