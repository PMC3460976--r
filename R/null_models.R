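## Null-model simulation, Monte-Carlo envelopes and the goodness-of-fit
## rank test.

#' Simulate complete spatial randomness
#'
#' \code{n} points independently uniform over the window (a binomial
#' process, i.e. homogeneous Poisson conditioned on \code{n}).
#'
#' @param n number of points, >= 0.
#' @param window a \code{\link{plot_window}}.
#' @param seed optional RNG seed (leave \code{NULL} to use the current RNG
#'   stream).
#' @return a \code{\link{point_pattern}}.
#' @export
simulate_csr <- function(n, window, seed = NULL) {
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  point_pattern(stats::runif(n, 0, window$Lx), stats::runif(n, 0, window$Ly),
                window, check = FALSE)
}

#' Simulate a heterogeneous Poisson pattern from an intensity surface
#'
#' Places \code{n} points by sampling grid cells with probability
#' proportional to \code{lambda x cell area}, then uniformly within each
#' cell: an inhomogeneous Poisson process conditioned on the point count,
#' which keeps null patterns directly comparable to the data.
#'
#' @param surface an \code{intensity_surface}.
#' @param n number of points.
#' @param seed optional RNG seed.
#' @return a \code{\link{point_pattern}}.
#' @export
simulate_hpp <- function(surface, n, seed = NULL) {
  stopifnot(inherits(surface, "intensity_surface"))
  if (all(surface$lambda <= 0)) stop("intensity surface is identically zero",
                                     call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ncell <- length(surface$lambda)
  cells <- sample.int(ncell, n, replace = TRUE, prob = c(surface$lambda))
  nx <- nrow(surface$lambda)
  ix <- ((cells - 1L) %% nx) + 1L
  iy <- ((cells - 1L) %/% nx) + 1L
  half <- surface$cell / 2
  w <- surface$window
  x <- pmin(surface$xcenters[ix] + stats::runif(n, -half, half), w$Lx)
  y <- pmin(surface$ycenters[iy] + stats::runif(n, -half, half), w$Ly)
  point_pattern(pmax(x, 0), pmax(y, 0), w, check = FALSE)
}

#' Pointwise Monte-Carlo simulation envelopes
#'
#' Per distance bin, the lower/upper envelope is the k-th smallest/largest
#' simulated value; with \code{m} simulations the nominal pointwise
#' two-sided level is \code{2k / (m + 1)} (0.05 for k = 5, m = 199).
#'
#' @param observed numeric vector of the observed summary function per bin
#'   (e.g. column \code{g} of a \code{pcf_estimate}).
#' @param null_fns matrix of simulated summary functions, bins x
#'   simulations, on the same bins.
#' @param k envelope rank.
#' @return data frame: observed, lower, upper, flag in
#'   {above, below, inside}; attributes \code{n_simulations}, \code{k},
#'   \code{alpha}.
#' @export
envelopes <- function(observed, null_fns, k = 5) {
  null_fns <- as.matrix(null_fns)
  if (length(observed) != nrow(null_fns))
    stop("observed and simulated functions on different bins", call. = FALSE)
  m <- ncol(null_fns)
  if (m < 2 * k) stop("need at least 2k simulations", call. = FALSE)
  srt <- apply(null_fns, 1, sort, na.last = TRUE)  # m x bins
  lower <- srt[k, ]
  upper <- srt[m - k + 1, ]
  flag <- ifelse(is.na(observed) | is.na(lower), NA_character_,
                 ifelse(observed > upper, "above",
                        ifelse(observed < lower, "below", "inside")))
  structure(data.frame(observed = observed, lower = lower, upper = upper,
                       flag = flag, stringsAsFactors = FALSE),
            n_simulations = m, k = k, alpha = 2 * k / (m + 1),
            class = c("envelope_result", "data.frame"))
}

#' Goodness-of-fit rank test over a distance interval
#'
#' Loosmore-Ford style test guarding against simultaneous inference across
#' bins: for the observed function and every simulation, sum over bins in
#' the interval the squared deviation from the mean of all other functions
#' (leave-one-out, the observed included in the pool); the p-value is the
#' add-one rank of the observed statistic, ties counted as extreme.
#'
#' @param observed numeric vector, observed summary function per bin.
#' @param null_fns bins x simulations matrix.
#' @param bins the \code{\link{distance_bins}} the functions live on.
#' @param interval distance interval (m) over which to sum.
#' @return list: \code{interval}, \code{u0}, \code{u_sim}, \code{p},
#'   \code{n_simulations}.
#' @export
gof_test <- function(observed, null_fns, bins, interval = c(0, 30)) {
  null_fns <- as.matrix(null_fns)
  m <- ncol(null_fns)
  if (m < 19) stop("need at least 19 simulations", call. = FALSE)
  sel <- bins$centers >= interval[1] & bins$centers <= interval[2]
  if (!any(sel)) stop("no bins inside the interval", call. = FALSE)
  all_fns <- cbind(observed, null_fns)[sel, , drop = FALSE]
  ok <- stats::complete.cases(all_fns)  # drop bins undefined anywhere, pairwise
  all_fns <- all_fns[ok, , drop = FALSE]
  if (!nrow(all_fns)) stop("no defined bins inside the interval", call. = FALSE)
  tot <- rowSums(all_fns)
  u <- vapply(seq_len(m + 1), function(i) {
    mean_others <- (tot - all_fns[, i]) / m
    sum((all_fns[, i] - mean_others)^2)
  }, numeric(1))
  p <- (1 + sum(u[-1] >= u[1])) / (m + 1)
  list(interval = interval, u0 = u[1], u_sim = u[-1], p = p,
       n_simulations = m)
}
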