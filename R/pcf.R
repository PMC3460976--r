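#' Distance bins for ring statistics
#'
#' Rings of width \code{width} with centres \code{r_k}. The defaults follow
#' the analysis convention used throughout the package: 2 m wide rings with
#' centres at 1, 3, 5, ... up to \code{r_max} (matching a 2 m spatial
#' resolution). Bins are half-open, \code{[r - w/2, r + w/2)}.
#'
#' @param r_max largest ring outer radius (m).
#' @param width ring width \code{dr} (m).
#' @param centers optional explicit bin centres; overrides \code{r_max}.
#' @return object of class \code{distance_bins}: list with \code{centers},
#'   \code{width}, \code{lo}, \code{hi}.
#' @export
distance_bins <- function(r_max = 50, width = 2, centers = NULL) {
  if (is.null(centers))
    centers <- seq(width / 2, r_max - width / 2, by = width)
  centers <- as.numeric(centers)
  if (any(diff(centers) <= 0)) stop("bin centers must be strictly increasing", call. = FALSE)
  lo <- centers - width / 2
  hi <- centers + width / 2
  if (any(lo < -1e-12)) stop("bin lower edges must be >= 0", call. = FALSE)
  structure(list(centers = centers, width = width, lo = pmax(lo, 0), hi = hi),
            class = "distance_bins")
}

## Per-focal-point ring counts: C[i, k] = #(targets with d(focal_i, .) in bin k).
## dmat is the focal x target distance matrix with self-distances already
## masked (set negative) for the univariate case.
ring_counts <- function(dmat, bins) {
  n <- nrow(dmat)
  K <- length(bins$centers)
  contiguous <- K == 1 || all(abs(bins$lo[-1] - bins$hi[-K]) < 1e-9)
  if (contiguous) {
    ## one findInterval pass over all focal-target distances
    idx <- findInterval(dmat, c(bins$lo[1], bins$hi))
    keep <- which(idx >= 1 & idx <= K)
    focal <- (keep - 1L) %% n + 1L
    return(matrix(tabulate(focal + (idx[keep] - 1L) * n, nbins = n * K), n, K))
  }
  C <- matrix(0L, n, K)
  for (k in seq_len(K))
    C[, k] <- .rowSums(dmat >= bins$lo[k] & dmat < bins$hi[k], n, ncol(dmat))
  C
}

## Edge-corrected ring areas A[i, k] for focal points (x, y).
## All 2K edge radii are evaluated in a single vectorised call.
ring_areas <- function(x, y, bins, window) {
  K <- length(bins$centers)
  n <- length(x)
  radii <- c(bins$lo, bins$hi)
  D <- matrix(disc_rect_area(rep(x, times = 2 * K), rep(y, times = 2 * K),
                             rep(radii, each = n), window),
              n, 2 * K)
  D[, K + seq_len(K), drop = FALSE] - D[, seq_len(K), drop = FALSE]
}

## Mean ring density over focal points; zero-corrected-area rings are
## excluded from the average (not counted as zero). All-zero bins give NA.
ring_mean_density <- function(C, A) {
  R <- C / A
  R[A <= 0] <- NA_real_
  O <- colMeans(R, na.rm = TRUE)
  O[is.nan(O)] <- NA_real_
  O
}

pcf_result <- function(bins, O, lambda_target, pair_count, type, n1, n2) {
  structure(data.frame(r = bins$centers, g = O / lambda_target, O = O,
                       pair_count = pair_count),
            bins = bins, type = type, n1 = n1, n2 = n2,
            lambda = lambda_target,
            class = c("pcf_estimate", "data.frame"))
}

#' Univariate pair-correlation function
#'
#' Ring-count estimator of the neighbourhood density \code{O(r)} (mean
#' density of further points of the pattern in rings of radius \code{r} and
#' width \code{dr} centred on the points) and of the pair-correlation
#' function \code{g(r) = O(r) / lambda}. Ring areas are clipped to the
#' window exactly (closed-form disc-rectangle geometry), which removes edge
#' bias in a rectangular plot. \code{g = 1} under complete spatial
#' randomness; \code{g > 1} indicates aggregation, \code{g < 1} regularity.
#'
#' @param pattern a \code{\link{point_pattern}} with at least 2 points.
#' @param bins a \code{\link{distance_bins}}.
#' @return a \code{pcf_estimate} data frame with columns \code{r}, \code{g},
#'   \code{O} (per m^2) and \code{pair_count} (raw ordered pairs per bin).
#'   Bins whose corrected area is zero for every point yield \code{NA}.
#' @export
pcf_univariate <- function(pattern, bins = distance_bins()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(bins, "distance_bins"))
  n <- pattern$n
  if (n < 2) stop("need at least 2 points to estimate the pcf", call. = FALSE)
  dmat <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  diag(dmat) <- -1  # exclude self-pairs from every bin
  C <- ring_counts(dmat, bins)
  A <- ring_areas(pattern$x, pattern$y, bins, pattern$window)
  pcf_result(bins, ring_mean_density(C, A), pattern$lambda, colSums(C),
             "univariate", n, n)
}

#' Bivariate (cross) pair-correlation function
#'
#' Mean density of pattern-2 points in rings around pattern-1 points,
#' edge-corrected as in \code{\link{pcf_univariate}}, normalised by the
#' intensity of pattern 2: \code{g12(r) = O12(r) / lambda2}. Not symmetric
#' in its arguments; compute \code{g21} by swapping them.
#'
#' @param pattern1 focal \code{\link{point_pattern}} (rings centred here).
#' @param pattern2 target \code{\link{point_pattern}}, same window.
#' @param bins a \code{\link{distance_bins}}.
#' @return a \code{pcf_estimate} data frame (see \code{\link{pcf_univariate}}).
#' @export
pcf_bivariate <- function(pattern1, pattern2, bins = distance_bins()) {
  stopifnot(inherits(pattern1, "point_pattern"), inherits(pattern2, "point_pattern"))
  if (pattern1$window$Lx != pattern2$window$Lx ||
      pattern1$window$Ly != pattern2$window$Ly)
    stop("patterns must share a window", call. = FALSE)
  if (pattern1$n < 1 || pattern2$n < 1)
    stop("both patterns must be non-empty", call. = FALSE)
  dmat <- sqrt(outer(pattern1$x, pattern2$x, "-")^2 +
                 outer(pattern1$y, pattern2$y, "-")^2)
  C <- ring_counts(dmat, bins)
  A <- ring_areas(pattern1$x, pattern1$y, bins, pattern1$window)
  pcf_result(bins, ring_mean_density(C, A), pattern2$lambda, colSums(C),
             "bivariate", pattern1$n, pattern2$n)
}
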