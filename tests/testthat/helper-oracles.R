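# Independent oracles used across the suite. Deliberately naive: scalar
# loops and direct formulas, sharing no code path with the package
# estimators they check.

# area of one circular segment cut from a disc of radius r by a chord at
# distance d from the centre
segment_area <- function(r, d) {
  if (d >= r) return(0)
  r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
}

# Monte-Carlo area of an annulus clipped to [0,Lx]x[0,Ly]
mc_annulus_area <- function(cx, cy, r, w, Lx, Ly, n = 1e6) {
  px <- runif(n, 0, Lx); py <- runif(n, 0, Ly)
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  inside <- d >= r - w / 2 & d < r + w / 2
  list(area = mean(inside) * Lx * Ly,
       se = sd(inside) / sqrt(n) * Lx * Ly)
}

# naive pair-correlation estimator: double loops, per-point ring areas via
# the package's exact geometry but assembled scalar-by-scalar
brute_pcf <- function(x1, y1, x2, y2, window, centers, width,
                      univariate = FALSE) {
  n1 <- length(x1)
  g <- O <- numeric(length(centers))
  lam2 <- length(x2) / window$area
  for (k in seq_along(centers)) {
    lo <- centers[k] - width / 2; hi <- centers[k] + width / 2
    dens <- numeric(n1)
    for (i in seq_len(n1)) {
      cnt <- 0
      for (j in seq_along(x2)) {
        if (univariate && i == j) next
        d <- sqrt((x1[i] - x2[j])^2 + (y1[i] - y2[j])^2)
        if (d >= lo && d < hi) cnt <- cnt + 1
      }
      a <- annulus_area_in_window(x1[i], y1[i], centers[k], width, window)
      dens[i] <- cnt / a
    }
    O[k] <- mean(dens)
    g[k] <- O[k] / lam2
  }
  list(r = centers, g = g, O = O)
}

# quadrat-count chi-square uniformity check, returns p-value
quadrat_chisq_p <- function(pattern, nx = 5, ny = 4) {
  qx <- pmin(floor(pattern$x / (pattern$window$Lx / nx)), nx - 1)
  qy <- pmin(floor(pattern$y / (pattern$window$Ly / ny)), ny - 1)
  counts <- tabulate(qx + nx * qy + 1, nbins = nx * ny)
  suppressWarnings(stats::chisq.test(counts)$p.value)
}

# minimal pair_record-shaped list for classifier unit tests
fake_pair_record <- function(r, flags, gof_p, label = NULL) {
  structure(list(sp1 = "A", sp2 = "B", stage = "sapling", skipped = FALSE,
                 pcf = data.frame(r = r, g = 1),
                 envelope = data.frame(observed = 1, lower = 0, upper = 2,
                                       flag = flags),
                 gof = list(p = gof_p), label = label),
            class = "pair_record")
}

# sequential random sequential-adsorption pattern with hard-core distance
rsa_pattern <- function(n, window, hard_core, max_tries = 1e5) {
  xs <- numeric(0); ys <- numeric(0); tries <- 0
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1
    px <- runif(1, 0, window$Lx); py <- runif(1, 0, window$Ly)
    if (!length(xs) || min((xs - px)^2 + (ys - py)^2) >= hard_core^2) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  point_pattern(xs, ys, window)
}
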