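test_that("three-point pattern reproduces the hand computation", {
  w <- plot_window(100, 100)
  p <- point_pattern(c(10, 20, 50), c(10, 10, 50), w)
  bins <- distance_bins(centers = 10, width = 2)
  est = pcf_univariate(p, bins)
  # one ordered pair in each direction between the two 10 m-apart points;
  # clipped annulus areas from closed-form segment geometry: the ring at
  # (10,10) overruns two edges, the ring at (20,10) only one, the ring at
  # (50,50) none
  a1 <- pi * (11^2 - 9^2) - 2 * segment_area(11, 10)
  a2 <- pi * (11^2 - 9^2) - segment_area(11, 10)
  a_mid <- annulus_area_in_window(50, 50, 10, 2, w)  # interior: 40 pi
  expect_equal(a_mid, 40 * pi, tolerance = 1e-12)
  O_hand <- mean(c(1 / a1, 1 / a2, 0 / a_mid))
  expect_equal(est$O, O_hand, tolerance = 1e-12)
  expect_equal(est$g, O_hand / (3 / 1e4), tolerance = 1e-12)
  expect_equal(est$pair_count, 2)
})

test_that("pcf estimates equal the brute-force estimator on the fixture", {
  cen <- fixture_small(42)$census
  w <- plot_window(100, 100)
  pat <- species_pattern(cen, "SPA")
  bins <- distance_bins(r_max = 20, width = 2)
  est <- pcf_univariate(pat, bins)
  oracle <- brute_pcf(pat$x, pat$y, pat$x, pat$y, w, bins$centers, 2,
                      univariate = TRUE)
  expect_equal(est$g, oracle$g, tolerance = 1e-12)
  expect_equal(est$O, oracle$O, tolerance = 1e-12)
})

test_that("the univariate estimator is unbiased under CSR", {
  w <- plot_window(100, 100)
  bins <- distance_bins(centers = c(6, 10, 20), width = 2)
  set.seed(21)
  gmat <- vapply(1:200, function(i)
    pcf_univariate(simulate_csr(200, w), bins)$g, numeric(3))
  gbar <- rowMeans(gmat)
  se <- apply(gmat, 1, sd) / sqrt(200)
  expect_true(all(abs(gbar - 1) < 3 * se))
})

test_that("Thomas-process estimates match the closed-form pcf", {
  bins <- distance_bins(r_max = 26, width = 2)
  spec <- community_spec(
    species = list(species_spec("SP",
                                abundance = c(sapling = 400, pole = 0,
                                              adult = 0),
                                sigma = 5, mu = 20)),
    gap_quadrats = 0, seed = 1)
  gmat <- vapply(1:50, function(i) {
    spec$seed <- i
    cm <- generate_community(spec)
    pcf_univariate(species_pattern(cm$census, "SP"), bins)$g
  }, numeric(length(bins$centers)))
  rho <- round(400 / 20) / (500 * 400)
  theory <- thomas_pcf(bins$centers, 5, rho)
  gbar <- rowMeans(gmat)
  se <- apply(gmat, 1, sd) / sqrt(50)
  # within Monte-Carlo error of theory at every distance
  expect_true(all(abs(gbar - theory) < 4 * se + 0.02 * theory))
})

test_that("independent patterns give cross-pcf near 1 and a shifted clone
           gives a large small-scale cross-pcf equal to brute force", {
  w <- plot_window(100, 100)
  bins <- distance_bins(centers = c(6, 10), width = 2)
  set.seed(31)
  g12 <- vapply(1:150, function(i)
    pcf_bivariate(simulate_csr(100, w), simulate_csr(100, w), bins)$g,
    numeric(2))
  gbar <- rowMeans(g12); se <- apply(g12, 1, sd) / sqrt(150)
  expect_true(all(abs(gbar - 1) < 3 * se))
  # pattern2 = pattern1 shifted by 1 m
  set.seed(5)
  p1 <- point_pattern(runif(100, 1, 99), runif(100, 1, 99), w)
  p2 <- point_pattern(p1$x + 1, p1$y, w)
  b1 <- distance_bins(centers = 1, width = 2)
  est <- pcf_bivariate(p1, p2, b1)
  # one guaranteed partner at 1 m per focal: O ~ 1/(4 pi), g ~ 8 at this
  # intensity, far above the independence value 1
  expect_gt(est$g, 5)
  oracle <- brute_pcf(p1$x, p1$y, p2$x, p2$y, w, 1, 2)
  expect_equal(est$g, oracle$g, tolerance = 1e-12)
})

test_that("ordered cross-pair counts are symmetric while g12 and g21 need
           not be", {
  w <- plot_window(100, 100)
  set.seed(8)
  p1 <- simulate_csr(60, w)
  p2 <- simulate_csr(40, w)
  bins <- distance_bins(r_max = 20, width = 2)
  e12 <- pcf_bivariate(p1, p2, bins)
  e21 <- pcf_bivariate(p2, p1, bins)
  expect_equal(e12$pair_count, e21$pair_count)
  expect_false(isTRUE(all.equal(e12$g, e21$g)))
})

test_that("the estimator is scale-equivariant", {
  w <- plot_window(100, 100)
  set.seed(13)
  p <- simulate_csr(80, w)
  bins <- distance_bins(r_max = 20, width = 2)
  est <- pcf_univariate(p, bins)
  cc <- 3
  p_scaled <- point_pattern(p$x * cc, p$y * cc, plot_window(100 * cc, 100 * cc))
  bins_scaled <- distance_bins(r_max = 20 * cc, width = 2 * cc)
  est_scaled <- pcf_univariate(p_scaled, bins_scaled)
  expect_equal(est_scaled$g, est$g, tolerance = 1e-9)
})

test_that("patterns that are too small are rejected", {
  w <- plot_window(100, 100)
  expect_error(pcf_univariate(point_pattern(1, 1, w)), "at least 2")
  expect_error(pcf_bivariate(point_pattern(numeric(0), numeric(0), w),
                             simulate_csr(5, w)), "non-empty")
})
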