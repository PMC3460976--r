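test_that("the generator is reproducible byte-for-byte", {
  a <- fixture_small(42)
  b <- fixture_small(42)
  expect_identical(a$census, b$census)
  expect_identical(a$habitat$category, b$habitat$category)
  d <- fixture_small(43)
  expect_false(identical(a$census, d$census))
})

test_that("the small fixture honours its contract and its frozen pcf", {
  fx <- fixture_small(42)
  expect_lte(nrow(fx$census), 200)
  expect_equal(sort(unique(fx$census$species)), c("SPA", "SPB", "SPC"))
  w <- attr(fx$census, "window")
  expect_equal(c(w$Lx, w$Ly), c(100, 100))
  pat <- species_pattern(fx$census, "SPA")
  bins <- distance_bins(centers = 5, width = 2)
  est <- pcf_univariate(pat, bins)
  oracle <- brute_pcf(pat$x, pat$y, pat$x, pat$y, w, 5, 2, univariate = TRUE)
  expect_equal(est$g, oracle$g, tolerance = 1e-12)
  # frozen value computed once with the brute-force estimator
  expect_equal(est$g, 7.2027574051, tolerance = 1e-9)
})

test_that("terrain construction matches its analytic pieces", {
  base_spec <- community_spec(species = list(), seed = 1)
  flat <- base_spec
  flat$dem <- list(base = 750, trend = c(0, 0), hills = list())
  g <- generate_dem(flat)
  expect_true(all(g$z == 750))
  map <- classify_habitat(compute_quadrat_metrics(g))
  expect_true(all(c(map$category) %in% c("valley", "low-slope")))
  one_hill <- base_spec
  one_hill$dem <- list(base = 700, trend = c(0, 0),
                       hills = list(c(200, 200, 100, 50)))
  gz <- generate_dem(one_hill)$z
  expect_equal(which(gz == max(gz), arr.ind = TRUE)[1, ],
               c(row = 11, col = 11))  # lattice node at (200, 200)
  expect_equal(max(gz), 800)
})

test_that("the default terrain spans the documented relief and produces
           at least five habitat classes plus gaps", {
  spec <- community_spec(species = list(), seed = 2)
  dem <- generate_dem(spec)
  expect_gt(min(dem$z), 695)
  expect_lt(max(dem$z), 880)
  expect_gt(max(dem$z) - min(dem$z), 120)
  gap <- generate_gap_mask(dem$nx, dem$ny, 25, seed = 3)
  map <- classify_habitat(compute_quadrat_metrics(dem), gap_mask = gap)
  counts <- habitat_counts(map)
  expect_gte(sum(counts > 0), 5)
  expect_equal(unname(counts[["gap"]]), 25)
  expect_equal(sum(counts), 500)
})

test_that("generated communities match requested totals and partition into
           stages", {
  spec <- community_spec(
    species = list(
      species_spec("AA", abundance = c(sapling = 80, pole = 40, adult = 10)),
      species_spec("BB", abundance = c(sapling = 50, pole = 20, adult = 5),
                   treelet = TRUE)),
    gap_quadrats = 10, seed = 12)
  cm <- generate_community(spec)
  expect_equal(sum(cm$census$species == "AA"), 130)
  expect_equal(sum(cm$census$species == "BB"), 75)
  expect_true(all(cm$census$stage %in% c("sapling", "pole", "adult")))
  expect_true(all(cm$census$dbh >= 1))
  expect_equal(cm$ground_truth$species$AA$sigma, 5)
})

test_that("a huge-dispersion species is indistinguishable from CSR", {
  spec <- community_spec(
    species = list(species_spec("U", abundance = c(sapling = 300, pole = 0,
                                                   adult = 0),
                                sigma = 5000, mu = 2)),
    gap_quadrats = 0, seed = 21)
  cm <- generate_community(spec)
  expect_gt(quadrat_chisq_p(species_pattern(cm$census, "U")), 0.01)
})

test_that("inconsistent pair coupling is rejected", {
  sp <- list(species_spec("A"), species_spec("B"))
  expect_error(community_spec(sp, coupling = data.frame(
    sp1 = "A", sp2 = "B", share_frac = 0.5, inhibit_radius = 4)),
    "xor")
  expect_error(community_spec(sp, coupling = data.frame(
    sp1 = "B", sp2 = "A", share_frac = 0.5, inhibit_radius = 0)),
    "before")
})

test_that("an attraction pair carries excess small-scale cross-correlation", {
  spec <- community_spec(
    species = list(
      species_spec("S1", abundance = c(sapling = 200, pole = 0, adult = 0),
                   sigma = 5, mu = 10),
      species_spec("S2", abundance = c(sapling = 200, pole = 0, adult = 0),
                   sigma = 5, mu = 10)),
    coupling = data.frame(sp1 = "S1", sp2 = "S2", share_frac = 0.8,
                          inhibit_radius = 0),
    gap_quadrats = 0, seed = 33)
  cm <- generate_community(spec)
  bins <- distance_bins(r_max = 10, width = 2)
  g12 <- pcf_bivariate(species_pattern(cm$census, "S1"),
                       species_pattern(cm$census, "S2"), bins)$g
  expect_gt(mean(g12), 3)
  expect_equal(cm$ground_truth$pairs$sign, 1L)
})

test_that("stage-wise de-clustering weakens small-scale aggregation", {
  spec <- community_spec(
    species = list(species_spec("SP",
                                abundance = c(sapling = 250, pole = 250,
                                              adult = 250),
                                sigma = 5, mu = 10,
                                dbh_meanlog = log(8), dbh_sdlog = 0.5)),
    gap_quadrats = 0, seed = 40)
  bins <- distance_bins(r_max = 10, width = 2)
  gmean <- function(cm, stg) {
    pat <- species_pattern(cm$census, "SP", stg)
    mean(pcf_univariate(pat, bins)$g)
  }
  # average over a few replicates to damp Monte-Carlo noise
  diffs <- vapply(1:6, function(i) {
    spec$seed <- 40 + i
    cm <- generate_community(spec)
    gmean(cm, "sapling") - gmean(cm, "adult")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
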