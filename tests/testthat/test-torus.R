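toy_map <- function(categories, nx, ny) {
  habitat_map(matrix(categories, nx, ny))
}

test_that("relative density is 1 under proportional spread and 2 under
           concentration in a half-plot habitat", {
  # 4 x 4 lattice, left half valley, right half low-slope
  map <- toy_map(rep(c("valley", "low-slope"), each = 8), 4, 4)
  w <- plot_window(80, 80)
  # one stem per quadrat: proportional to area
  centers <- expand.grid(x = c(10, 30, 50, 70), y = c(10, 30, 50, 70))
  cen <- assign_stems_to_quadrats(
    census_table(paste0("t", 1:16), "S", centers$x, centers$y, rep(2, 16), w))
  rd <- relative_density(cen, "S", map)
  expect_equal(unname(rd[c("valley", "low-slope")]), c(1, 1))
  expect_true(all(is.na(rd[c("high-slope", "high-gully", "high-plateau",
                             "gap")])))
  # all stems in the valley half (the first two quadrat rows, y < 40)
  set.seed(6)
  cen2 <- assign_stems_to_quadrats(
    census_table(paste0("t", 1:10), "S", runif(10, 0, 79.9),
                 runif(10, 0, 39.9), rep(2, 10), w))
  expect_equal(unname(relative_density(cen2, "S", map)["valley"]), 2)
})

test_that("relative density matches a hand count on a toy map", {
  map <- toy_map(c(rep("valley", 5), rep("low-slope", 7),
                   rep("high-gully", 4)), 4, 4)
  w <- plot_window(80, 80)
  # 10 stems: 6 in quadrat (0,0) [valley], 4 in quadrat (3,3) [high-gully]
  cen <- assign_stems_to_quadrats(census_table(
    paste0("t", 1:10), "S",
    x = c(rep(5, 6), rep(75, 4)), y = c(rep(5, 6), rep(75, 4)),
    dbh = rep(2, 10), w))
  rd <- relative_density(cen, "S", map)
  expect_equal(unname(rd["valley"]), (6 / 10) / (5 / 16))
  expect_equal(unname(rd["high-gully"]), (4 / 10) / (4 / 16))
  expect_equal(unname(rd["low-slope"]), 0)
})

test_that("torus maps enumerate 4N - 1 area-preserving translations", {
  m22 <- toy_map(c("valley", "low-slope", "gap", "high-gully"), 2, 2)
  maps <- torus_maps(m22)
  expect_length(maps, 15)
  for (mm in maps)
    expect_equal(sort(c(mm)), sort(c(m22$category)))
  # exhaustive enumeration oracle: every variant x shift except identity
  oracle <- list()
  flip <- function(M, fx, fy) {
    if (fx) M <- M[nrow(M):1, , drop = FALSE]
    if (fy) M <- M[, ncol(M):1, drop = FALSE]
    M
  }
  for (v in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                 c(TRUE, TRUE)))
    for (dx in 0:1) for (dy in 0:1) {
      if (!v[1] && !v[2] && dx == 0 && dy == 0) next
      M <- flip(m22$category, v[1], v[2])
      M <- M[c(2 - dx %% 2, (2 - dx %% 2) %% 2 + 1), , drop = FALSE][
        , c(2 - dy %% 2, (2 - dy %% 2) %% 2 + 1), drop = FALSE]
      oracle[[length(oracle) + 1]] <- M
    }
  key <- function(M) paste(c(M), collapse = "|")
  expect_setequal(vapply(maps, key, character(1)),
                  vapply(oracle, key, character(1)))
  # lattice of 500 quadrats yields 1999 maps
  big <- habitat_map(matrix(sample(c("valley", "gap"), 500, TRUE), 25, 20))
  expect_length(torus_maps(big), 1999)
})

test_that("random habitat maps preserve areas and are seed-deterministic", {
  cm <- fixture_small(5)
  maps1 <- random_habitat_maps(cm$habitat, n_maps = 5, seed = 3)
  maps2 <- random_habitat_maps(cm$habitat, n_maps = 5, seed = 3)
  expect_identical(maps1, maps2)
  ref <- sort(c(cm$habitat$category))
  for (mm in maps1) expect_equal(sort(c(mm)), ref)
  # single-habitat map: every generated map is the original
  flat <- toy_map(rep("valley", 12), 4, 3)
  for (mm in random_habitat_maps(flat, 3, seed = 1))
    expect_equal(mm, flat$category)
})

test_that("a species confined to an asymmetric habitat tests positive,
           with tail probabilities matching exhaustive enumeration", {
  nx <- 6; ny <- 5
  cat_ <- matrix("valley", nx, ny)
  cat_[1, 1] <- "gap"; cat_[2, 3] <- "gap"
  map <- habitat_map(cat_)
  w <- plot_window(nx * 20, ny * 20)
  # 12 stems inside the two gap quadrats
  cen <- assign_stems_to_quadrats(census_table(
    paste0("t", 1:12), "S",
    x = c(rep(10, 6), rep(30, 6)), y = c(rep(10, 6), rep(50, 6)),
    dbh = rep(2, 12), w))
  res <- torus_translation_test(cen, "S", map)
  expect_equal(res$label[res$habitat == "gap"], "positive")
  expect_equal(res$n_maps[1], 4 * nx * ny - 1)
  # oracle: enumerate all torus maps by hand and rank the gap density
  obs_stat <- 12 / 12 / (2 / 30)
  stat_of <- function(M) {
    labs <- M[cbind(cen$qx + 1, cen$qy + 1)]
    (sum(labs == "gap") / 12) / (2 / 30)
  }
  null_stats <- c()
  for (v in 1:4) for (dx in 0:(nx - 1)) for (dy in 0:(ny - 1)) {
    if (v == 1 && dx == 0 && dy == 0) next
    M <- switch(v, cat_, cat_[nx:1, ], cat_[, ny:1], cat_[nx:1, ny:1])
    M <- M[((seq_len(nx) - 1 - dx) %% nx) + 1, ((seq_len(ny) - 1 - dy) %% ny) + 1]
    null_stats <- c(null_stats, stat_of(M))
  }
  p_up_oracle <- (1 + sum(null_stats >= obs_stat)) / (length(null_stats) + 1)
  expect_equal(res$p_upper[res$habitat == "gap"], p_up_oracle)
})

test_that("all habitats are neutral on a single-habitat map", {
  map <- toy_map(rep("valley", 20), 5, 4)
  w <- plot_window(100, 80)
  set.seed(2)
  cen <- assign_stems_to_quadrats(census_table(
    paste0("t", 1:30), "S", runif(30, 0, 100), runif(30, 0, 80),
    rep(2, 30), w))
  res <- torus_translation_test(cen, "S", map)
  expect_equal(res$label[res$habitat == "valley"], "neutral")
})

test_that("type-I error of the torus test is near the nominal level", {
  cm <- fixture_small(3)
  # a 25 x 20 habitat map from the default terrain
  spec0 <- community_spec(species = list(), seed = 2)
  dem <- generate_dem(spec0)
  map <- classify_habitat(compute_quadrat_metrics(dem),
                          gap_mask = generate_gap_mask(25, 20, 25, seed = 2))
  w <- plot_window(500, 400)
  set.seed(77)
  n_rep <- 200
  nonneutral <- matrix(NA, n_rep, 6)
  for (i in seq_len(n_rep)) {
    cen <- assign_stems_to_quadrats(census_table(
      paste0("t", 1:200), "S", runif(200, 0, 500), runif(200, 0, 400),
      rep(2, 200), w))
    res <- torus_translation_test(cen, "S", map)
    nonneutral[i, ] <- res$label != "neutral"
  }
  pooled <- mean(nonneutral)
  expect_gt(pooled, 0.05 - 3 * sqrt(0.05 * 0.95 / (n_rep * 6)))
  expect_lt(pooled, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
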