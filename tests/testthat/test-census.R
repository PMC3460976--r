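make_census_file <- function(rows, sep = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste(c("tag", "species", "x", "y", "dbh"), collapse = sep),
               vapply(rows, paste, character(1), collapse = sep)), path)
  path
}

test_that("a well-formed census file round-trips", {
  path <- make_census_file(list(c("t1", "SPA", 10, 20, 2.5),
                                c("t2", "SPA", 400, 300, 10),
                                c("t3", "SPB", 0, 0, 1)))
  cen <- read_census(path, plot_window(500, 400))
  expect_s3_class(cen, "census_table")
  expect_equal(nrow(cen), 3)
  expect_equal(cen$dbh, c(2.5, 10, 1))
  out <- tempfile(fileext = ".tsv")
  write_census(cen, out)
  again <- read_census(out, plot_window(500, 400))
  expect_equal(as.data.frame(again), as.data.frame(cen))
})

test_that("schema, parse and window violations are reported", {
  path <- tempfile()
  writeLines(c("tag,species,x,y", "t1,SPA,1,2"), path)
  expect_error(read_census(path, plot_window(500, 400)), "dbh")
  bad_num <- make_census_file(list(c("t1", "SPA", "abc", 20, 2.5)))
  expect_error(read_census(bad_num, plot_window(500, 400)), "row")
  outside <- make_census_file(list(c("t9", "SPA", -1, 20, 2.5)))
  expect_error(read_census(outside, plot_window(500, 400)), "t9")
  small <- make_census_file(list(c("t1", "SPA", 1, 2, 0.4)))
  expect_error(read_census(small, plot_window(500, 400)), "minimum DBH")
})

test_that("degenerate species summaries are exact", {
  w <- plot_window(100, 100)
  one <- census_table("t1", "SPA", 10, 10, 5, w)
  s <- compute_species_summaries(one)
  expect_equal(s$relative_density, 100)
  expect_equal(s$relative_dominance, 100)
  expect_equal(s$relative_frequency, 100)
  expect_equal(s$importance_value, 300)
  # two species identical in counts, sizes and occupancy: IV = 150 each
  two <- census_table(paste0("t", 1:4), c("A", "A", "B", "B"),
                      c(10, 50, 30, 70), c(10, 50, 30, 70), rep(5, 4), w)
  s2 <- compute_species_summaries(two)
  expect_equal(s2$importance_value, c(150, 150))
})

test_that("importance-value components each sum to 100", {
  cen <- fixture_small(7)$census
  s <- compute_species_summaries(cen)
  expect_equal(sum(s$relative_density), 100, tolerance = 1e-9)
  expect_equal(sum(s$relative_dominance), 100, tolerance = 1e-9)
  expect_equal(sum(s$relative_frequency), 100, tolerance = 1e-9)
})

test_that("D95_0.1 uses the nearest-rank percentile of the eligible stems", {
  w <- plot_window(100, 100)
  dbh <- c(1.2, 2.5, 3.1, 4.0, 5.5, 6.0, 8.2, 12.0, 40.0)
  cen <- census_table(paste0("t", seq_along(dbh)), "SPA",
                      seq_along(dbh), seq_along(dbh), dbh, w)
  th <- compute_life_stage_thresholds(cen, "SPA", treelet = FALSE)
  expect_equal(th$d_max, 40)
  # cutoff 4.0 leaves {4.0, 5.5, 6.0, 8.2, 12.0, 40.0}; ceil(.95*6) = 6th
  expect_equal(th$d95_01, 40.0)
  # constant distribution and singleton
  cen2 <- census_table(paste0("s", 1:5), "SPB", 1:5, 1:5, rep(7, 5), w)
  expect_equal(compute_life_stage_thresholds(cen2, "SPB")$d95_01, 7)
  cen3 <- census_table("u1", "SPC", 1, 1, 10, w)
  th3 <- compute_life_stage_thresholds(cen3, "SPC")
  expect_equal(th3$d_max, 10)
  expect_equal(th3$d95_01, 10)
  expect_error(compute_life_stage_thresholds(cen, "NOPE"), "no stems")
})

test_that("adding a thicker stem never decreases D95_0.1", {
  w <- plot_window(1000, 1000)
  set.seed(3)
  for (rep in 1:25) {
    dbh <- round(rlnorm(sample(3:40, 1), log(5), 0.8) + 1, 2)
    cen <- census_table(paste0("t", seq_along(dbh)), "S",
                        seq_along(dbh), seq_along(dbh), dbh, w)
    d95 <- compute_life_stage_thresholds(cen, "S")$d95_01
    dbh2 <- c(dbh, max(dbh) * 1.5)
    cen2 <- census_table(paste0("t", seq_along(dbh2)), "S",
                         seq_along(dbh2), seq_along(dbh2), dbh2, w)
    expect_gte(compute_life_stage_thresholds(cen2, "S")$d95_01, d95)
  }
})

test_that("life-stage boundaries follow the documented conventions", {
  canopy <- list(sapling_upper = 5, d95_01 = 30)
  treelet <- list(sapling_upper = 3, d95_01 = 12)
  expect_equal(classify_life_stage(3.0, canopy), "sapling")
  expect_equal(classify_life_stage(3.5, treelet), "pole")
  expect_equal(classify_life_stage(31, canopy), "adult")
  # stems exactly at a cutpoint are poles
  expect_equal(classify_life_stage(5, canopy), "pole")
  expect_equal(classify_life_stage(30, canopy), "pole")
  expect_error(classify_life_stage(0.5, canopy), "census minimum")
})

test_that("stage patterns partition each species", {
  cen <- fixture_small(11)$census
  for (sp in unique(cen$species)) {
    th <- compute_life_stage_thresholds(cen, sp)
    parts <- split_by_stage(cen, sp, th)
    expect_equal(sum(vapply(parts, function(p) p$n, numeric(1))),
                 sum(cen$species == sp))
    # brute-force filter oracle
    dbh <- cen$dbh[cen$species == sp]
    expect_equal(parts$sapling$n, sum(dbh < th$sapling_upper))
    expect_equal(parts$pole$n,
                 sum(dbh >= th$sapling_upper & dbh <= th$d95_01))
    expect_equal(parts$adult$n, sum(dbh > th$d95_01))
  }
  # all-sapling species: pole and adult empty
  w <- plot_window(50, 50)
  cen2 <- census_table(paste0("t", 1:6), "S", 1:6, 1:6,
                       rep(2, 6), w)
  parts <- split_by_stage(cen2, "S",
                          list(sapling_upper = 5, d95_01 = 30))
  expect_equal(parts$sapling$n, 6)
  expect_equal(parts$pole$n + parts$adult$n, 0)
})
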