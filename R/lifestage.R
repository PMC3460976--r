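## Life-stage classification by DBH.
##
## Saplings are 1-5 cm DBH (1-3 cm for treelet species, whose maximum DBH
## does not exceed 20 cm), poles run from the sapling cutpoint to D95_0.1,
## and adults are thicker than D95_0.1, where D95_0.1 is the 95th percentile
## of DBH among stems with DBH >= 0.1 x the species' maximum DBH. The
## percentile is the nearest-rank (ceil(0.95 n)-th) order statistic, which is
## well defined for any sample size.

## nearest-rank percentile: smallest value with at least p of the sample <= it
nearest_rank_percentile <- function(v, p = 0.95) {
  sort(v)[max(1L, ceiling(p * length(v)))]
}

#' Life-stage thresholds for one species
#'
#' @param census a \code{census_table}.
#' @param species_code species to summarise.
#' @param treelet flag: is the species a treelet (sapling cutpoint 3 cm
#'   instead of 5 cm)? Default \code{NA} infers it from the data as
#'   maximum DBH <= 20 cm.
#' @return list with \code{species}, \code{d_max} (cm), \code{d95_01} (cm),
#'   \code{is_treelet}, \code{sapling_upper} (cm).
#' @export
compute_life_stage_thresholds <- function(census, species_code, treelet = NA) {
  dbh <- census$dbh[census$species == species_code]
  if (!length(dbh)) stop("no stems of species ", species_code, call. = FALSE)
  d_max <- max(dbh)
  if (is.na(treelet)) treelet <- d_max <= 20
  eligible <- dbh[dbh >= 0.1 * d_max]
  list(species = species_code,
       d_max = d_max,
       d95_01 = nearest_rank_percentile(eligible, 0.95),
       is_treelet = isTRUE(treelet),
       sapling_upper = if (isTRUE(treelet)) 3.0 else 5.0)
}

#' Classify stems into life stages
#'
#' Sapling if \code{dbh < sapling_upper}; pole if
#' \code{sapling_upper <= dbh <= d95_01}; adult if \code{dbh > d95_01}.
#' A stem exactly at either cutpoint is a pole. If \code{d95_01} does not
#' exceed the sapling cutpoint the pole class is empty, without error.
#'
#' @param dbh stem DBH values (cm), all >= the census minimum (1 cm).
#' @param thresholds result of \code{\link{compute_life_stage_thresholds}}.
#' @return character vector in \code{c("sapling", "pole", "adult")}.
#' @export
classify_life_stage <- function(dbh, thresholds) {
  if (any(dbh < 1))
    stop("DBH below the 1 cm census minimum", call. = FALSE)
  ifelse(dbh < thresholds$sapling_upper, "sapling",
         ifelse(dbh <= thresholds$d95_01, "pole", "adult"))
}

#' Add a stage column to a census
#'
#' Computes per-species thresholds and classifies every stem.
#'
#' @param census a \code{census_table}.
#' @param treelet_flags optional named logical vector (names = species
#'   codes); species absent from it fall back to the d_max <= 20 cm rule.
#' @return the census with a \code{stage} column.
#' @export
classify_census_stages <- function(census, treelet_flags = NULL) {
  census$stage <- NA_character_
  for (sp in unique(census$species)) {
    fl <- if (!is.null(treelet_flags) && sp %in% names(treelet_flags))
      treelet_flags[[sp]] else NA
    th <- compute_life_stage_thresholds(census, sp, treelet = fl)
    rows <- census$species == sp
    census$stage[rows] <- classify_life_stage(census$dbh[rows], th)
  }
  census
}

#' Split one species into per-stage point patterns
#'
#' @param census a \code{census_table}.
#' @param species_code species to split.
#' @param thresholds optional precomputed thresholds; computed if missing.
#' @return named list of three \code{\link{point_pattern}}s:
#'   \code{sapling}, \code{pole}, \code{adult}; they partition the species'
#'   stems.
#' @export
split_by_stage <- function(census, species_code, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- compute_life_stage_thresholds(census, species_code)
  rows <- census$species == species_code
  stage <- classify_life_stage(census$dbh[rows], thresholds)
  w <- census_window(census)
  xs <- census$x[rows]; ys <- census$y[rows]
  stats::setNames(
    lapply(c("sapling", "pole", "adult"), function(s)
      point_pattern(xs[stage == s], ys[stage == s], w)),
    c("sapling", "pole", "adult"))
}
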