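#' Published abundances of the twenty dominant species
#'
#' Per-species stem counts by life stage, life type and habitat-association
#' labels of the twenty dominant tree species of a 20-ha (500 x 400 m)
#' tropical seasonal rain-forest census (95,498 stems >= 1 cm DBH in
#' total), shipped as a small table. Used both as arithmetic input for the
#' importance-value checks and to parameterise the default synthetic
#' community.
#'
#' @return data frame with columns rank, code, life_type, n_individuals,
#'   percent, n_saplings, n_poles, n_adults, habitat_association; attribute
#'   \code{total_stems} holds the full census stem count.
#' @export
dominant_species_counts <- function() {
  path <- system.file("extdata", "dominant_species_counts.tsv",
                      package = "forestspat", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", fill = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  tab$habitat_association[is.na(tab$habitat_association)] <- ""
  meta <- jsonlite::read_json(system.file("extdata", "plot_summary.json",
                                          package = "forestspat",
                                          mustWork = TRUE))
  attr(tab, "total_stems") <- meta$total_stems_geq_1cm
  attr(tab, "window_m") <- unlist(meta$window_m)
  tab
}

## "habitat+;other-" label string -> multiplier vector (4 for +, 0.25 for -)
association_multipliers <- function(label, up = 4, down = 0.25) {
  if (!nzchar(label)) return(NULL)
  parts <- strsplit(label, ";")[[1]]
  habs <- sub("[+-]$", "", parts)
  signs <- sub("^.*([+-])$", "\\1", parts)
  stats::setNames(ifelse(signs == "+", up, down), habs)
}

#' Default synthetic community emulating the study plot
#'
#' Twenty species in the 500 x 400 m window with the published per-stage
#' abundances, treelet flags from the life-type column, and habitat
#' intensity multipliers of 4 (positive) or 0.25 (negative) where a species
#' carries a habitat-association label. Thomas clustering uses a 5 m
#' offspring dispersion and 25 offspring per parent for all species (the
#' census publishes no clustering parameters; these give the strong
#' <10 m sapling aggregation typical of such plots). Abundances can be
#' scaled down for desk-scale experiments.
#'
#' @param seed master seed.
#' @param scale multiply all abundances by this factor (e.g. 0.1 for quick
#'   experiments); counts are rounded, minimum drawn from the data.
#' @return a \code{\link{community_spec}}.
#' @export
default_community_spec <- function(seed = 1, scale = 1) {
  tab <- dominant_species_counts()
  species <- lapply(seq_len(nrow(tab)), function(i) {
    species_spec(
      code = tab$code[i],
      abundance = c(sapling = round(scale * tab$n_saplings[i]),
                    pole = round(scale * tab$n_poles[i]),
                    adult = round(scale * tab$n_adults[i])),
      sigma = 5, mu = 25,
      multipliers = association_multipliers(tab$habitat_association[i]),
      dbh_meanlog = if (tab$life_type[i] == "Treelet") log(2.2) else log(3.5),
      dbh_sdlog = if (tab$life_type[i] == "Treelet") 0.55 else 0.95,
      treelet = tab$life_type[i] == "Treelet")
  })
  community_spec(species = species, seed = seed)
}
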