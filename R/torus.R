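## Harms-style torus-translation tests of species-habitat association.
##
## The stem map stays fixed; the habitat map is shifted toroidally (and
## rotated/mirrored) to build the null distribution of each species'
## relative density in each habitat.

#' Observed relative density of a species in a habitat
#'
#' \code{(n_sh / n_s) / (a_h / A)}: the species' share of stems in the
#' habitat divided by the habitat's share of plot area. 1 when stems are
#' spread proportionally to habitat area. \code{NA} for a habitat with zero
#' area (excluded from testing).
#'
#' @param census a \code{census_table} with quadrat indices (see
#'   \code{\link{assign_stems_to_quadrats}}).
#' @param species_code species to evaluate.
#' @param map a \code{habitat_map} on the same quadrat lattice.
#' @param habitat habitat name, or \code{NULL} for all six at once.
#' @return named numeric vector of relative densities.
#' @export
relative_density <- function(census, species_code, map, habitat = NULL) {
  rows <- census$species == species_code
  if (!any(rows)) stop("no stems of species ", species_code, call. = FALSE)
  if (is.null(census$qx)) stop("assign stems to quadrats first", call. = FALSE)
  lab <- map$category[cbind(census$qx[rows] + 1L, census$qy[rows] + 1L)]
  n_h <- table(factor(lab, levels = habitat_levels))
  a_h <- habitat_counts(map)  # areas in quadrat units; ratio is unitless
  rd <- (as.numeric(n_h) / sum(rows)) / (as.numeric(a_h) / (map$nx * map$ny))
  rd[a_h == 0] <- NA_real_
  names(rd) <- habitat_levels
  if (is.null(habitat)) rd else rd[habitat]
}

## Apply variant v (1 identity, 2 mirror in x, 3 mirror in y, 4 180 degree
## rotation) then toroidal shift (dx, dy) to a category matrix.
shift_map <- function(category, dx, dy, variant = 1L) {
  nx <- nrow(category); ny <- ncol(category)
  m <- switch(variant,
              category,
              category[nx:1, , drop = FALSE],
              category[, ny:1, drop = FALSE],
              category[nx:1, ny:1, drop = FALSE])
  ix <- ((seq_len(nx) - 1L - dx) %% nx) + 1L
  iy <- ((seq_len(ny) - 1L - dy) %% ny) + 1L
  m[ix, iy, drop = FALSE]
}

#' All torus-translated null habitat maps
#'
#' Every toroidal translation of the quadrat lattice combined with the four
#' symmetries {identity, mirror, mirrored rotation, 180 degree rotation},
#' excluding the untranslated original: \code{4 N - 1} maps for \code{N}
#' quadrats. Each preserves per-habitat quadrat counts exactly. On small
#' lattices some of the generated maps can coincide as label arrays.
#'
#' @param map a \code{habitat_map}.
#' @return list of category matrices.
#' @export
torus_maps <- function(map) {
  out <- vector("list", 4L * map$nx * map$ny - 1L)
  k <- 0L
  for (variant in 1:4)
    for (dx in seq_len(map$nx) - 1L)
      for (dy in seq_len(map$ny) - 1L) {
        if (variant == 1L && dx == 0L && dy == 0L) next
        k <- k + 1L
        out[[k]] <- shift_map(map$category, dx, dy, variant)
      }
  out
}

#' Randomly seeded null habitat maps
#'
#' Habitat-area-preserving random maps grown from one random seed quadrat
#' per habitat by random adjacent accretion (4-neighbourhood) until each
#' habitat reaches its original quadrat count; if a region gets walled in,
#' growth restarts from a random unassigned quadrat, which guarantees
#' termination. Reproducible under a fixed seed.
#'
#' @param map a \code{habitat_map}.
#' @param n_maps number of maps.
#' @param seed RNG seed.
#' @return list of category matrices, each with the original habitat counts.
#' @export
random_habitat_maps <- function(map, n_maps = 1000, seed = 1) {
  stopifnot(n_maps >= 1)
  counts <- habitat_counts(map)
  habs <- names(counts)[counts > 0]
  nx <- map$nx; ny <- map$ny
  set.seed(seed)
  lapply(seq_len(n_maps), function(i) {
    lab <- matrix(NA_character_, nx, ny)
    remaining <- stats::setNames(as.integer(counts[habs]), habs)
    frontier <- stats::setNames(vector("list", length(habs)), habs)
    free <- which(is.na(lab))
    for (h in sample(habs)) {
      s <- free[sample.int(length(free), 1)]
      lab[s] <- h
      remaining[h] <- remaining[h] - 1L
      frontier[[h]] <- s
      free <- setdiff(free, s)
    }
    neighbours <- function(cell) {
      ix <- ((cell - 1L) %% nx) + 1L
      iy <- ((cell - 1L) %/% nx) + 1L
      nb <- c(if (ix > 1) cell - 1L, if (ix < nx) cell + 1L,
              if (iy > 1) cell - nx, if (iy < ny) cell + nx)
      nb
    }
    active <- habs[remaining > 0]
    while (length(active)) {
      h <- if (length(active) == 1) active else sample(active, 1)
      cand <- unlist(lapply(frontier[[h]], neighbours))
      cand <- cand[is.na(lab[cand])]
      cell <- if (length(cand)) cand[sample.int(length(cand), 1)]
              else { free <- which(is.na(lab)); free[sample.int(length(free), 1)] }
      lab[cell] <- h
      frontier[[h]] <- c(frontier[[h]], cell)
      remaining[h] <- remaining[h] - 1L
      active <- habs[remaining > 0]
    }
    lab
  })
}

#' Torus-translation (or random-map) test of species-habitat association
#'
#' Compares each habitat's observed relative density with its distribution
#' over null maps. Tail probabilities use the add-one rank rule
#' \code{(1 + #extreme) / (n_maps + 1)} with ties counted as extreme; a
#' habitat is labelled \code{positive} when the upper tail probability is at
#' most \code{alpha/2}, \code{negative} when the lower tail is, else
#' \code{neutral}.
#'
#' @param census a \code{census_table} with quadrat indices.
#' @param species_code species to test.
#' @param map a \code{habitat_map}.
#' @param alpha two-sided significance level.
#' @param null \code{"torus"} for all torus translations, \code{"random"}
#'   for seeded random maps.
#' @param n_maps number of random maps (ignored for \code{"torus"}).
#' @param seed RNG seed for random maps.
#' @return data frame: habitat, observed, p_lower, p_upper, label,
#'   n_maps.
#' @export
torus_translation_test <- function(census, species_code, map, alpha = 0.05,
                                   null = c("torus", "random"),
                                   n_maps = 1000, seed = 1) {
  null <- match.arg(null)
  if (is.null(census$qx)) census <- assign_stems_to_quadrats(census, 20)
  rows <- census$species == species_code
  if (!any(rows)) stop("species not testable: 0 stems", call. = FALSE)
  maps <- if (null == "torus") torus_maps(map)
          else random_habitat_maps(map, n_maps, seed)
  m <- length(maps)
  qlin <- cbind(census$qx[rows] + 1L, census$qy[rows] + 1L)
  n_s <- sum(rows)
  a_h <- as.numeric(habitat_counts(map))
  area_share <- a_h / (map$nx * map$ny)
  rd_of <- function(category) {
    n_h <- tabulate(factor(category[qlin], levels = habitat_levels),
                    nbins = length(habitat_levels))
    (n_h / n_s) / area_share
  }
  obs <- rd_of(map$category)
  null_rd <- vapply(maps, rd_of, numeric(length(habitat_levels)))
  p_up <- (1 + rowSums(null_rd >= obs)) / (m + 1)
  p_lo <- (1 + rowSums(null_rd <= obs)) / (m + 1)
  label <- ifelse(p_up <= alpha / 2, "positive",
                  ifelse(p_lo <= alpha / 2, "negative", "neutral"))
  testable <- a_h > 0
  data.frame(species = species_code, habitat = habitat_levels,
             observed = ifelse(testable, obs, NA_real_),
             p_lower = ifelse(testable, p_lo, NA_real_),
             p_upper = ifelse(testable, p_up, NA_real_),
             label = ifelse(testable, label, NA_character_),
             n_maps = m, stringsAsFactors = FALSE, row.names = NULL)
}
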