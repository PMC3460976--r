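## Synthetic forest generator.
##
## Produces censuses with known ground truth: habitat-affine Thomas
## (parent-offspring) clustering per species, lognormal DBH marks,
## progressive de-clustering across life stages, and controllable pairwise
## attraction (shared parents) or repulsion (cross-species hard core), over
## a smooth synthetic terrain. Every pipeline stage can be exercised
## against the generator's parameters without any external census.

#' Specification of one synthetic species
#'
#' @param code species code.
#' @param abundance named integer vector \code{c(sapling=, pole=, adult=)}.
#' @param sigma Thomas offspring dispersion (m), > 0.
#' @param mu mean offspring per parent; the parent count is
#'   \code{round(total abundance / mu)}.
#' @param multipliers named nonnegative vector of habitat intensity
#'   multipliers (missing habitats default to 1): parents are placed with
#'   probability proportional to the multiplier of their quadrat's habitat.
#' @param dbh_meanlog,dbh_sdlog lognormal DBH parameters (cm scale).
#' @param treelet treelet flag (3 cm sapling cutpoint).
#' @export
species_spec <- function(code, abundance = c(sapling = 120, pole = 60,
                                             adult = 20),
                         sigma = 5, mu = 25, multipliers = NULL,
                         dbh_meanlog = log(3), dbh_sdlog = 0.9,
                         treelet = FALSE) {
  stopifnot(sigma > 0, mu > 0, all(abundance >= 0))
  mult <- stats::setNames(rep(1, length(habitat_levels)), habitat_levels)
  if (!is.null(multipliers)) {
    if (any(multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
    mult[names(multipliers)] <- multipliers
  }
  list(code = code, abundance = abundance, sigma = sigma, mu = mu,
       multipliers = mult, dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
       treelet = treelet)
}

#' Specification of a synthetic community
#'
#' @param species list of \code{\link{species_spec}}s.
#' @param window a \code{\link{plot_window}} (default the 500 x 400 m plot).
#' @param dem terrain parameters: list with \code{base} (m), \code{trend}
#'   (c(dz/dx, dz/dy)), \code{hills} (list of c(cx, cy, amp, width)).
#' @param coupling data frame with columns \code{sp1}, \code{sp2},
#'   \code{share_frac} (fraction of sp2's parents shared with sp1;
#'   attraction) and \code{inhibit_radius} (cross-species hard core, m;
#'   repulsion). For any pair at most one of the two may be active, and
#'   \code{sp1} must be generated before \code{sp2} (listed earlier).
#' @param gap_quadrats number of gap quadrats to carve into the habitat map.
#' @param seed master seed; every draw derives from it.
#' @param quadrat_size quadrat side (m).
#' @export
community_spec <- function(species, window = plot_window(500, 400),
                           dem = list(base = 742.7,
                                      trend = c(-0.09, 0.222),
                                      hills = list(c(88, 174, -53, 45),
                                                   c(467, 21, 26, 30),
                                                   c(11, 240, 24, 51),
                                                   c(384, 176, 54, 54),
                                                   c(423, 284, -46, 31),
                                                   c(135, 80, 38, 30),
                                                   c(21, 2, -37, 29),
                                                   c(139, 322, 24, 54),
                                                   c(173, 337, 39, 40))),
                           coupling = NULL, gap_quadrats = 25, seed = 1,
                           quadrat_size = 20) {
  codes <- vapply(species, `[[`, character(1), "code")
  if (anyDuplicated(codes)) stop("duplicate species codes", call. = FALSE)
  if (!is.null(coupling)) {
    if (is.null(coupling$share_frac)) coupling$share_frac <- 0
    if (is.null(coupling$inhibit_radius)) coupling$inhibit_radius <- 0
    both <- coupling$share_frac > 0 & coupling$inhibit_radius > 0
    if (any(both))
      stop("coupling must be attraction xor repulsion for a pair",
           call. = FALSE)
    if (any(match(coupling$sp1, codes) >= match(coupling$sp2, codes)))
      stop("coupling sp1 must be listed before sp2", call. = FALSE)
  }
  list(species = species, window = window, dem = dem, coupling = coupling,
       gap_quadrats = gap_quadrats, seed = seed, quadrat_size = quadrat_size)
}

#' Synthetic corner-elevation lattice
#'
#' Smooth terrain: base elevation + linear trend + Gaussian hills, sampled
#' at the quadrat corners. The default parameters emulate a dissected
#' 500 x 400 m slope whose elevation spans roughly 709-869 m with steep
#' flanks, so all topographic habitat classes occur.
#'
#' @param spec a \code{\link{community_spec}} (only \code{window},
#'   \code{dem} and \code{quadrat_size} are used).
#' @param seed unused (the surface is deterministic in the parameters);
#'   kept so terrain variants can opt into noise later.
#' @return an \code{\link{elevation_grid}}.
#' @export
generate_dem <- function(spec, seed = NULL) {
  s <- spec$quadrat_size
  xs <- seq(0, spec$window$Lx, by = s)
  ys <- seq(0, spec$window$Ly, by = s)
  z <- outer(xs * spec$dem$trend[1], ys * spec$dem$trend[2], "+") +
    spec$dem$base
  for (hill in spec$dem$hills) {
    d2 <- outer((xs - hill[1])^2, (ys - hill[2])^2, "+")
    z <- z + hill[3] * exp(-d2 / (2 * hill[4]^2))
  }
  elevation_grid(z, s)
}

#' Random gap mask
#'
#' Grows \code{n_quadrats} gap quadrats as a few contiguous canopy-opening
#' patches on the quadrat lattice.
#'
#' @param nx,ny lattice dimensions.
#' @param n_quadrats total gap quadrats.
#' @param seed RNG seed.
#' @param n_patches number of openings.
#' @return logical \code{nx x ny} matrix.
#' @export
generate_gap_mask <- function(nx, ny, n_quadrats = 25, seed = 1,
                              n_patches = 4) {
  set.seed(seed)
  mask <- matrix(FALSE, nx, ny)
  per <- diff(round(seq(0, n_quadrats, length.out = n_patches + 1)))
  for (size in per[per > 0]) {
    cur <- sample.int(nx * ny, 1)
    mask[cur] <- TRUE
    grown <- 1L
    frontier <- cur
    while (grown < size) {
      ix <- ((frontier - 1L) %% nx) + 1L
      iy <- ((frontier - 1L) %/% nx) + 1L
      nb <- c(frontier[ix > 1] - 1L, frontier[ix < nx] + 1L,
              frontier[iy > 1] - nx, frontier[iy < ny] + nx)
      nb <- unique(nb[!mask[nb]])
      if (!length(nb)) nb <- which(!mask)
      add <- nb[sample.int(length(nb), 1)]
      mask[add] <- TRUE
      frontier <- c(frontier, add)
      grown <- grown + 1L
    }
  }
  mask
}

## Habitat multiplier per quadrat for one species.
quadrat_weights <- function(multipliers, map) {
  matrix(multipliers[map$category], map$nx, map$ny)
}

## Local-density counts on a coarse grid (cell m cells), for stage-wise
## de-clustering: how many of the pool points sit within the point's cell
## block of 3 x 3 cells.
local_density <- function(x, y, window, cell = 10) {
  nx <- max(1L, as.integer(ceiling(window$Lx / cell)))
  ny <- max(1L, as.integer(ceiling(window$Ly / cell)))
  ix <- pmin(as.integer(floor(x / cell)) + 1L, nx)
  iy <- pmin(as.integer(floor(y / cell)) + 1L, ny)
  counts <- matrix(tabulate(ix + (iy - 1L) * nx, nbins = nx * ny), nx, ny)
  padded <- matrix(0, nx + 2, ny + 2)
  padded[2:(nx + 1), 2:(ny + 1)] <- counts
  block <- matrix(0, nx, ny)
  for (dx in 0:2) for (dy in 0:2)
    block <- block + padded[dx + seq_len(nx), dy + seq_len(ny)]
  block[ix + (iy - 1L) * nx]
}

#' Generate a synthetic census with ground truth
#'
#' Per species: parents are placed uniformly, thinned by the habitat
#' multiplier of their quadrat; each stem picks a random parent and a
#' Gaussian displacement (sd \code{sigma}), redrawn until inside the
#' window, giving a Thomas cluster process with habitat-dependent
#' intensity. Saplings keep the full clustering; poles and adults are
#' subsampled from a larger offspring pool with retention probability
#' decreasing in local conspecific density (stronger for adults), so
#' clumping declines across life stages as under density-dependent
#' mortality. Attraction pairs share a fraction of parents; repulsion pairs
#' redraw stems of the second species that fall within the hard-core
#' radius of the first. DBH is lognormal (truncated at the 1 cm census
#' minimum), assigned so that the life-stage classifier reproduces the
#' requested stage abundances.
#'
#' @param spec a \code{\link{community_spec}}.
#' @return list: \code{census} (a \code{census_table} with \code{stage}),
#'   \code{habitat} (the \code{habitat_map} used), \code{dem},
#'   \code{ground_truth} (per-species and per-pair generator parameters).
#' @export
generate_community <- function(spec) {
  w <- spec$window
  dem <- generate_dem(spec)
  metrics <- compute_quadrat_metrics(dem)
  gap <- if (spec$gap_quadrats > 0)
    generate_gap_mask(dem$nx, dem$ny, spec$gap_quadrats,
                      seed = derive_seed(spec$seed, "gaps"))
  map <- classify_habitat(metrics, gap_mask = gap)

  qsize <- spec$quadrat_size
  parents_of <- list()
  tabs <- list()
  truth_species <- list()
  declust <- c(sapling = 0, pole = 0.08, adult = 0.25)  # per-neighbour rate

  for (sp in spec$species) {
    set.seed(derive_seed(spec$seed, "species", sp$code))
    n_total <- sum(sp$abundance)
    if (n_total == 0) next
    n_parents <- max(1L, as.integer(round(n_total / sp$mu)))

    ## habitat-weighted parent placement by rejection
    wts <- quadrat_weights(sp$multipliers, map)
    wmax <- max(wts)
    if (wmax <= 0) stop("all habitat multipliers zero for ", sp$code,
                        call. = FALSE)
    px <- numeric(0); py <- numeric(0)
    while (length(px) < n_parents) {
      need <- (n_parents - length(px)) * 2 + 10
      cx <- stats::runif(need, 0, w$Lx); cy <- stats::runif(need, 0, w$Ly)
      qx <- pmin(floor(cx / qsize) + 1, map$nx)
      qy <- pmin(floor(cy / qsize) + 1, map$ny)
      keep <- stats::runif(need) < wts[cbind(qx, qy)] / wmax
      px <- c(px, cx[keep]); py <- c(py, cy[keep])
    }
    px <- px[seq_len(n_parents)]; py <- py[seq_len(n_parents)]

    ## pair attraction: replace a fraction of parents with the partner's
    cp <- spec$coupling
    if (!is.null(cp)) {
      for (k in which(cp$sp2 == sp$code & cp$share_frac > 0)) {
        donor <- parents_of[[cp$sp1[k]]]
        n_share <- min(round(cp$share_frac[k] * n_parents), nrow(donor))
        if (n_share > 0) {
          take <- sample.int(nrow(donor), n_share)
          repl <- sample.int(n_parents, n_share)
          px[repl] <- donor$x[take]; py[repl] <- donor$y[take]
        }
      }
    }
    parents_of[[sp$code]] <- data.frame(x = px, y = py)

    unif_limit <- sp$sigma >= 2 * sqrt(w$Lx^2 + w$Ly^2)
    draw_offspring <- function(m) {
      ## for dispersion far beyond the window the within-window offspring
      ## distribution is uniform; use that limit directly
      if (unif_limit)
        return(data.frame(x = stats::runif(m, 0, w$Lx),
                          y = stats::runif(m, 0, w$Ly)))
      x <- numeric(m); y <- numeric(m); todo <- seq_len(m)
      while (length(todo)) {
        pid <- sample.int(n_parents, length(todo), replace = TRUE)
        xx <- px[pid] + stats::rnorm(length(todo), 0, sp$sigma)
        yy <- py[pid] + stats::rnorm(length(todo), 0, sp$sigma)
        ok <- xx >= 0 & xx <= w$Lx & yy >= 0 & yy <= w$Ly
        x[todo[ok]] <- xx[ok]; y[todo[ok]] <- yy[ok]
        todo <- todo[!ok]
      }
      data.frame(x = x, y = y)
    }

    ## stage patterns: saplings as-is; poles/adults de-clustered from a pool
    stage_pts <- list()
    for (stg in c("sapling", "pole", "adult")) {
      m <- sp$abundance[[stg]]
      if (m == 0) { stage_pts[[stg]] <- data.frame(x = numeric(0), y = numeric(0)); next }
      if (declust[[stg]] == 0) {
        stage_pts[[stg]] <- draw_offspring(m)
      } else {
        pool <- draw_offspring(max(3L * m, 30L))
        dens <- local_density(pool$x, pool$y, w)
        keep <- sample.int(nrow(pool), m,
                           prob = exp(-declust[[stg]] * dens))
        stage_pts[[stg]] <- pool[keep, , drop = FALSE]
      }
    }

    ## pair repulsion: redraw second-species stems inside the hard core
    if (!is.null(cp)) {
      for (k in which(cp$sp2 == sp$code & cp$inhibit_radius > 0)) {
        other <- tabs[[cp$sp1[k]]]
        rad <- cp$inhibit_radius[k]
        for (stg in names(stage_pts)) {
          pts <- stage_pts[[stg]]
          if (!nrow(pts) || !nrow(other)) next
          for (attempt in 1:50) {
            mind <- apply(sqrt(outer(pts$x, other$x, "-")^2 +
                                 outer(pts$y, other$y, "-")^2), 1, min)
            bad <- which(mind < rad)
            if (!length(bad)) break
            pts[bad, ] <- draw_offspring(length(bad))
          }
          stage_pts[[stg]] <- pts
        }
      }
    }

    ## DBH marks: lognormal truncated at 1 cm, matched to stage abundances
    dbh <- numeric(0)
    while (length(dbh) < n_total) {
      d <- stats::rlnorm(2L * (n_total - length(dbh)) + 10L,
                         sp$dbh_meanlog, sp$dbh_sdlog)
      dbh <- c(dbh, d[d >= 1])
    }
    dbh <- sort(dbh[seq_len(n_total)])
    counts <- vapply(stage_pts, nrow, integer(1))
    ## smallest DBHs to saplings, largest to adults; shuffle within stage
    bounds <- cumsum(counts)
    dbh_by_stage <- list(
      sapling = dbh[seq_len(counts[1])],
      pole = dbh[seq_len(counts[2]) + bounds[1]],
      adult = dbh[seq_len(counts[3]) + bounds[2]])
    rows <- do.call(rbind, lapply(names(stage_pts), function(stg) {
      pts <- stage_pts[[stg]]
      if (!nrow(pts)) return(NULL)
      d <- dbh_by_stage[[stg]]
      data.frame(species = sp$code, x = pts$x, y = pts$y,
                 dbh = d[sample.int(length(d))],
                 stringsAsFactors = FALSE)
    }))
    tabs[[sp$code]] <- rows
    truth_species[[sp$code]] <- list(
      sigma = sp$sigma, n_parents = n_parents,
      rho = n_parents / w$area, mu = sp$mu,
      multipliers = sp$multipliers, treelet = sp$treelet,
      stage_declustering = declust)
  }

  all_rows <- do.call(rbind, tabs)
  census <- census_table(tag = sprintf("T%06d", seq_len(nrow(all_rows))),
                         species = all_rows$species,
                         x = all_rows$x, y = all_rows$y, dbh = all_rows$dbh,
                         window = w)
  treelets <- vapply(spec$species, `[[`, logical(1), "treelet")
  names(treelets) <- vapply(spec$species, `[[`, character(1), "code")
  census <- classify_census_stages(census, treelet_flags = treelets)
  census <- assign_stems_to_quadrats(census, qsize)

  truth_pairs <- if (!is.null(spec$coupling))
    data.frame(sp1 = spec$coupling$sp1, sp2 = spec$coupling$sp2,
               sign = ifelse(spec$coupling$share_frac > 0, 1L, -1L),
               stringsAsFactors = FALSE)
  list(census = census, habitat = map, dem = dem,
       ground_truth = list(species = truth_species, pairs = truth_pairs,
                           seed = spec$seed))
}

#' Small deterministic test census
#'
#' Three clustered species (one attraction pair), at most 200 stems, in a
#' 100 x 100 m window; byte-for-byte reproducible for a given seed. Used
#' as a compact fixture throughout the test suite.
#'
#' @param seed master seed.
#' @return see \code{\link{generate_community}}.
#' @export
fixture_small <- function(seed = 42) {
  spec <- community_spec(
    species = list(
      species_spec("SPA", abundance = c(sapling = 45, pole = 20, adult = 10),
                   sigma = 4, mu = 15, dbh_meanlog = log(4), dbh_sdlog = 1),
      species_spec("SPB", abundance = c(sapling = 40, pole = 15, adult = 5),
                   sigma = 5, mu = 12, dbh_meanlog = log(3), dbh_sdlog = 0.8),
      species_spec("SPC", abundance = c(sapling = 40, pole = 20, adult = 5),
                   sigma = 6, mu = 10, dbh_meanlog = log(2.5),
                   dbh_sdlog = 0.7, treelet = TRUE)),
    window = plot_window(100, 100),
    dem = list(base = 740, trend = c(0.1, 0.15),
               hills = list(c(30, 70, 40, 30))),
    coupling = data.frame(sp1 = "SPA", sp2 = "SPB", share_frac = 0.8,
                          inhibit_radius = 0),
    gap_quadrats = 3, seed = seed, quadrat_size = 20)
  generate_community(spec)
}
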