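#' Corner-elevation lattice
#'
#' Elevations (m) surveyed at the corners of a square quadrat grid: an
#' \code{(nx+1) x (ny+1)} node lattice at \code{spacing} m over the plot,
#' node \code{[i, j]} at \code{((i-1) spacing, (j-1) spacing)}.
#'
#' @param z numeric matrix of corner elevations, x index first.
#' @param spacing node spacing (m), the quadrat side.
#' @return object of class \code{elevation_grid}.
#' @export
elevation_grid <- function(z, spacing = 20) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("elevations must be finite", call. = FALSE)
  structure(list(z = z, spacing = spacing,
                 nx = nrow(z) - 1L, ny = ncol(z) - 1L),
            class = "elevation_grid")
}

#' Read a corner-elevation lattice from delimited text
#'
#' Plain whitespace/comma-delimited matrix, one row per line of constant y,
#' rows running south to north, values west to east.
#'
#' @param path file path.
#' @param spacing node spacing (m).
#' @export
read_elevation_grid <- function(path, spacing = 20) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[,\t ]+")[[1]]))
  if (length(unique(lengths(rows))) != 1)
    stop("ragged elevation lattice", call. = FALSE)
  ## file rows are y levels; transpose so matrix index 1 is x
  elevation_grid(t(do.call(rbind, rows)), spacing)
}

#' Per-quadrat topographic metrics
#'
#' For each quadrat: \code{mean_elevation} is the mean of its four corner
#' elevations; \code{slope} (degrees) is the mean inclination of the four
#' planes through the corner triplets, the convention used for large
#' forest-dynamics plots; \code{convexity} (m) is the quadrat's mean
#' elevation minus the mean of its (up to 8) neighbouring quadrats' mean
#' elevations, so ridges are positive and gullies negative.
#'
#' @param grid an \code{elevation_grid}.
#' @return list of three \code{nx x ny} matrices: \code{mean_elevation},
#'   \code{slope}, \code{convexity}.
#' @export
compute_quadrat_metrics <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$z; s <- grid$spacing
  nx <- grid$nx; ny <- grid$ny
  if (nx < 1 || ny < 1) stop("lattice too small for any quadrat", call. = FALSE)
  z00 <- z[1:nx, 1:ny]         # SW corner of each quadrat
  z10 <- z[2:(nx + 1), 1:ny]   # SE... (x index first: z10 is +x)
  z01 <- z[1:nx, 2:(ny + 1)]
  z11 <- z[2:(nx + 1), 2:(ny + 1)]
  mean_elev <- (z00 + z10 + z01 + z11) / 4

  angle <- function(gx, gy) atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope <- (angle((z10 - z00) / s, (z01 - z00) / s) +   # triplet omitting z11
            angle((z10 - z00) / s, (z11 - z10) / s) +   # omitting z01
            angle((z11 - z01) / s, (z01 - z00) / s) +   # omitting z10
            angle((z11 - z01) / s, (z11 - z10) / s)) / 4  # omitting z00

  neigh_sum <- matrix(0, nx, ny)
  neigh_n <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    neigh_sum[okx, oky] <- neigh_sum[okx, oky] + mean_elev[xs[okx], ys[oky]]
    neigh_n[okx, oky] <- neigh_n[okx, oky] + 1
  }
  list(mean_elevation = mean_elev, slope = slope,
       convexity = mean_elev - neigh_sum / neigh_n)
}

habitat_levels <- c("valley", "low-slope", "high-slope", "high-gully",
                    "high-plateau", "gap")

#' Classify quadrats into six topographic habitat types
#'
#' Low ground (elevation below the elevation threshold) splits by slope into
#' \emph{valley} (gentler) and \emph{low-slope} (steeper). High ground splits
#' by convexity and slope: concave (\code{convexity <= 0}) quadrats are
#' \emph{high-gully}; convex ones are \emph{high-slope} when steep and
#' \emph{high-plateau} when gentle. Slope exactly at the threshold counts as
#' steep. Canopy gaps are not derivable from elevation, so they enter as a
#' logical mask and override the topographic class, keeping the six
#' categories a partition (set \code{gap_overrides = FALSE} to keep the
#' topographic label and return the mask alongside).
#'
#' @param metrics result of \code{\link{compute_quadrat_metrics}}.
#' @param thresholds list with \code{slope} (degrees), \code{elevation} (m),
#'   \code{convexity} (m).
#' @param gap_mask optional logical \code{nx x ny} matrix of gap quadrats.
#' @param gap_overrides should gaps replace the topographic class?
#' @return object of class \code{habitat_map}: list with \code{category}
#'   (factor matrix via character \code{nx x ny}), \code{thresholds},
#'   \code{gap_mask}.
#' @export
classify_habitat <- function(metrics,
                             thresholds = list(slope = 27.1,
                                               elevation = 764.87,
                                               convexity = 0),
                             gap_mask = NULL, gap_overrides = TRUE) {
  e <- metrics$mean_elevation; sl <- metrics$slope; cv <- metrics$convexity
  cat_ <- ifelse(e < thresholds$elevation,
                 ifelse(sl < thresholds$slope, "valley", "low-slope"),
                 ifelse(cv <= thresholds$convexity, "high-gully",
                        ifelse(sl >= thresholds$slope, "high-slope",
                               "high-plateau")))
  if (!is.null(gap_mask) && gap_overrides) cat_[gap_mask] <- "gap"
  habitat_map(matrix(cat_, nrow(e), ncol(e)), thresholds, gap_mask)
}

#' Construct a habitat map from a category matrix
#'
#' @param category character \code{nx x ny} matrix with values among the six
#'   habitat types.
#' @param thresholds thresholds used (metadata).
#' @param gap_mask optional logical gap mask (metadata).
#' @export
habitat_map <- function(category, thresholds = NULL, gap_mask = NULL) {
  stopifnot(is.matrix(category))
  if (!all(category %in% habitat_levels))
    stop("unknown habitat categories: ",
         paste(setdiff(unique(c(category)), habitat_levels), collapse = ", "),
         call. = FALSE)
  structure(list(category = category, nx = nrow(category), ny = ncol(category),
                 thresholds = thresholds, gap_mask = gap_mask),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat map: %d x %d quadrats\n", x$nx, x$ny))
  print(habitat_counts(x))
  invisible(x)
}

#' Per-habitat quadrat counts
#'
#' @param map a \code{habitat_map}.
#' @return named integer vector over the six habitat types.
#' @export
habitat_counts <- function(map) {
  table(factor(c(map$category), levels = habitat_levels))
}

#' Write a habitat map as delimited text plus a JSON summary
#'
#' One row per quadrat (\code{ix}, \code{iy} zero-based, \code{category});
#' a sidecar \code{<path>.json} records category counts and thresholds.
#'
#' @param map a \code{habitat_map}.
#' @param path output TSV path.
#' @export
write_habitat_map <- function(map, path) {
  idx <- expand.grid(ix = seq_len(map$nx) - 1L, iy = seq_len(map$ny) - 1L)
  utils::write.table(data.frame(idx, category = c(map$category)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(habitat_counts(map)), thresholds = map$thresholds),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
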