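#' Read a stem census table
#'
#' Reads a delimited stem table (comma or tab, autodetected from the header
#' line) with columns \code{tag}, \code{species}, \code{x}, \code{y},
#' \code{dbh}: one row per stem, coordinates in metres from the plot's
#' south-west corner, DBH in cm.
#'
#' @param path path to the census file.
#' @param window a \code{\link{plot_window}} giving the plot extent.
#' @param min_dbh census minimum DBH (cm); smaller stems are an error.
#' @return a \code{census_table}: data frame with columns \code{tag},
#'   \code{species}, \code{x}, \code{y}, \code{dbh} and attribute
#'   \code{window}.
#' @export
read_census <- function(path, window, min_dbh = 1.0) {
  if (!file.exists(path)) stop("census file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  needed <- c("tag", "species", "x", "y", "dbh")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("census file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    v
  }
  census_table(tag = raw$tag, species = raw$species,
               x = num("x"), y = num("y"), dbh = num("dbh"),
               window = window, min_dbh = min_dbh)
}

#' Construct a validated census table
#'
#' @param tag unique stem identifiers.
#' @param species species codes (non-empty strings).
#' @param x,y stem coordinates (m).
#' @param dbh stem diameters at breast height (cm).
#' @param window a \code{\link{plot_window}}.
#' @param min_dbh census minimum DBH (cm).
#' @return a \code{census_table} data frame (see \code{\link{read_census}}).
#' @export
census_table <- function(tag, species, x, y, dbh, window, min_dbh = 1.0) {
  stopifnot(inherits(window, "plot_window"))
  n <- length(tag)
  if (length(species) == 1) species <- rep(species, n)
  stopifnot(length(species) == n, length(x) == n, length(y) == n,
            length(dbh) == n)
  if (any(!nzchar(species)))
    stop("empty species code(s) in census", call. = FALSE)
  out_of_window <- x < 0 | x > window$Lx | y < 0 | y > window$Ly
  if (any(out_of_window))
    stop("stem(s) outside the window: ",
         paste(utils::head(tag[out_of_window], 5), collapse = ", "),
         call. = FALSE)
  if (any(dbh < min_dbh))
    stop("stem(s) below census minimum DBH: ",
         paste(utils::head(tag[dbh < min_dbh], 5), collapse = ", "),
         call. = FALSE)
  structure(data.frame(tag = as.character(tag), species = as.character(species),
                       x = as.numeric(x), y = as.numeric(y),
                       dbh = as.numeric(dbh), stringsAsFactors = FALSE),
            window = window, min_dbh = min_dbh,
            class = c("census_table", "data.frame"))
}

#' Write a census table to delimited text
#'
#' @param census a \code{census_table}.
#' @param path output path; tab-separated with header.
#' @export
write_census <- function(census, path) {
  utils::write.table(as.data.frame(census)[c("tag", "species", "x", "y", "dbh")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

census_window <- function(census) attr(census, "window")

#' Assign stems to 20 m quadrats
#'
#' Adds zero-based quadrat indices \code{(qx, qy) = (floor(x/s), floor(y/s))}
#' with half-open cells; stems exactly on the plot's upper boundary are
#' clamped into the last quadrat so every stem is assigned.
#'
#' @param census a \code{census_table}.
#' @param quadrat_size cell side (m).
#' @return the census with integer columns \code{qx}, \code{qy} added.
#' @export
assign_stems_to_quadrats <- function(census, quadrat_size = 20) {
  w <- census_window(census)
  nqx <- as.integer(ceiling(w$Lx / quadrat_size))
  nqy <- as.integer(ceiling(w$Ly / quadrat_size))
  census$qx <- pmin(as.integer(floor(census$x / quadrat_size)), nqx - 1L)
  census$qy <- pmin(as.integer(floor(census$y / quadrat_size)), nqy - 1L)
  census
}

#' Point pattern of one species (optionally one life stage)
#'
#' @param census a \code{census_table} (with a \code{stage} column if
#'   \code{stage} is given).
#' @param species_code species code.
#' @param stage optional life stage filter.
#' @return a \code{\link{point_pattern}}.
#' @export
species_pattern <- function(census, species_code, stage = NULL) {
  rows <- census$species == species_code
  if (!is.null(stage)) {
    if (is.null(census$stage)) stop("census has no stage column", call. = FALSE)
    rows <- rows & census$stage == stage
  }
  point_pattern(census$x[rows], census$y[rows], census_window(census))
}

#' Species importance-value summaries
#'
#' Per-species relative density (RD, percent of stems), relative dominance
#' (RA, percent of total basal area, basal area of a stem being
#' \code{pi (dbh/2)^2}), relative frequency (RF, percent of total
#' quadrat occupancy over species) and the importance value
#' \code{IV = RD + RA + RF} (max 300). \code{percent_of_total} is RD rounded
#' to one decimal, as conventionally tabulated.
#'
#' @param census a \code{census_table}.
#' @param quadrat_size quadrat side (m) for the frequency component.
#' @return data frame, one row per species, sorted by decreasing IV.
#' @export
compute_species_summaries <- function(census, quadrat_size = 20) {
  if (nrow(census) == 0) stop("empty census", call. = FALSE)
  census <- assign_stems_to_quadrats(census, quadrat_size)
  sp <- census$species
  n_s <- tapply(rep(1, nrow(census)), sp, sum)
  ba <- tapply(pi * (census$dbh / 2)^2, sp, sum)
  occ <- tapply(census$qx * 10000L + census$qy, sp,
                function(q) length(unique(q)))
  rd <- 100 * n_s / sum(n_s)
  ra <- 100 * ba / sum(ba)
  rf <- 100 * occ / sum(occ)
  out <- data.frame(species = names(n_s), n_stems = as.integer(n_s),
                    relative_density = as.numeric(rd),
                    relative_dominance = as.numeric(ra),
                    relative_frequency = as.numeric(rf),
                    importance_value = as.numeric(rd + ra + rf),
                    percent_of_total = round(as.numeric(rd), 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$importance_value), , drop = FALSE]
}
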