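#' Analysis configuration
#'
#' Bundles every tunable of the uni-/bivariate analyses with its default:
#' 199 null simulations with envelope rank k = 5 (pointwise two-sided level
#' 2k/(m+1) = 0.05), Epanechnikov bandwidth 30 m on a 2 m grid, 2 m rings
#' with centres 1, 3, ..., 49 m, goodness-of-fit interval 0-30 m,
#' small-scale association window 0-5 m, and a minimum of 20 points per
#' pattern for an analysis to run.
#'
#' @param n_sims null simulations per analysis.
#' @param k envelope rank.
#' @param h intensity bandwidth (m).
#' @param cell intensity grid cell (m).
#' @param bins a \code{\link{distance_bins}}.
#' @param gof_interval GoF summation interval (m).
#' @param scale_window small-scale window (m) for pair labels.
#' @param min_points minimum pattern size analysed.
#' @param alpha significance threshold for the GoF gate.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_sims = 199, k = 5, h = 30, cell = 2,
                            bins = distance_bins(r_max = 50, width = 2),
                            gof_interval = c(0, 30), scale_window = c(0, 5),
                            min_points = 20, alpha = 0.05) {
  structure(list(n_sims = n_sims, k = k, h = h, cell = cell, bins = bins,
                 gof_interval = gof_interval, scale_window = scale_window,
                 min_points = min_points, alpha = alpha),
            class = "pipeline_config")
}

#' Deterministic per-task seed derived from a master seed
#'
#' Hashes the task labels (species, stage, pair order, ...) together with
#' the master seed so that parallel and serial runs agree and every task
#' gets an independent, reproducible stream. Result is in [1, 2^31 - 2].
#'
#' @param master_seed integer master seed.
#' @param ... character/numeric task labels.
#' @export
derive_seed <- function(master_seed, ...) {
  s <- paste(c(master_seed, ...), collapse = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483563
  as.integer(h + 1)
}

## Shared core: observed pcf + m null pcfs + envelopes + GoF.
mc_analysis <- function(observed_pcf, simulate_fn, pcf_fn, config) {
  null_g <- vapply(seq_len(config$n_sims),
                   function(i) pcf_fn(simulate_fn())$g,
                   numeric(length(config$bins$centers)))
  env <- envelopes(observed_pcf$g, null_g, k = config$k)
  gof <- gof_test(observed_pcf$g, null_g, config$bins, config$gof_interval)
  list(pcf = observed_pcf, envelope = env, gof = gof)
}

#' Univariate analysis of one species-stage pattern
#'
#' Estimates the pattern's own intensity surface (Epanechnikov kernel),
#' simulates heterogeneous Poisson null patterns from it, and compares the
#' observed pair-correlation function against envelopes and the
#' goodness-of-fit test. Per-bin flags: \code{aggregated} above the upper
#' envelope, \code{regular} below the lower, \code{random} inside.
#'
#' @param census a \code{census_table} (stages classified).
#' @param species_code species to analyse.
#' @param stage life stage (\code{"sapling"}, \code{"pole"}, \code{"adult"}),
#'   or \code{NULL} for all stems of the species.
#' @param config a \code{\link{pipeline_config}}.
#' @param seed RNG seed for the null simulations.
#' @return list of class \code{univariate_record}: species, stage, n,
#'   \code{pcf}, \code{envelope}, \code{gof}, \code{flags}; or a skipped
#'   record (\code{skipped = TRUE} with a reason) when the pattern is
#'   smaller than \code{config$min_points}.
#' @export
analyze_univariate <- function(census, species_code, stage = NULL,
                               config = pipeline_config(), seed = 1) {
  pat <- species_pattern(census, species_code, stage)
  rec <- list(species = species_code, stage = stage %||% "all", n = pat$n)
  if (pat$n < config$min_points) {
    rec$skipped <- TRUE
    rec$reason <- sprintf("only %d points (< %d)", pat$n, config$min_points)
    return(structure(rec, class = "univariate_record"))
  }
  set.seed(seed)
  surf <- estimate_intensity(pat, h = config$h, cell = config$cell)
  obs <- pcf_univariate(pat, config$bins)
  res <- mc_analysis(obs, function() simulate_hpp(surf, pat$n),
                     function(p) pcf_univariate(p, config$bins), config)
  rec <- c(rec, res, list(skipped = FALSE))
  rec$flags <- ifelse(is.na(res$envelope$flag), NA_character_,
                      c(above = "aggregated", below = "regular",
                        inside = "random")[res$envelope$flag])
  structure(rec, class = "univariate_record")
}

#' Bivariate analysis of one ordered species pair at one stage
#'
#' Keeps the first species' stems fixed and randomises the second species
#' under a heterogeneous Poisson null built from the second species' own
#' pattern, so habitat preference of species 2 is retained while its
#' small-scale arrangement is randomised. Envelopes and GoF as in
#' \code{\link{analyze_univariate}}; the small-scale label is set by
#' \code{\link{classify_pair}}.
#'
#' @param census a \code{census_table} (stages classified).
#' @param sp1,sp2 focal and target species codes.
#' @param stage life stage or \code{NULL}.
#' @param config a \code{\link{pipeline_config}}.
#' @param seed RNG seed.
#' @return list of class \code{pair_record}: sp1, sp2, stage, n1, n2,
#'   \code{pcf} (g12), \code{envelope}, \code{gof}, \code{label} in
#'   {p, n, r}; or a skipped record.
#' @export
analyze_bivariate <- function(census, sp1, sp2, stage = NULL,
                              config = pipeline_config(), seed = 1) {
  p1 <- species_pattern(census, sp1, stage)
  p2 <- species_pattern(census, sp2, stage)
  rec <- list(sp1 = sp1, sp2 = sp2, stage = stage %||% "all",
              n1 = p1$n, n2 = p2$n)
  if (p1$n < config$min_points || p2$n < config$min_points) {
    rec$skipped <- TRUE
    rec$reason <- sprintf("pattern sizes %d, %d (min %d)", p1$n, p2$n,
                          config$min_points)
    return(structure(rec, class = "pair_record"))
  }
  set.seed(seed)
  surf2 <- estimate_intensity(p2, h = config$h, cell = config$cell)
  obs <- pcf_bivariate(p1, p2, config$bins)
  res <- mc_analysis(obs, function() simulate_hpp(surf2, p2$n),
                     function(p) pcf_bivariate(p1, p, config$bins), config)
  rec <- c(rec, res, list(skipped = FALSE))
  rec <- structure(rec, class = "pair_record")
  rec$label <- classify_pair(rec, window = config$scale_window,
                             alpha = config$alpha)
  rec
}

#' Small-scale association label of a pair record
#'
#' \code{"r"} (random/no association) unless the goodness-of-fit test
#' rejects over its interval AND the observed g12 leaves the envelope at
#' some bin inside the small-scale window; otherwise the sign of the
#' excursion at the smallest such bin: \code{"p"} above (attraction),
#' \code{"n"} below (repulsion).
#'
#' @param record a \code{pair_record} from \code{\link{analyze_bivariate}}.
#' @param window distance window (m), default 0-5 m.
#' @param alpha GoF gate threshold.
#' @return one of \code{"p"}, \code{"n"}, \code{"r"}.
#' @export
classify_pair <- function(record, window = c(0, 5), alpha = 0.05) {
  if (isTRUE(record$skipped)) return(NA_character_)
  if (record$gof$p >= alpha) return("r")
  r <- record$pcf$r
  sel <- which(r >= window[1] & r <= window[2])
  flags <- record$envelope$flag[sel]
  hit <- which(flags %in% c("above", "below"))
  if (!length(hit)) return("r")
  if (flags[hit[1]] == "above") "p" else "n"
}

#' Enumerate ordered heterospecific pair tasks
#'
#' All ordered pairs of distinct species, repeated for every stage:
#' 20 species give 380 pairs per stage and 1140 tasks over three stages.
#'
#' @param species_codes character vector, >= 2 species.
#' @param stages character vector of life stages.
#' @return data frame with columns \code{sp1}, \code{sp2}, \code{stage}.
#' @export
enumerate_pairs <- function(species_codes,
                            stages = c("sapling", "pole", "adult")) {
  species_codes <- unique(species_codes)
  if (length(species_codes) < 2) stop("need at least 2 species", call. = FALSE)
  pairs <- expand.grid(sp2 = species_codes, sp1 = species_codes,
                       stringsAsFactors = FALSE)[c("sp1", "sp2")]
  pairs <- pairs[pairs$sp1 != pairs$sp2, , drop = FALSE]
  out <- merge(pairs, data.frame(stage = stages), by = NULL)
  rownames(out) <- NULL
  out[order(match(out$stage, stages), match(out$sp1, species_codes),
            match(out$sp2, species_codes)), , drop = FALSE]
}

#' Count significant attractions and repulsions by scale
#'
#' Per distance bin, how many pair records sit above (attraction) or below
#' (repulsion) their envelopes. With \code{gof_gate = TRUE} only records
#' whose GoF test rejects are counted.
#'
#' @param pair_records list of \code{pair_record}s (skipped ones ignored).
#' @param stage optional stage filter.
#' @param gof_gate require GoF rejection before counting excursions.
#' @param alpha GoF threshold.
#' @return data frame: r, attraction, repulsion, n_pairs.
#' @export
tabulate_by_scale <- function(pair_records, stage = NULL, gof_gate = TRUE,
                              alpha = 0.05) {
  recs <- Filter(function(rec) !isTRUE(rec$skipped) &&
                   (is.null(stage) || identical(rec$stage, stage)),
                 pair_records)
  if (!length(recs)) stop("no analysable pair records", call. = FALSE)
  r <- recs[[1]]$pcf$r
  att <- rep_len(0L, length(r)); repl <- rep_len(0L, length(r))
  for (rec in recs) {
    if (!identical(rec$pcf$r, r))
      stop("pair records on different bins", call. = FALSE)
    if (gof_gate && rec$gof$p >= alpha) next
    att <- att + (rec$envelope$flag %in% "above")
    repl <- repl + (rec$envelope$flag %in% "below")
  }
  data.frame(r = r, attraction = att, repulsion = repl,
             n_pairs = length(recs))
}

#' Proportions of positive / negative / random pair labels
#'
#' @param pair_records list of \code{pair_record}s.
#' @param stage optional stage filter.
#' @return data frame with one row per label: count, denominator, percent
#'   (one decimal).
#' @export
summarize_proportions <- function(pair_records, stage = NULL) {
  recs <- Filter(function(rec) !isTRUE(rec$skipped) &&
                   (is.null(stage) || identical(rec$stage, stage)),
                 pair_records)
  if (!length(recs)) stop("no analysable pair records", call. = FALSE)
  labels <- vapply(recs, function(rec) rec$label, character(1))
  n <- length(labels)
  counts <- table(factor(labels, levels = c("p", "n", "r")))
  data.frame(label = names(counts), count = as.integer(counts),
             of = n, percent = round(100 * as.integer(counts) / n, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run univariate analyses for many species-stage tasks
#'
#' @param census a \code{census_table} with stages.
#' @param species_codes species to analyse.
#' @param stages life stages.
#' @param config a \code{\link{pipeline_config}}.
#' @param master_seed per-task seeds derive from this (see
#'   \code{\link{derive_seed}}), so serial and parallel runs agree.
#' @return list of \code{univariate_record}s.
#' @export
run_univariate_suite <- function(census, species_codes,
                                 stages = c("sapling", "pole", "adult"),
                                 config = pipeline_config(), master_seed = 1) {
  tasks <- expand.grid(species = species_codes, stage = stages,
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tasks)), function(i)
    analyze_univariate(census, tasks$species[i], tasks$stage[i], config,
                       seed = derive_seed(master_seed, "uni",
                                          tasks$species[i], tasks$stage[i])))
}

#' Run bivariate analyses for a pair-task table
#'
#' @param census a \code{census_table} with stages.
#' @param pairs data frame from \code{\link{enumerate_pairs}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param master_seed see \code{\link{run_univariate_suite}}.
#' @return list of \code{pair_record}s.
#' @export
run_bivariate_suite <- function(census, pairs, config = pipeline_config(),
                                master_seed = 1) {
  lapply(seq_len(nrow(pairs)), function(i)
    analyze_bivariate(census, pairs$sp1[i], pairs$sp2[i], pairs$stage[i],
                      config,
                      seed = derive_seed(master_seed, "biv", pairs$sp1[i],
                                         pairs$sp2[i], pairs$stage[i])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
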