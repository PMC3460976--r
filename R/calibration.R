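## Monte-Carlo calibration experiments for the null-model machinery.
## These re-run the full estimator + envelope / GoF pipeline on data drawn
## from the null itself, so their rejection rates measure the realised
## significance level of the procedures.

#' Pointwise rejection rate of simulation envelopes under CSR
#'
#' Draws CSR patterns, builds for each a pointwise envelope at a single
#' distance bin from fresh CSR simulations, and reports how often the
#' pattern's own pair-correlation value falls outside. Under
#' exchangeability the expected rate is \code{2k / (n_sims + 1)}.
#'
#' @param n_rep number of replicates.
#' @param n_points points per pattern.
#' @param window a \code{\link{plot_window}}.
#' @param bin_center,bin_width the evaluation ring (m).
#' @param n_sims null simulations per envelope.
#' @param k envelope rank.
#' @param seed RNG seed.
#' @return list: \code{rate}, \code{n_rep}, \code{nominal}.
#' @export
calibrate_envelope_rejection <- function(n_rep = 500, n_points = 100,
                                         window = plot_window(200, 200),
                                         bin_center = 10, bin_width = 2,
                                         n_sims = 199, k = 5, seed = 1) {
  bins <- distance_bins(centers = bin_center, width = bin_width)
  set.seed(seed)
  outside <- vapply(seq_len(n_rep), function(i) {
    obs <- pcf_univariate(simulate_csr(n_points, window), bins)$g
    nulls <- vapply(seq_len(n_sims), function(j)
      pcf_univariate(simulate_csr(n_points, window), bins)$g, numeric(1))
    env <- envelopes(obs, matrix(nulls, 1), k = k)
    env$flag != "inside"
  }, logical(1))
  list(rate = mean(outside), n_rep = n_rep, nominal = 2 * k / (n_sims + 1))
}

#' Type-I error of the goodness-of-fit rank test under CSR
#'
#' Draws CSR patterns and tests each against fresh CSR simulations with the
#' GoF rank test over a distance interval, reporting the rejection rate at
#' \code{alpha}.
#'
#' @param n_rep number of replicates.
#' @param n_points points per pattern.
#' @param window a \code{\link{plot_window}}.
#' @param interval GoF summation interval (m).
#' @param n_sims null simulations per test.
#' @param alpha rejection threshold.
#' @param seed RNG seed.
#' @return list: \code{rate}, \code{p_values}, \code{n_rep}, \code{alpha}.
#' @export
calibrate_gof_type1 <- function(n_rep = 400, n_points = 100,
                                window = plot_window(200, 200),
                                interval = c(0, 30), n_sims = 199,
                                alpha = 0.05, seed = 1) {
  bins <- distance_bins(r_max = interval[2], width = 2)
  set.seed(seed)
  ps <- vapply(seq_len(n_rep), function(i) {
    obs <- pcf_univariate(simulate_csr(n_points, window), bins)$g
    nulls <- vapply(seq_len(n_sims), function(j)
      pcf_univariate(simulate_csr(n_points, window), bins)$g,
      numeric(length(bins$centers)))
    gof_test(obs, nulls, bins, interval)$p
  }, numeric(1))
  list(rate = mean(ps < alpha), p_values = ps, n_rep = n_rep, alpha = alpha)
}
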