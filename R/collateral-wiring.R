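#' Wiring configuration for recurrent-collateral analytics
#'
#' Parameters of the binomial model of contact within a nuclear group:
#' each of `m` presynaptic cells contacts `z` of the `n` DCNs at random
#' (divergence 1:z), so a given DCN is contacted by a given presynaptic
#' cell with probability `z/n`.
#'
#' @param n DCN group size (default 50).
#' @param z divergence: DCNs contacted per presynaptic cell (default 5);
#'   0 < z <= n.
#' @param m number of presynaptic cells.
#' @return A `collateral_config` list with fields `n`, `z`, `m` and the
#'   per-cell contact probability `p = z/n`.
#' @export
collateral_config <- function(n = 50, z = 5, m = 10) {
  if (z <= 0 || z > n) stop("require 0 < z <= n")
  if (m < 0) stop("`m` must be non-negative")
  structure(list(n = n, z = z, m = m, p = z / n),
            class = "collateral_config")
}

#' Probability that a DCN receives contact from exactly y presynaptic cells
#'
#' Evaluates the closed-form contact probability
#' `P(y) = (z/n)^y * (1 - z/n)^(m - y) * choose(m, y)`:
#' a binomial pmf in `y` with `m` trials and success probability `z/n`.
#'
#' @param y number of contacting presynaptic cells; 0 <= y <= m. Vectorized.
#' @param config a [collateral_config()].
#' @return Probability(ies).
#' @examples
#' contact_pmf(0, collateral_config(n = 50, z = 5, m = 10)) # 0.9^10
#' @export
contact_pmf <- function(y, config) {
  stopifnot(inherits(config, "collateral_config"))
  if (any(y < 0) || any(y > config$m)) stop("require 0 <= y <= m")
  p <- config$p
  p^y * (1 - p)^(config$m - y) * choose(config$m, y)
}

#' Probability that a DCN receives contact from at least y presynaptic cells
#'
#' `P(y or more) = 1 - sum_{j < y} P(j)`; `prob_at_least(0, ...)` is 1.
#'
#' @inheritParams contact_pmf
#' @param y contact-count threshold (scalar, 0 <= y <= m).
#' @return Probability.
#' @export
prob_at_least <- function(y, config) {
  stopifnot(inherits(config, "collateral_config"), length(y) == 1L)
  if (y < 0 || y > config$m) stop("require 0 <= y <= m")
  if (y == 0) return(1)
  1 - sum(contact_pmf(0:(y - 1), config))
}

#' Probability that exactly x DCNs receive contact from at least y cells
#'
#' The printed joint form treats DCNs as independent, each contacted by at
#' least `y` of the `m` presynaptic cells with probability
#' `q = prob_at_least(y)`:
#' `P = q^x * (1 - q)^(n - x) * choose(n, x)`.
#' In the true wiring process the per-DCN counts are weakly negatively
#' dependent (each presynaptic cell places exactly `z` contacts), which
#' the Monte-Carlo simulator [simulate_collateral_wiring()] quantifies; the
#' marginal per-DCN distribution, and hence all expectations linear in the
#' per-DCN indicators, are exact.
#'
#' @param x number of DCNs, 0 <= x <= n. Vectorized.
#' @inheritParams prob_at_least
#' @return Probability(ies).
#' @export
joint_prob_x_dcns <- function(x, y, config) {
  stopifnot(inherits(config, "collateral_config"))
  if (any(x < 0) || any(x > config$n)) stop("require 0 <= x <= n")
  q <- prob_at_least(y, config)
  q^x * (1 - q)^(config$n - x) * choose(config$n, x)
}

#' Expected number of DCNs contacted by at least y presynaptic cells
#'
#' @inheritParams prob_at_least
#' @return List with `expected` (`n * prob_at_least(y)`) and `rounded`.
#' @examples
#' # 10 Purkinje cells, divergence 1:5, group of 50: about 33 DCNs contacted
#' expected_contacted(1, collateral_config(50, 5, 10))
#' @export
expected_contacted <- function(y, config) {
  e <- config$n * prob_at_least(y, config)
  list(expected = e, rounded = round(e))
}

#' Monte-Carlo simulation of collateral wiring
#'
#' Draws the wiring process directly: each of the `m` presynaptic cells
#' contacts a uniform random subset of `z` out of `n` DCNs (without
#' replacement within a cell, independently across cells). Serves as the
#' simulation counterpart of the closed-form analytics, including a check
#' on the independence assumption of [joint_prob_x_dcns()].
#'
#' @param config a [collateral_config()].
#' @param n_reps number of independent wiring replicates.
#' @param y contact-count threshold for the "contacted" summary (default 1).
#' @param seed optional seed.
#' @return List with `mean_contacted` (mean number of DCNs with >= `y`
#'   contacts), `se_contacted` (standard error of that mean), and
#'   `count_freq` (pooled relative frequency of per-DCN contact counts,
#'   indexed 0..m).
#' @export
simulate_collateral_wiring <- function(config, n_reps = 1e4, y = 1,
                                       seed = NULL) {
  stopifnot(inherits(config, "collateral_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n; z <- config$z; m <- config$m
  count_freq <- numeric(m + 1)
  contacted <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    hits <- tabulate(unlist(lapply(seq_len(m), function(j) {
      sample.int(n, z)
    })), nbins = n)
    contacted[r] <- sum(hits >= y)
    tb <- tabulate(hits + 1L, nbins = m + 1L)
    count_freq <- count_freq + tb
  }
  list(mean_contacted = mean(contacted),
       se_contacted = stats::sd(contacted) / sqrt(n_reps),
       count_freq = count_freq / sum(count_freq))
}

#' Distribution of per-DCN spike input in one millisecond bin
#'
#' Simulates a nuclear group under random-sample wiring (each of `n_dcn`
#' DCNs contacted by `convergence` of `n_pc` Purkinje cells, all firing at
#' a shared constant probability) and returns the number of spikes each DCN
#' receives in a single 1 ms bin, or the rolling mean over the trailing
#' `window_bins` bins when `rolled = TRUE`. Its theoretical counterpart
#' (with the refractory period disabled) is Binomial(`convergence`,
#' per-afferent spike probability per bin).
#'
#' @param rate_hz shared constant firing rate (default 147.5 Hz, one
#'   mid-cycle timestep of the step-cycle sinusoid).
#' @param n_pc,n_dcn,convergence wiring parameters, see [sample_wiring()].
#' @param bin_index which 1 ms bin to read out (default 5).
#' @param rolled take a rolling mean of consecutive bins (window
#'   `window_bins`) before reading out.
#' @param window_bins rolling window in bins (default 2).
#' @param bin_ms,dt,refractory_ms grid parameters.
#' @param seed optional seed.
#' @return Numeric vector of `n_dcn` per-DCN values.
#' @export
dcn_count_distribution <- function(rate_hz = 147.5, n_pc = 400, n_dcn = 50,
                                   convergence = 40, bin_index = 5,
                                   rolled = FALSE, window_bins = 2,
                                   bin_ms = 1, dt = 0.05, refractory_ms = 1,
                                   seed = NULL) {
  if (rate_hz < 0) stop("`rate_hz` must be non-negative")
  if (rolled && bin_index < window_bins) {
    stop("`bin_index` must be >= `window_bins` for a rolled readout")
  }
  if (!is.null(seed)) set.seed(seed)
  wiring <- sample_wiring(n_pc, n_dcn, convergence, seed = NULL)
  duration_ms <- bin_index * bin_ms
  raster <- generate_ensemble(constant_rate(rate_hz), n_pc, duration_ms,
                              dt, refractory_ms, seed = NULL)
  steps_per_bin <- as.integer(round(bin_ms / dt))
  per_cell_bins <- t(apply(raster, 1, function(row) {
    colSums(matrix(row, nrow = steps_per_bin))
  }))
  vapply(wiring, function(idx) {
    counts <- colSums(per_cell_bins[idx, , drop = FALSE])
    if (rolled) {
      rolling_mean(counts, window_bins)[bin_index - window_bins + 1]
    } else {
      counts[bin_index]
    }
  }, numeric(1))
}

#' Resample a distribution by sample means
#'
#' Models innervation by recurrent axon collaterals: each of
#' `resample_count` DCNs randomly samples `sample_size` values of the
#' source distribution (with replacement; divergence assumption 1:5 gives
#' the default sample size 5) and averages them. Averaging narrows the
#' distribution: the CV of the means falls below the CV of the source by
#' about `sqrt(sample_size)` for a near-normal source.
#'
#' @param x source values (non-empty numeric).
#' @param resample_count number of sample means to draw (default 50, one
#'   per DCN of a group).
#' @param sample_size values averaged per draw (default 5; >= 1).
#' @param replace sample with replacement (default TRUE).
#' @param seed optional seed.
#' @return Numeric vector of `resample_count` sample means.
#' @export
resample_means <- function(x, resample_count = 50, sample_size = 5,
                           replace = TRUE, seed = NULL) {
  if (length(x) == 0) stop("source distribution is empty")
  if (sample_size < 1) stop("`sample_size` must be >= 1")
  if (!replace && sample_size > length(x)) {
    stop("`sample_size` exceeds the source when sampling without replacement")
  }
  if (!is.null(seed)) set.seed(seed)
  if (replace) {
    draws <- matrix(sample(x, resample_count * sample_size, replace = TRUE),
                    nrow = resample_count)
    rowMeans(draws)
  } else {
    # without replacement applies within one draw; draws stay independent
    vapply(seq_len(resample_count),
           function(i) mean(sample(x, sample_size, replace = FALSE)),
           numeric(1))
  }
}
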