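#' Random-sample wiring from a microzone onto a nuclear group
#'
#' Each DCN of the group receives contact from a uniformly random subset of
#' the Purkinje cells afferent to the group, drawn without replacement
#' within a cell but independently across cells ("replacement" at group
#' level: one DCN's sample has no influence on any other's).
#'
#' @param n_pc afferent Purkinje-cell population (default 400).
#' @param n_dcn number of DCNs in the group (default 50).
#' @param convergence afferents sampled per DCN (default 40, the
#'   physiological mean); must be <= `n_pc`.
#' @param seed optional seed; fixed seed gives identical wiring.
#' @return List of `n_dcn` sorted integer index vectors into `1:n_pc`.
#' @export
sample_wiring <- function(n_pc = 400, n_dcn = 50, convergence = 40,
                          seed = NULL) {
  if (convergence > n_pc) stop("`convergence` cannot exceed `n_pc`")
  if (convergence < 1 || n_dcn < 1) stop("counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_dcn), function(i) sort(sample.int(n_pc, convergence)))
}

#' Simulate inhibitory current into every DCN of a nuclear group
#'
#' One ensemble of `n_pc` Purkinje trains shares a synchronized
#' time-varying spike probability (default: a sinusoid spanning one 400 ms
#' cycle). Each DCN receives the summed spikes of its own random sample of
#' afferents; its somatic current is the superposition of unit quanta,
#' smoothed with a short rolling mean. Because DCNs independently sample
#' the same population, their traces bunch tightly around the group mean:
#' the group output is synchronized.
#'
#' @param profile shared rate profile (default sinusoid 50-250 Hz,
#'   wavelength 400 ms).
#' @param n_pc,n_dcn,convergence wiring parameters, see [sample_wiring()].
#' @param taus decay constants in ms.
#' @param duration_ms simulation length (default 400, one cycle). A warning
#'   is issued if it does not cover one full cycle of a sinusoid profile.
#' @param window_ms rolling-mean window in ms (default 1).
#' @param dt,refractory_ms grid parameters.
#' @param seed optional root seed.
#' @return A list with `wiring` and, per tau (named by tau), a list of
#'   `traces` (matrix, DCNs x samples, rolled) and `mean_trace`.
#' @export
simulate_group <- function(profile = sinusoid_rate(100, 150, 400),
                           n_pc = 400, n_dcn = 50, convergence = 40,
                           taus = c(1.25, 2.5, 5, 7.5), duration_ms = 400,
                           window_ms = 1, dt = 0.05, refractory_ms = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (profile$kind == "sinusoid" && duration_ms < profile$wavelength_ms) {
    warning("duration does not cover one full cycle of the rate profile")
  }
  wiring <- sample_wiring(n_pc, n_dcn, convergence, seed = NULL)
  raster <- generate_ensemble(profile, n_pc, duration_ms, dt, refractory_ms,
                              seed = NULL)
  per_tau <- lapply(taus, function(tau) {
    kernel <- make_kernel(tau, dt = dt)
    traces <- t(vapply(wiring, function(idx) {
      counts <- colSums(raster[idx, , drop = FALSE])
      as.numeric(rolling_current(superpose(counts, kernel, dt = dt),
                                 window_ms))
    }, numeric(ncol(raster) - round(window_ms / dt) + 1)))
    list(traces = traces, mean_trace = colMeans(traces))
  })
  names(per_tau) <- as.character(taus)
  c(list(wiring = wiring), per_tau)
}

#' Simulate subdivision of one DCN soma into subregions
#'
#' The somatic surface is divided into `n_subregions` sites, each contacted
#' by a random sample of `sample_size` out of the `pool` Purkinje cells
#' afferent to the cell (the pool exceeds the count of "significant"
#' afferents). Each site's charge-entry trace is computed as for a whole
#' soma; the across-site mean represents charge entry to the cell.
#'
#' @param profile rate profile (default constant 50 Hz).
#' @param pool afferent pool size (default 60).
#' @param n_subregions number of somatic sites (default 40).
#' @param sample_size afferents per site (default 30); must be <= `pool`.
#' @param taus decay constants in ms.
#' @param duration_ms run length (default 200; 4,000 samples at 0.05 ms).
#' @param dt,refractory_ms grid parameters.
#' @param seed optional root seed.
#' @return A list with `wiring` and, per tau, `traces` (subregions x
#'   samples, raw) and `mean_trace`.
#' @export
simulate_subregions <- function(profile = constant_rate(50), pool = 60,
                                n_subregions = 40, sample_size = 30,
                                taus = c(1.25, 2.5, 5, 7.5),
                                duration_ms = 200, dt = 0.05,
                                refractory_ms = 1, seed = NULL) {
  if (sample_size > pool) stop("`sample_size` cannot exceed `pool`")
  if (!is.null(seed)) set.seed(seed)
  wiring <- sample_wiring(pool, n_subregions, sample_size, seed = NULL)
  raster <- generate_ensemble(profile, pool, duration_ms, dt, refractory_ms,
                              seed = NULL)
  per_tau <- lapply(taus, function(tau) {
    kernel <- make_kernel(tau, dt = dt)
    traces <- t(vapply(wiring, function(idx) {
      counts <- colSums(raster[idx, , drop = FALSE])
      as.numeric(superpose(counts, kernel, dt = dt))
    }, numeric(ncol(raster))))
    list(traces = traces, mean_trace = colMeans(traces))
  })
  names(per_tau) <- as.character(taus)
  c(list(wiring = wiring), per_tau)
}

#' Compare linearity of mean charge entry with and without subregions
#'
#' For each rate, one seed-matched ensemble of `pool` cells drives (a) a
#' whole soma contacted by the full pool and (b) `n_subregions` sites each
#' sampling `sample_size` of the pool, averaged across sites. Returns the
#' 200 ms mean current of both arms; subdividing the soma leaves the linear
#' relation of mean current and discharge rate essentially unchanged.
#'
#' @param rates constant rates in Hz.
#' @param tau decay constant in ms (default 2.5).
#' @inheritParams simulate_subregions
#' @return data.frame with columns `rate`, `mean_full`, `mean_subdivided`.
#' @export
subregion_sweep <- function(rates = seq(50, 200, by = 10), tau = 2.5,
                            pool = 60, n_subregions = 40, sample_size = 30,
                            duration_ms = 200, dt = 0.05, refractory_ms = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kernel <- make_kernel(tau, dt = dt)
  rows <- lapply(rates, function(rate) {
    wiring <- sample_wiring(pool, n_subregions, sample_size, seed = NULL)
    raster <- generate_ensemble(constant_rate(rate), pool, duration_ms, dt,
                                refractory_ms, seed = NULL)
    full <- superpose(raster, kernel)
    sub_means <- vapply(wiring, function(idx) {
      counts <- colSums(raster[idx, , drop = FALSE])
      mean(superpose(counts, kernel, dt = dt))
    }, numeric(1))
    data.frame(rate = rate, mean_full = mean(full),
               mean_subdivided = mean(sub_means))
  })
  do.call(rbind, rows)
}

#' Pointwise across-DCN spread and synchrony of a simulated group
#'
#' @param group_tau one per-tau element of a [simulate_group()] result.
#' @return List with `pointwise_sd` (mean over time of the across-DCN SD),
#'   `pointwise_cv` (mean over time of across-DCN SD / mean) and
#'   `mean_pairwise_corr` of the rolled traces.
#' @export
group_synchrony <- function(group_tau) {
  traces <- group_tau$traces
  sds <- apply(traces, 2, stats::sd)
  mus <- colMeans(traces)
  list(pointwise_sd = mean(sds),
       pointwise_cv = mean(sds / mus),
       mean_pairwise_corr = pairwise_correlation(t(traces))$mean)
}
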