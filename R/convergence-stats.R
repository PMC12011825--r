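#' Spike counts per bin across converging afferents
#'
#' Sums spikes across all cells of a raster in consecutive bins (default
#' 1 ms), giving the combined spike input received by one postsynaptic DCN
#' from its afferent Purkinje cells.
#'
#' @param raster a `spike_raster` from [generate_ensemble()].
#' @param bin_ms bin width in ms; must be a whole number of timesteps and
#'   divide the raster duration.
#' @return A `binned_counts` integer vector with attributes `n_afferents`
#'   and `bin_ms`.
#' @export
bin_counts <- function(raster, bin_ms = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  dt <- attr(raster, "dt")
  steps_per_bin <- bin_ms / dt
  if (abs(steps_per_bin - round(steps_per_bin)) > 1e-9) {
    stop("`bin_ms` must be a whole number of timesteps")
  }
  steps_per_bin <- as.integer(round(steps_per_bin))
  n_steps <- ncol(raster)
  if (n_steps %% steps_per_bin != 0L) {
    stop("`bin_ms` must divide the raster duration")
  }
  total <- colSums(raster)
  counts <- as.integer(colSums(matrix(total, nrow = steps_per_bin)))
  structure(counts, class = "binned_counts",
            n_afferents = nrow(raster), bin_ms = bin_ms)
}

#' Trailing rolling mean
#'
#' Arithmetic mean over a trailing window, "valid" edges: the output has
#' `length(x) - window + 1` elements, the first being the mean of
#' `x[1:window]`. Used as a proxy for postsynaptic integration of binned
#' spike counts and for sub-millisecond smoothing of current traces.
#'
#' @param x numeric series.
#' @param window window length in samples (>= 1, <= `length(x)`).
#' @return Numeric vector of rolled means.
#' @export
rolling_mean <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("`window` must be >= 1")
  if (window > n) stop("`window` larger than the series")
  x <- as.numeric(x)
  if (window == 1) return(x)
  cs <- cumsum(c(0, x))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Jitter of binned spike counts
#'
#' Jitter is the mean absolute difference in spike count between consecutive
#' bins, normalized by the convergence ratio (number of afferent cells) and
#' expressed as a percentage. It measures bin-to-bin roughness relative to
#' what a single afferent could contribute.
#'
#' @param counts numeric or `binned_counts` series (>= 2 bins).
#' @param n_afferents convergence ratio; defaults to the `n_afferents`
#'   attribute when `counts` is a `binned_counts`.
#' @return Jitter in percent.
#' @export
count_jitter <- function(counts, n_afferents = attr(counts, "n_afferents")) {
  if (is.null(n_afferents) || n_afferents < 1) {
    stop("`n_afferents` must be a positive count")
  }
  if (length(counts) < 2) stop("need at least 2 bins")
  100 * mean(abs(diff(as.numeric(counts)))) / n_afferents
}

#' Coefficient of variation
#'
#' @param x numeric vector with non-zero mean.
#' @return `sd(x) / mean(x)`.
#' @export
cv <- function(x) stats::sd(x) / mean(x)

#' Mean and SD of all pairwise Pearson correlations
#'
#' @param mat numeric matrix, one column per series.
#' @return List with `mean`, `sd` and the vector of pairwise correlations.
#' @export
pairwise_correlation <- function(mat) {
  stopifnot(ncol(mat) >= 2)
  cm <- stats::cor(mat)
  r <- cm[upper.tri(cm)]
  list(mean = mean(r), sd = stats::sd(r), r = r)
}

#' Reliability of the decoded rate signal vs convergence ratio
#'
#' For each convergence ratio, simulates `n_cycles` independent cycles of an
#' ensemble of that many afferents, bins the summed spikes (1 ms bins),
#' optionally integrates with a short rolling mean, and computes the Pearson
#' correlation over all pairs of cycles. High correlation means the decoded
#' signal reproducibly tracks the underlying probability function.
#'
#' @param ratios integer convergence ratios (each >= 1).
#' @param profile shared rate profile (default: sinusoid 50-250 Hz over a
#'   200 ms step cycle).
#' @param n_cycles number of independent cycles (>= 2; default 20).
#' @param duration_ms cycle length in ms.
#' @param window integration window in bins (default 2, a rolling mean of
#'   consecutive counts); `integrated = FALSE` correlates raw counts.
#' @param integrated logical; correlate integrated series (default) or raw.
#' @param bin_ms,dt,refractory_ms grid parameters, see [generate_ensemble()].
#' @param seed optional root seed.
#' @return data.frame with columns `ratio`, `mean_corr`, `sd_corr`.
#' @export
reliability_curve <- function(ratios,
                              profile = sinusoid_rate(100, 150, 200),
                              n_cycles = 20, duration_ms = 200, window = 2,
                              integrated = TRUE, bin_ms = 1, dt = 0.05,
                              refractory_ms = 1, seed = NULL) {
  if (any(ratios < 1)) stop("convergence ratios must be >= 1")
  if (n_cycles < 2) stop("`n_cycles` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(ratios, function(ratio) {
    series <- vapply(seq_len(n_cycles), function(j) {
      raster <- generate_ensemble(profile, ratio, duration_ms, dt,
                                  refractory_ms, seed = NULL)
      counts <- bin_counts(raster, bin_ms)
      if (integrated) rolling_mean(counts, window) else as.numeric(counts)
    }, numeric(duration_ms / bin_ms - if (integrated) window - 1 else 0))
    pc <- pairwise_correlation(series)
    data.frame(ratio = ratio, mean_corr = pc$mean, sd_corr = pc$sd)
  })
  do.call(rbind, out)
}

#' Noise-reduction summary across convergence ratios
#'
#' For each convergence ratio, simulates `n_cycles` cycles and averages the
#' coefficient of variation of the binned counts and the jitter with and
#' without rolling-mean integration. Increasing convergence reduces the CV
#' and jitter of the combined input; integration reduces jitter further at
#' every ratio.
#'
#' @inheritParams reliability_curve
#' @return data.frame with one row per ratio: `ratio`, `cv`,
#'   `jitter_raw`, `jitter_integrated`.
#' @export
convergence_summary <- function(ratios,
                                profile = sinusoid_rate(100, 150, 200),
                                n_cycles = 20, duration_ms = 200, window = 2,
                                bin_ms = 1, dt = 0.05, refractory_ms = 1,
                                seed = NULL) {
  if (any(ratios < 1)) stop("convergence ratios must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(ratios, function(ratio) {
    per_cycle <- vapply(seq_len(n_cycles), function(j) {
      raster <- generate_ensemble(profile, ratio, duration_ms, dt,
                                  refractory_ms, seed = NULL)
      counts <- bin_counts(raster, bin_ms)
      integrated <- rolling_mean(counts, window)
      c(cv = cv(as.numeric(counts)),
        jitter_raw = count_jitter(counts),
        jitter_integrated = count_jitter(integrated, ratio))
    }, c(cv = 0, jitter_raw = 0, jitter_integrated = 0))
    means <- rowMeans(per_cycle)
    data.frame(ratio = ratio, cv = means[["cv"]],
               jitter_raw = means[["jitter_raw"]],
               jitter_integrated = means[["jitter_integrated"]])
  })
  do.call(rbind, out)
}
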