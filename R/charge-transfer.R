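#' Unit quantum of inhibitory charge entry
#'
#' Builds the stereotyped current waveform triggered by one afferent spike:
#' a fast linear rise to a peak of 1 (the unit of current), then exponential
#' decay with constant `tau_ms`. The waveform is truncated where it falls
#' below `trunc` of the peak, giving bounded support for exact convolution.
#' The quantum is inviolable: it has the same shape for every spike and
#' overlapping quanta sum linearly.
#'
#' @param tau_ms decay constant in ms (> 0). The simulations use
#'   1.25, 2.5, 5 and 7.5 ms; ~2.5 ms is the reported physiological value
#'   in mice.
#' @param rise_ms rise time in ms; default one timestep.
#' @param dt timestep in ms (> 0, default 0.05).
#' @param trunc truncation threshold as a fraction of peak (default 1e-6).
#' @return A `quantum_kernel` numeric vector (samples at `dt` spacing,
#'   peak = 1) with attributes `tau_ms`, `rise_ms`, `dt`, `peak_index`.
#' @examples
#' k <- make_kernel(2.5)
#' max(k)  # 1
#' @export
make_kernel <- function(tau_ms, rise_ms = dt, dt = 0.05, trunc = 1e-6) {
  if (tau_ms <= 0) stop("`tau_ms` must be positive")
  if (dt <= 0) stop("`dt` must be positive")
  if (rise_ms < 0) stop("`rise_ms` must be non-negative")
  rise_steps <- max(1L, as.integer(round(rise_ms / dt)))
  rise <- seq_len(rise_steps) / rise_steps
  n_decay <- ceiling(tau_ms * log(1 / trunc) / dt)
  decay <- exp(-(seq_len(n_decay) * dt) / tau_ms)
  decay <- decay[decay >= trunc]
  structure(c(rise, decay), class = "quantum_kernel", tau_ms = tau_ms,
            rise_ms = rise_ms, dt = dt, peak_index = rise_steps)
}

#' @export
print.quantum_kernel <- function(x, ...) {
  cat(sprintf("<quantum_kernel> tau %g ms, rise %g ms, %d samples at dt %g ms\n",
              attr(x, "tau_ms"), attr(x, "rise_ms"), length(x), attr(x, "dt")))
  invisible(x)
}

#' Superpose unit quanta over a spike train
#'
#' Convolves the summed spike train with the quantum kernel: every spike
#' launches one copy of the kernel at its own timestep and all copies add
#' linearly, with no saturation. This is the total inhibitory current
#' entering the soma per timestep, in units of the peak current of one
#' quantum.
#'
#' @param spikes a `spike_raster` (cells are summed) or a numeric vector of
#'   spike counts per timestep.
#' @param kernel a [make_kernel()] quantum; its `dt` must match the raster's.
#' @param dt timestep in ms; required only when `spikes` is a bare vector.
#' @return A `current_trace` numeric vector (one value per timestep) with
#'   attributes `dt` and `duration_ms`.
#' @export
superpose <- function(spikes, kernel, dt = NULL) {
  stopifnot(inherits(kernel, "quantum_kernel"))
  if (inherits(spikes, "spike_raster")) {
    dt <- attr(spikes, "dt")
    counts <- colSums(spikes)
  } else {
    if (is.null(dt)) stop("`dt` is required for a bare count vector")
    counts <- as.numeric(spikes)
  }
  if (abs(dt - attr(kernel, "dt")) > 1e-12) {
    stop("timestep mismatch between spikes and kernel")
  }
  n <- length(counts)
  k <- length(kernel)
  padded <- c(numeric(k - 1), counts)
  trace <- stats::filter(padded, as.numeric(kernel), method = "convolution",
                         sides = 1)
  trace <- as.numeric(trace)[k:(k + n - 1)]
  structure(trace, class = "current_trace", dt = dt, duration_ms = n * dt)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples at dt %g ms (%g ms), mean %.4g\n",
              length(x), attr(x, "dt"), attr(x, "duration_ms"),
              mean(as.numeric(x))))
  invisible(x)
}

#' Rolling mean of a current trace
#'
#' Trailing mean over a short time window (0.1, 0.5 or 1 ms in the figure
#' conditions), mimicking fast but not instantaneous voltage-proportional
#' charge expulsion from the soma. "Valid" edges: the output is shorter by
#' `window_ms/dt - 1` samples.
#'
#' @param trace a `current_trace` (or numeric vector with `dt` given).
#' @param window_ms window in ms; must be >= `dt` and a whole number of
#'   timesteps.
#' @param dt timestep in ms; taken from the trace attribute by default.
#' @return A `current_trace` of rolled values.
#' @export
rolling_current <- function(trace, window_ms, dt = attr(trace, "dt")) {
  if (is.null(dt)) stop("`dt` is required")
  if (window_ms < dt) stop("`window_ms` must be at least one timestep")
  w <- window_ms / dt
  if (abs(w - round(w)) > 1e-9) {
    stop("`window_ms` must be a whole number of timesteps")
  }
  rolled <- rolling_mean(as.numeric(trace), as.integer(round(w)))
  structure(rolled, class = "current_trace", dt = dt,
            duration_ms = length(rolled) * dt)
}

#' Linearity sweep of mean charge entry vs discharge probability
#'
#' Runs one ensemble of `n_cells` Purkinje cells per rate over
#' `duration_ms`, and for each decay constant computes the mean and CV of
#' the current trace (and of its rolled version when `window_ms` is given).
#' The mean of the trace over the full run is linearly related to the
#' nominal discharge rate for every decay constant.
#'
#' @param rates constant firing rates in Hz (non-empty, all >= 0).
#' @param taus decay constants in ms (default `c(1.25, 2.5, 5, 7.5)`).
#' @param n_cells afferents per run (default 40, the physiological mean
#'   convergence).
#' @param duration_ms run length in ms (default 200).
#' @param window_ms optional rolling window in ms; adds `mean_rolled` and
#'   `cv_rolled` columns.
#' @param dt,refractory_ms,rise_ms see [generate_ensemble()], [make_kernel()].
#' @param seed optional root seed.
#' @return data.frame with columns `rate`, `tau`, `mean_current`, `cv`
#'   (plus rolled columns when requested).
#' @export
linearity_sweep <- function(rates = 50:200, taus = c(1.25, 2.5, 5, 7.5),
                            n_cells = 40, duration_ms = 200,
                            window_ms = NULL, dt = 0.05, refractory_ms = 1,
                            rise_ms = dt, seed = NULL) {
  if (length(rates) == 0) stop("`rates` must be non-empty")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  kernels <- lapply(taus, make_kernel, rise_ms = rise_ms, dt = dt)
  rows <- vector("list", length(rates) * length(taus))
  i <- 0L
  for (rate in rates) {
    raster <- generate_ensemble(constant_rate(rate), n_cells, duration_ms,
                                dt, refractory_ms, seed = NULL)
    for (j in seq_along(taus)) {
      trace <- superpose(raster, kernels[[j]])
      row <- data.frame(rate = rate, tau = taus[j],
                        mean_current = mean(trace),
                        cv = if (mean(trace) > 0) cv(as.numeric(trace)) else NA_real_)
      if (!is.null(window_ms)) {
        rolled <- rolling_current(trace, window_ms)
        row$mean_rolled <- mean(rolled)
        row$cv_rolled <- if (mean(rolled) > 0) cv(as.numeric(rolled)) else NA_real_
      }
      i <- i + 1L
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows)
}
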