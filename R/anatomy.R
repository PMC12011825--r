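#' Small anatomical/arithmetic helpers
#'
#' Convenience quantities used throughout the model of Purkinje-cell
#' contact on the DCN soma.
#'
#' `interspike_interval_ms` is the mean interval between spikes at a given
#' constant rate (5 ms at 200 Hz, the time available for intrabouton GABA
#' to return to baseline between spikes).
#'
#' @param rate_hz firing rate in Hz (> 0).
#' @return Interval in ms.
#' @export
interspike_interval_ms <- function(rate_hz) {
  if (any(rate_hz <= 0)) stop("`rate_hz` must be positive")
  1000 / rate_hz
}

#' @rdname interspike_interval_ms
#' @param n_afferents afferent Purkinje cells per DCN (default 40).
#' @param boutons_per_afferent boutons per afferent on one soma (default 30,
#'   the midpoint of the reported 24-36 range).
#' @return Total bouton count on the soma (1,200 at the defaults).
#' @export
total_boutons <- function(n_afferents = 40, boutons_per_afferent = 30) {
  if (any(n_afferents < 0) || any(boutons_per_afferent < 0)) {
    stop("counts must be non-negative")
  }
  n_afferents * boutons_per_afferent
}

#' @rdname interspike_interval_ms
#' @param subset subset size (e.g. 10 Purkinje cells).
#' @param population population size (e.g. 400 afferent to a nuclear
#'   group).
#' @return Subset as a percentage of the population (2.5% at 10 of 400).
#' @export
afferent_fraction_pct <- function(subset, population) {
  if (any(population <= 0)) stop("`population` must be positive")
  if (any(subset < 0)) stop("`subset` must be non-negative")
  100 * subset / population
}
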