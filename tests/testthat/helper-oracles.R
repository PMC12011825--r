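# Independent brute-force oracles used across the suite. Each is a direct,
# unoptimized restatement of the definition, kept free of the package's own
# computational paths.

# Per-event superposition: walk every spike and add a shifted copy of the
# kernel into the trace.
naive_superpose <- function(raster, kernel) {
  n <- ncol(raster)
  k <- length(kernel)
  trace <- numeric(n)
  for (cell in seq_len(nrow(raster))) {
    for (s in which(raster[cell, ] == 1L)) {
      idx <- s:min(n, s + k - 1)
      trace[idx] <- trace[idx] + kernel[seq_along(idx)]
    }
  }
  trace
}

# Trailing rolling mean by explicit loop.
naive_rolling_mean <- function(x, window) {
  n <- length(x)
  out <- numeric(n - window + 1)
  for (i in seq_along(out)) out[i] <- mean(x[i:(i + window - 1)])
  out
}

# Jitter by explicit loop over consecutive bin pairs.
naive_jitter <- function(counts, n_afferents) {
  s <- 0
  for (i in 2:length(counts)) s <- s + abs(counts[i] - counts[i - 1])
  100 * s / ((length(counts) - 1) * n_afferents)
}

# Binomial pmf by enumeration of all 2^m contact patterns of m cells, each
# contacting with probability p.
enumerate_contact_pmf <- function(y, m, p) {
  total <- 0
  for (pattern in 0:(2^m - 1)) {
    bits <- sum(bitwAnd(pattern, 2^(0:(m - 1))) > 0)
    if (bits == y) total <- total + p^bits * (1 - p)^(m - bits)
  }
  total
}

# Step-cycle profile shared by the convergence experiments (50-250 Hz).
step_cycle_profile <- function() sinusoid_rate(100, 150, 200)
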