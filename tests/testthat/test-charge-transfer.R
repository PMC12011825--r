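test_that("quantum kernel has unit peak, 1/e decay point and bounded support", {
  for (tau in c(1.25, 2.5, 5, 7.5)) {
    k <- make_kernel(tau)
    expect_equal(max(k), 1)
    expect_true(all(k >= 0))
    # value tau ms after the peak is 1/e of the peak
    peak <- attr(k, "peak_index")
    expect_equal(k[peak + round(tau / 0.05)], exp(-1))
    # truncated below 1e-6 of peak
    expect_gte(min(k), 1e-6)
  }
  expect_lt(length(make_kernel(1.25)), length(make_kernel(7.5)))
  expect_error(make_kernel(0), "positive")
  expect_error(make_kernel(2.5, dt = 0), "positive")
})

test_that("superposition copies the kernel per spike and sums linearly", {
  k <- make_kernel(2.5)
  counts <- numeric(4000)
  counts[100] <- 1
  tr <- superpose(counts, k, dt = 0.05)
  expect_equal(as.numeric(tr)[100:(99 + length(k))], as.numeric(k))
  expect_equal(as.numeric(tr)[1:99], numeric(99))
  # two coincident spikes double the waveform
  counts[100] <- 2
  expect_equal(max(superpose(counts, k, dt = 0.05)), 2)
  expect_error(superpose(counts, make_kernel(2.5, dt = 0.1), dt = 0.05),
               "mismatch")
})

test_that("superposition equals the naive per-event loop to machine precision", {
  for (tau in c(1.25, 7.5)) {
    k <- make_kernel(tau)
    r <- generate_ensemble(constant_rate(50), 40, 100, seed = 5)
    expect_equal(as.numeric(superpose(r, k)), naive_superpose(r, k),
                 tolerance = 1e-12)
  }
})

test_that("no charge is created or lost by superposition", {
  # spikes confined to the first half so every quantum decays fully in-trace
  k <- make_kernel(2.5)
  set.seed(6)
  counts <- c(rpois(2000, 0.2), numeric(2000))
  tr <- superpose(counts, k, dt = 0.05)
  expect_equal(sum(tr), sum(counts) * sum(k), tolerance = 1e-12)
})

test_that("rolling a current trace smooths and gains precision for short tau", {
  k <- make_kernel(1.25)
  r <- generate_ensemble(constant_rate(50), 40, 200, seed = 9)
  tr <- superpose(r, k)
  expect_equal(as.numeric(rolling_current(tr, 0.05)), as.numeric(tr))
  expect_lt(cv(as.numeric(rolling_current(tr, 1))), cv(as.numeric(tr)))
  const <- structure(rep(2.5, 100), class = "current_trace", dt = 0.05)
  expect_equal(as.numeric(rolling_current(const, 1)), rep(2.5, 81))
  expect_error(rolling_current(tr, 0.01), "at least one timestep")
})

test_that("mean current is linear in rate; doubling the rate doubles it", {
  sw <- linearity_sweep(rates = c(0, 60, 120), taus = 2.5, n_cells = 40,
                        refractory_ms = 0, seed = 13)
  expect_equal(sw$mean_current[sw$rate == 0], 0)
  # doubling the rate doubles mean current (refractory off), within 3 SE:
  # replicate the 60/120 pair over seeds and compare
  pairs <- vapply(1:10, function(s) {
    d <- linearity_sweep(rates = c(60, 120), taus = 2.5, n_cells = 40,
                         refractory_ms = 0, seed = 100 + s)
    d$mean_current[d$rate == 120] / d$mean_current[d$rate == 60]
  }, numeric(1))
  expect_lt(abs(mean(pairs) - 2), 3 * stats::sd(pairs) / sqrt(10))
  expect_error(linearity_sweep(rates = numeric(0)), "non-empty")
})

test_that("longer decay constants smooth the trace but widen its absolute range", {
  stats_by_tau <- vapply(1:20, function(s) {
    r <- generate_ensemble(constant_rate(50), 40, 200, seed = 300 + s)
    vapply(c(1.25, 2.5, 5, 7.5), function(tau) {
      tr <- as.numeric(superpose(r, make_kernel(tau)))
      c(sd = stats::sd(tr), cv = cv(tr))
    }, c(sd = 0, cv = 0))
  }, matrix(0, 2, 4))
  means <- apply(stats_by_tau, c(1, 2), mean)
  # absolute spread around the mean grows with tau (data vary in a larger
  # range even though they vary more smoothly) ...
  expect_true(all(diff(means["sd", ]) > 0))
  # ... while the shot-noise CV shrinks as overlapping quanta average out
  # (filtered-Poisson scaling: CV ~ 1/sqrt(rate * tau))
  expect_true(all(diff(means["cv", ]) < 0))
})
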