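test_that("wiring samples uniformly, without replacement, reproducibly", {
  w <- sample_wiring(n_pc = 400, n_dcn = 50, convergence = 40, seed = 1)
  expect_length(w, 50)
  expect_true(all(vapply(w, function(s) length(unique(s)) == 40, logical(1))))
  expect_identical(w, sample_wiring(400, 50, 40, seed = 1))
  # convergence = n_pc gives the full population to every DCN
  full <- sample_wiring(60, 5, 60, seed = 2)
  expect_true(all(vapply(full, identical, logical(1), y = 1:60)))
  # each Purkinje cell is sampled by 50 * 40 / 400 = 5 DCNs on average
  # (exact: total contacts are fixed at n_dcn * convergence)
  per_pc <- tabulate(unlist(w), nbins = 400)
  expect_equal(mean(per_pc), 5)
  expect_error(sample_wiring(10, 5, 11), "exceed")
})

test_that("a group sampling the full population produces identical traces", {
  sim <- simulate_group(n_pc = 30, n_dcn = 4, convergence = 30, taus = 2.5,
                        duration_ms = 100,
                        profile = sinusoid_rate(100, 150, 100), seed = 3)
  tr <- sim[["2.5"]]$traces
  for (i in 2:4) expect_equal(tr[i, ], tr[1, ])
  expect_equal(sim[["2.5"]]$mean_trace, tr[1, ])
})

test_that("across-DCN spread of the sampled mean shrinks with convergence", {
  # spread of the per-afferent mean trace scales as 1/sqrt(convergence)
  sd40 <- group_synchrony(simulate_group(taus = 2.5, convergence = 40,
                                         seed = 1)[["2.5"]])$pointwise_sd / 40
  sd80 <- group_synchrony(simulate_group(taus = 2.5, convergence = 80,
                                         seed = 1)[["2.5"]])$pointwise_sd / 80
  expect_lt(sd80, sd40)
})

test_that("group traces are synchronized and bunch around the mean", {
  sim <- simulate_group(taus = c(2.5, 7.5), seed = 4)
  syn25 <- group_synchrony(sim[["2.5"]])
  # regression bound: traces of independent random samples co-modulate
  expect_gt(syn25$mean_pairwise_corr, 0.85)
  # across-DCN pointwise spread < across-time spread of one trace
  tr <- sim[["2.5"]]$traces
  expect_lt(syn25$pointwise_cv, cv(tr[1, ]))
  # precision (absolute across-DCN spread in current units) inversely
  # related to the duration of the decay constant
  expect_lt(syn25$pointwise_sd, group_synchrony(sim[["7.5"]])$pointwise_sd)
  expect_warning(simulate_group(n_pc = 20, n_dcn = 2, convergence = 5,
                                duration_ms = 100, taus = 2.5, seed = 1),
                 "full cycle")
})

test_that("subregion simulation matches the 40 x 4000 layout and averages", {
  sim <- simulate_subregions(taus = 2.5, seed = 5)
  expect_equal(dim(sim[["2.5"]]$traces), c(40, 4000))
  expect_equal(sim[["2.5"]]$mean_trace, colMeans(sim[["2.5"]]$traces))
  # sampling the full pool makes all subregion traces identical
  same <- simulate_subregions(pool = 20, n_subregions = 3, sample_size = 20,
                              taus = 2.5, duration_ms = 50, seed = 6)
  tr <- same[["2.5"]]$traces
  expect_equal(tr[2, ], tr[1, ])
  expect_equal(tr[3, ], tr[1, ])
  expect_error(simulate_subregions(pool = 10, sample_size = 11), "exceed")
})

test_that("subdividing the soma preserves the linearity of mean vs rate", {
  sw <- subregion_sweep(rates = seq(50, 200, by = 25), tau = 2.5, seed = 7)
  r2_full <- summary(stats::lm(mean_full ~ rate, sw))$r.squared
  r2_sub <- summary(stats::lm(mean_subdivided ~ rate, sw))$r.squared
  expect_lt(abs(r2_full - r2_sub), 0.01)
  expect_gt(r2_full, 0.98)
})
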