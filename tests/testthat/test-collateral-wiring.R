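test_that("contact pmf matches enumeration over all contact patterns", {
  cfg <- collateral_config(n = 50, z = 5, m = 10)
  expect_equal(contact_pmf(0, cfg), 0.9^10)
  expect_equal(sum(contact_pmf(0:10, cfg)), 1)
  expect_equal(contact_pmf(0, collateral_config(50, 5, 0)), 1)
  # brute-force 2^m enumeration oracle, m <= 12
  for (m in c(6, 10)) {
    cfgm <- collateral_config(50, 5, m)
    for (y in 0:m) {
      expect_equal(contact_pmf(y, cfgm), enumerate_contact_pmf(y, m, 0.1),
                   tolerance = 1e-12)
    }
  }
  # independent binomial route as cross-check
  expect_equal(contact_pmf(0:10, cfg), dbinom(0:10, 10, 0.1))
  expect_error(contact_pmf(11, cfg), "<= m")
  expect_error(collateral_config(50, 0, 10), "0 < z")
})

test_that("tail and joint probabilities follow the printed closed forms", {
  cfg <- collateral_config(50, 5, 10)
  expect_equal(prob_at_least(0, cfg), 1)
  expect_equal(prob_at_least(1, cfg), 1 - 0.9^10)
  expect_equal(prob_at_least(3, cfg), 1 - pbinom(2, 10, 0.1))
  # joint form = binomial in the number of DCNs with tail prob as success
  q <- prob_at_least(2, cfg)
  expect_equal(joint_prob_x_dcns(0:50, 2, cfg), dbinom(0:50, 50, q))
  expect_equal(sum(joint_prob_x_dcns(0:50, 2, cfg)), 1)
})

test_that("expected contacted DCNs reproduce the wiring anchors", {
  cfg10 <- collateral_config(50, 5, 10)
  ec <- expected_contacted(1, cfg10)
  expect_equal(ec$expected, 50 * (1 - 0.9^10))
  expect_equal(ec$rounded, 33)
  # 33 recurrent axons, divergence 1:5 -> 86% of DCNs doubly contacted
  expect_equal(round(100 * prob_at_least(2, collateral_config(50, 5, 33))),
               86)
})

test_that("analytics agree with the Monte-Carlo wiring simulation", {
  cfg <- collateral_config(50, 5, 10)
  mc <- simulate_collateral_wiring(cfg, n_reps = 2e4, y = 1, seed = 2)
  expect_lt(abs(mc$mean_contacted - expected_contacted(1, cfg)$expected),
            3 * mc$se_contacted)
  # pooled per-DCN contact counts follow the binomial pmf
  pooled_n <- 2e4 * 50
  pmf <- contact_pmf(0:10, cfg)
  se <- sqrt(pmf * (1 - pmf) / pooled_n)
  expect_true(all(abs(mc$count_freq - pmf) < pmax(4 * se, 1e-4)))
})

test_that("per-DCN spike counts in one bin follow the binomial oracle", {
  expect_equal(dcn_count_distribution(rate_hz = 0, seed = 1), rep(0, 50))
  # refractory disabled: expected count = convergence * rate/1000 per ms
  means <- vapply(1:8, function(s) {
    mean(dcn_count_distribution(rate_hz = 147.5, refractory_ms = 0,
                                seed = s))
  }, numeric(1))
  expect_lt(abs(mean(means) - 40 * 0.1475),
            3 * stats::sd(means) / sqrt(8))
  # rolled readout is narrower than the raw readout
  sds <- vapply(1:8, function(s) {
    c(raw = stats::sd(dcn_count_distribution(seed = s)),
      rolled = stats::sd(dcn_count_distribution(rolled = TRUE, seed = s)))
  }, c(raw = 0, rolled = 0))
  expect_lt(mean(sds["rolled", ]), mean(sds["raw", ]))
})

test_that("resampling by sample means narrows the distribution by ~sqrt(k)", {
  expect_equal(resample_means(rep(4, 20), 10, 5, seed = 1), rep(4, 10))
  # CLT oracle on a near-normal source, large counts for precision
  set.seed(3)
  src <- rnorm(5000, mean = 10, sd = 2)
  means <- resample_means(src, resample_count = 5000, sample_size = 5,
                          seed = 4)
  expect_equal(cv(src) / cv(means), sqrt(5), tolerance = 0.05)
  # sample_size 1 changes nothing in expectation
  m1 <- resample_means(src, resample_count = 5000, sample_size = 1, seed = 5)
  expect_equal(cv(m1), cv(src), tolerance = 0.05)
  expect_error(resample_means(numeric(0)), "empty")
  expect_error(resample_means(1:3, 5, 0), ">= 1")
  expect_error(resample_means(1:3, 5, 4, replace = FALSE), "exceeds")
})

test_that("resampling tightens the CV in every repetition batch", {
  set.seed(8)
  tighter <- vapply(1:20, function(r) {
    src <- dcn_count_distribution(seed = NULL)
    cv(resample_means(src, seed = NULL)) < cv(src)
  }, logical(1))
  expect_true(all(tighter))
})
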