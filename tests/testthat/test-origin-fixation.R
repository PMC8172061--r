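# Population-scale semi-Markov model: kernels, likelihoods, sampling,
# stationarity and Monte Carlo p-values.

test_that("omega allocation follows the stationarity rule", {
  f <- def_freqs()
  om <- omega_from_mean_rate(6.05e-4, f)
  expect_equal(om[1], 6.05e-4 / (4 * 243 / 620), tolerance = 1e-12)
  expect_equal(round(om[1], 7), 3.859e-4, tolerance = 1e-4)
  expect_equal(omega_from_mean_rate(2e-3, rep(0.25, 4)), rep(2e-3, 4))
  expect_equal(omega_from_mean_rate(0, f), rep(0, 4))
  expect_error(omega_from_mean_rate(1e-3, c(0.5, 0.5, 0, 0)), "positive")
})

test_that("the Markov kernel is the exact matrix exponential on the cycle", {
  expect_equal(transition_matrix_markov(rep(1e-3, 4), 0), diag(4))
  P <- transition_matrix_markov(rep(1e-3, 4), 1000)
  # Poisson count mod 4: e^-1 (1 + 1/4! + 1/8! + ...)
  expect_equal(P[1, 1], exp(-1) * sum(1 / factorial(seq(0, 24, 4))),
               tolerance = 1e-10)
  expect_equal(round(P[1, 1], 5), 0.38322)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  expect_true(all(P >= 0))
  f <- def_freqs()
  Pinf <- transition_matrix_markov(omega_from_mean_rate(6.05e-4, f), 2e5)
  for (i in 1:4) expect_equal(Pinf[i, ], f, tolerance = 1e-6)
  expect_error(transition_matrix_markov(rep(1e-3, 4), -1), ">= 0")
})

test_that("instantaneous-fixation path probabilities are Poissonian", {
  p <- unif_params()
  h0 <- language_history("x", 0, 1000, 2)
  expect_equal(path_probability(h0, p), -1e-3 * 1000)
  h1 <- language_history("x", 0, 1000, 0, data.frame(time = 500, new_stage = 1))
  expect_equal(path_probability(h1, p), dpois(1, 1, log = TRUE), tolerance = 1e-9)
  # structural zero: the required origination rate is zero
  pz <- of_params(c(1e-3, 0, 1e-3, 1e-3))
  h2 <- language_history("x", 0, 1000, 0,
                         data.frame(time = c(300, 600), new_stage = c(1, 2)))
  expect_identical(path_probability(h2, pz), -Inf)
})

test_that("summing exact-m probabilities reproduces the endpoint kernel", {
  f <- def_freqs()
  om <- omega_from_mean_rate(6.05e-4, f)
  d <- count_distribution(0, 3000, of_params(om))
  ker <- transition_matrix_markov(om, 3000)
  for (j in 0:3) {
    expect_equal(sum(d[seq(j, length(d) - 1, by = 4) + 1]), ker[1, j + 1],
                 tolerance = 1e-6)
  }
  # endpoint likelihood variant agrees with the kernel
  h <- language_history("x", 0, 3000, 0, data.frame(time = 1500, new_stage = 1))
  expect_equal(path_probability(h, of_params(om), variant = "endpoint"),
               log(ker[1, 2]), tolerance = 1e-6)
})

test_that("Gamma-fixation path probabilities match a Monte Carlo oracle", {
  # Oracle: 2e5 simulated sojourn sequences (Exp(1e-3) + Gamma(4, 0.04),
  # i.e. mean fixation 100 yr, variance 2500 yr^2) counted in a 1000-yr
  # window, seed 42: P(m=0) = 0.40611, P(m=1) = 0.40306, P(m=2) = 0.15648,
  # binomial standard errors 0.0011, 0.0011, 0.0008.
  p <- of_params(rep(1e-3, 4), mean_fix = 100, var_fix = 2500)
  h0 <- language_history("x", 0, 1000, 0)
  expect_equal(exp(path_probability(h0, p)), 0.40611, tolerance = 3 * 0.0011 / 0.40611)
  h1 <- language_history("x", 0, 1000, 0, data.frame(time = 500, new_stage = 1))
  expect_equal(exp(path_probability(h1, p)), 0.40306, tolerance = 3 * 0.0011 / 0.40306)
  h2 <- language_history("x", 0, 1000, 0,
                         data.frame(time = c(300, 600), new_stage = c(1, 2)))
  expect_equal(exp(path_probability(h2, p)), 0.15648, tolerance = 3 * 0.0008 / 0.15648)
})

test_that("fixation-time limits recover Markov behaviour", {
  om <- rep(1e-3, 4)
  # vanishing variance acts as a deterministic delay of the last sojourn
  pd <- of_params(om, mean_fix = 100, var_fix = 0.01)
  h0 <- language_history("x", 0, 1050, 0)
  expect_equal(exp(path_probability(h0, pd)), exp(-1e-3 * 950), tolerance = 1e-3)
  # T_F -> 0 converges to the pure Markov kernel
  dm <- count_distribution(0, 1000, of_params(om))
  dg <- count_distribution(0, 1000, of_params(om, mean_fix = 0.5, var_fix = 0.25))
  n <- min(length(dm), length(dg))
  expect_lt(max(abs(dm[seq_len(n)] - dg[seq_len(n)])), 1e-4)
})

test_that("corpus log-likelihood is additive and order-invariant", {
  p <- unif_params()
  h <- language_history("x", 0, 1000, 0, data.frame(time = 500, new_stage = 1))
  two <- corpus(list(h, h))
  expect_equal(corpus_log_likelihood(two, p), 2 * path_probability(h, p))
  expect_equal(corpus_log_likelihood(corpus(list(), "f"), p), 0)
  cp <- tiny_corpus()
  cp_rev <- corpus(rev(cp$histories), cp$feature)
  expect_equal(corpus_log_likelihood(cp, p), corpus_log_likelihood(cp_rev, p))
})

test_that("sampled histories have the right counting statistics", {
  # no origination
  expect_equal(n_changes(sample_history(of_params(rep(0, 4)), 0, 5000, seed = 1)), 0)
  # Poisson law at T_F = 0
  set.seed(2)
  ms <- replicate(4000, n_changes(sample_history(unif_params(), 0, 1000)))
  expect_lt(abs(mean(ms) - 1), 3 * sd(ms) / sqrt(length(ms)))
  # renewal theorem: long-run rate 1/(1/omega + mean_fix)
  hh <- sample_history(of_params(rep(1e-3, 4), 100, 2500), 0, 1e6, seed = 7)
  rate <- n_changes(hh) / 1e6
  expect_lt(abs(rate - 1 / 1100), 3 * sqrt(n_changes(hh)) / 1e6)
  # reproducibility
  expect_identical(sample_history(unif_params(), 0, 5000, seed = 9)$transitions,
                   sample_history(unif_params(), 0, 5000, seed = 9)$transitions)
})

test_that("stationary occupancy follows renewal-reward weights", {
  f <- def_freqs()
  p0 <- of_params(omega_from_mean_rate(6.05e-4, f))
  expect_equal(stationary_occupancy(p0), f, tolerance = 1e-12)
  expect_equal(stationary_occupancy(of_params(rep(1e-3, 4), 300, 100)),
               rep(0.25, 4))
  # general weights 1/omega_i + mean_fix
  p <- of_params(c(1e-3, 2e-3, 5e-4, 1e-3), 250, 100)
  w <- 1 / p$omega + 250
  expect_equal(stationary_occupancy(p), w / sum(w))
  expect_error(stationary_occupancy(of_params(c(0, 1, 1, 1) * 1e-3)), "degenerate")
})

test_that("occupancy of a long simulated trajectory matches the formula", {
  p <- of_params(c(2e-3, 1e-3, 4e-3, 1.5e-3), mean_fix = 150, var_fix = 5000)
  h <- sample_history(p, 0, 2e6, seed = 31)
  # time spent recorded at each stage (stage changes at fixation completion)
  times <- c(h$window_start, h$transitions$time, h$window_end)
  stages <- c(h$initial_stage, h$transitions$new_stage)
  occ <- vapply(0:3, function(s) sum(diff(times)[stages == s]), numeric(1))
  occ <- occ / sum(occ)
  expect_equal(occ, stationary_occupancy(p), tolerance = 0.02)
})

test_that("the Monte Carlo p-value behaves as a goodness-of-fit probability", {
  p <- unif_params()
  # structural zero: nothing can be less likely
  pz <- of_params(c(1e-3, 0, 1e-3, 1e-3))
  h2 <- language_history("x", 0, 1000, 0,
                         data.frame(time = c(300, 600), new_stage = c(1, 2)))
  expect_equal(mc_p_value(corpus(list(h2)), pz, n_sims = 50, seed = 1)$p, 0)
  # a corpus exactly at the modal outcome is not extreme
  set.seed(3)
  cp <- corpus(lapply(1:20, function(i) sample_history(p, 0, 1000,
                                                       language = paste0("l", i))))
  res <- mc_p_value(cp, p, n_sims = 500, seed = 4)
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
  expect_equal(res$log_lik_obs, corpus_log_likelihood(cp, p))
})
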