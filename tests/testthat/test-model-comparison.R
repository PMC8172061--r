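# Theory families, the WF -> OF bridge, AICc machinery and goodness of fit.

test_that("AICc and evidence ratios follow the defining formulas", {
  expect_equal(aicc(1, 52, -63), 128.08)
  expect_equal(aicc(2, 52, -63), 130.2449, tolerance = 1e-7)
  expect_equal(aicc(1, 1e6, -63), 2 - 2 * (-63), tolerance = 1e-5)  # plain AIC limit
  expect_error(aicc(2, 3, -10), "n > k")
  expect_equal(evidence_ratio(0), 1)
  expect_equal(evidence_ratio(10), 148.4132, tolerance = 1e-6)
  expect_equal(log10(evidence_ratio(204)), 44.3, tolerance = 0.005)
})

test_that("theory specifications encode the family constraints", {
  child <- theory_spec("child_based", s = 0.5)
  expect_equal(child$R, 0.04)        # one update per 25-year generation
  expect_equal(child$epsilon, 1)
  expect_equal(child$memory_time, 25)
  usage <- theory_spec("usage_based", R = 1000, memory_time = 0.01)
  expect_equal(usage$epsilon, 1 / (1000 * 0.01))
  expect_true(usage$physical)
  slow <- theory_spec("usage_based", R = 0.01, memory_time = 25)
  expect_equal(slow$epsilon, 4)
  expect_false(slow$physical)        # epsilon > 1 flagged unphysical
  expect_error(theory_spec("usage_based"), "interaction rate")
})

test_that("the WF bridge collapses to the right limits", {
  eta <- rep(1e-3, 4)
  # eta = 0: no origination at all
  expect_equal(of_params_from_wf(wf_params(1000, 1, 0.1))$omega, rep(0, 4))
  # neutral: Q = eps/N exactly, so omega = R eta eps independent of N
  for (N in c(1e3, 1e6)) {
    op <- of_params_from_wf(wf_params(N, 100, 0.01, 0, eta = eta))
    expect_equal(op$omega, 100 * eta * 0.01, tolerance = 1e-9)
  }
  # infinite selection: Q = 1, omega = N R eta, instantaneous fixation
  opI <- of_params_from_wf(wf_params(1000, 0.04, 1, Inf, eta = eta))
  expect_equal(opI$omega, 1000 * 0.04 * eta)
  expect_true(opI$instantaneous)
  # networks enter through the effective size
  net <- powerlaw_moments(1e6, 1.2)
  opn <- of_params_from_wf(wf_params(1e6, 0.04, 1, 0.01, eta = eta), net)
  oph <- of_params_from_wf(wf_params(1e6, 0.04, 1, 0.01, eta = eta))
  expect_lt(opn$mean_fix, oph$mean_fix)  # heterogeneity shortens fixation
})

test_that("baseline fitting recovers a generating rate and scales correctly", {
  f <- def_freqs()
  gen <- of_params(omega_from_mean_rate(6e-4, f))
  cp <- generate_corpus(synthetic_config(52, window_range = c(1500, 1500),
                                         model = gen, f = f, seed = 41))
  fit <- fit_theory(cp, theory_spec("poisson_baseline"), f)
  expect_lt(abs(fit$fitted_rate - 6e-4) / 6e-4, 0.25)
  expect_equal(fit$k, 1L)
  expect_equal(fit$n, 52L)
  expect_equal(fit$aicc, aicc(1, 52, fit$log_likelihood))
  # dimensional consistency: scaling windows by c and rates by 1/c is neutral
  scale_hist <- function(h, c) language_history(
    h$language, h$window_start * c, h$window_end * c, h$initial_stage,
    if (nrow(h$transitions)) data.frame(time = h$transitions$time * c,
                                        new_stage = h$transitions$new_stage),
    h$population_size)
  cp10 <- corpus(lapply(cp$histories, scale_hist, c = 10), cp$feature)
  fit10 <- fit_theory(cp10, theory_spec("poisson_baseline"), f)
  expect_equal(fit10$fitted_rate * 10, fit$fitted_rate, tolerance = 1e-3)
  expect_equal(fit10$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
})

test_that("a changeless corpus drives the baseline rate to its lower bound", {
  f <- def_freqs()
  quiet <- corpus(lapply(1:10, function(i) {
    language_history(paste0("l", i), 0, 1000, 0, population_size = 1e4)
  }), "definite")
  fit <- fit_theory(quiet, theory_spec("poisson_baseline"), f,
                    bounds = c(1e-8, 3e-2))
  expect_lt(fit$fitted_rate, 2e-8 * 10)   # pinned near the lower bound
})

test_that("delta AICc bookkeeping matches the fits", {
  f <- def_freqs()
  cp <- generate_corpus(synthetic_config(20, model = of_params(omega_from_mean_rate(6e-4, f)),
                                         f = f, seed = 42))
  base <- fit_theory(cp, theory_spec("poisson_baseline"), f)
  cand <- against_baseline(fit_theory(cp, theory_spec("child_based", s = Inf), f), base)
  expect_equal(cand$delta_aicc, cand$aicc - base$aicc)
  expect_equal(cand$evidence_ratio, evidence_ratio(cand$delta_aicc))
  expect_error(against_baseline(cand, fit_theory(tiny_corpus(),
                                                 theory_spec("poisson_baseline"), f)),
               "different corpora")
})

test_that("overdispersion detects misfit and spares the generating model", {
  f <- def_freqs()
  gen <- of_params(omega_from_mean_rate(8e-4, f))
  cp <- generate_corpus(synthetic_config(52, model = gen, f = f, seed = 43))
  ok <- overdispersion(cp, gen, "counts", n_sims = 1500, seed = 1)
  expect_lt(abs(ok$mean - 1), 0.6)          # single-corpus noise band
  # a model with half the true rate is overdispersed
  half <- of_params(omega_from_mean_rate(4e-4, f))
  bad <- overdispersion(cp, half, "counts", n_sims = 1500, seed = 2)
  expect_gt(bad$mean, 1.5)
  # binary statistic is defined and bounded by design
  ob <- overdispersion(cp, gen, "binary", n_sims = 1500, seed = 3)
  expect_true(is.finite(ob$mean))
  expect_equal(length(ob$per_language), 52L)
})

test_that("profiled likelihood responds monotonically to nested structure", {
  # with the same emergent family, widening the profile bounds cannot
  # decrease the maximised likelihood
  f <- def_freqs()
  cp <- generate_corpus(synthetic_config(15, model = of_params(omega_from_mean_rate(6e-4, f)),
                                         f = f, seed = 44))
  narrow <- fit_theory(cp, theory_spec("poisson_baseline"), f, bounds = c(1e-4, 2e-4))
  wide <- fit_theory(cp, theory_spec("poisson_baseline"), f, bounds = c(1e-6, 1e-2))
  expect_gte(wide$log_likelihood, narrow$log_likelihood - 1e-6)
})
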