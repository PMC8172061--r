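# Individual-based simulator and diffusion numerics.

test_that("parameter objects validate and derive the memory time", {
  wp <- wf_params(100, 0.04, 1)
  expect_equal(wp$memory_time, 25)
  expect_true(wp$physical)
  expect_false(wf_params(100, 100, 2)$physical)
  expect_error(wf_params(1, 1, 1), "N must")
  expect_error(wf_params(10, 1, 0), "epsilon")
  expect_error(wf_params(10, 1, 0.5, s = -2), "selection")
  expect_error(wf_params(10, 1, 0.5, eta = rep(1, 4)), "eta")
})

test_that("effective population size follows the degree-moment formula", {
  star <- as_social_network(igraph::make_star(5, mode = "undirected"))
  expect_equal(effective_population_size(star, 1), 5 * (1.6^2 / 4))  # 3.2
  reg <- build_regular_network(60, 6, seed = 1)
  expect_equal(effective_population_size(reg, 1), 60)
  expect_equal(effective_population_size(reg, 0.5),
               2 * effective_population_size(reg, 1))
  # discrete-update correction: factor (2 - eps)/2, continuous as eps -> 0
  expect_equal(effective_population_size(reg, 1, discrete = TRUE), 30)
  expect_equal(effective_population_size(reg, 1e-4, discrete = TRUE),
               effective_population_size(reg, 1e-4), tolerance = 1e-4)
  expect_error(effective_population_size(list(N = 5), 1), "social_network")
})

test_that("power-law networks have the requested degree structure", {
  net <- build_powerlaw_network(1000, 5, z_min = 2, seed = 2)
  expect_true(all(net$degrees >= 2))
  ratio <- net$zbar^2 / net$z2bar
  expect_gte(ratio, 0.8)   # near-homogeneous at nu = 5
  expect_lte(ratio, 1.0)
  het <- build_powerlaw_network(1e4, 1.2, z_min = 1, seed = 3)
  expect_lt(het$zbar^2 / het$z2bar, 0.2)   # hub-dominated at nu = 1.2
  expect_true(igraph::is_connected(het$graph))
  expect_equal(igraph::count_multiple(net$graph), rep(1, igraph::ecount(net$graph)))
  # analytic continuum moments reach the N^(2 - 2/nu) scaling asymptotically
  Ns <- 10^(10:14)
  ne <- vapply(Ns, function(N) effective_population_size(powerlaw_moments(N, 1.2)),
               numeric(1))
  slope <- stats::coef(stats::lm(log(ne) ~ log(Ns)))[2]
  expect_equal(unname(slope), 2 - 2 / 1.2, tolerance = 0.05)
})

test_that("absorbing states and update bounds are respected", {
  net <- build_regular_network(30, 4, seed = 4)
  wp <- wf_params(30, 1, 0.5)
  res <- simulate_to_absorption(wp, net, x0 = 1, seed = 5)
  expect_true(res$fixed)
  expect_equal(res$absorption_time, 0)
  res0 <- simulate_to_absorption(wp, net, x0 = 0, seed = 5)
  expect_false(res0$fixed)
  traj <- simulate_to_absorption(wp, net, x0 = 0.4, seed = 6, record = TRUE,
                                 record_every = 10)$trajectory
  expect_true(all(traj$freq >= 0 & traj$freq <= 1))
  expect_error(simulate_to_absorption(wf_params(30, 1, 0.5, eta = rep(0.1, 4)),
                                      net, x0 = 0.5), "absorbing")
})

test_that("neutral drift is a martingale and seeds fix at rate eps/N", {
  net <- build_regular_network(100, 10, seed = 1)
  wp <- wf_params(100, 1, 1)
  set.seed(2)
  b <- simulate_to_absorption(wp, net, x0 = 0.3, n_reps = 1500)
  expect_lt(abs(mean(b$fixed) - 0.3), 3 * sd(b$fixed) / sqrt(nrow(b)))
  # single seeded speaker at impact eps: fixation probability eps/N
  wp2 <- wf_params(100, 1, 0.5)
  set.seed(7)
  b2 <- simulate_to_absorption(wp2, net, x0 = "single", n_reps = 6000)
  expect_lt(abs(mean(b2$fixed) - 0.5 / 100),
            3 * sd(b2$fixed) / sqrt(nrow(b2)))
})

test_that("diffusion fixation probability matches the closed form", {
  expect_equal(fixation_probability(1000, 0, 0.01), 0.01)
  expect_equal(fixation_probability(500, 1e-12, 0.37), 0.37)  # neutral branch
  expect_equal(fixation_probability(1000, 0.01, 0.01),
               (1 - exp(-0.2)) / (1 - exp(-20)), tolerance = 1e-12)
  expect_equal(round(fixation_probability(1000, 0.01, 0.01), 5), 0.18127)
  # stable for strong selection and counter-selection
  expect_equal(fixation_probability(1e9, 1, 1e-9), 1 - exp(-2), tolerance = 1e-6)
  expect_gt(fixation_probability(1e4, -0.05, 0.5), 0)
  expect_lt(fixation_probability(1e4, -0.05, 0.5), 1e-100)
  expect_error(fixation_probability(-1, 0, 0.5), "positive")
})

test_that("conditional fixation-time quadrature matches closed forms", {
  # neutral Kimura-Ohta oracle: mean = -2 Ne (1-p) log(1-p) / p (times T_M)
  ko <- function(Ne, p) -2 * Ne * (1 - p) * log(1 - p) / p
  for (Ne in c(100, 1000)) {
    for (p in c(1e-4, 0.01, 0.2)) {
      m <- fixation_time_moments(Ne, 1, 0, p)
      expect_equal(m$mean, ko(Ne, p), tolerance = 0.02)
    }
  }
  # x0 -> 0 limit is 2 Ne T_M
  expect_equal(fixation_time_moments(100, 1, 0, 1e-6)$mean, 200, tolerance = 0.02)
  # time-unit rescaling: doubling T_M doubles the mean, quadruples the variance
  m1 <- fixation_time_moments(150, 1, 0.01, 1 / 150)
  m2 <- fixation_time_moments(150, 2, 0.01, 1 / 150)
  expect_equal(m2$mean / m1$mean, 2, tolerance = 1e-10)
  expect_equal(m2$variance / m1$variance, 4, tolerance = 1e-10)
  # selection-sign symmetry in the rare-innovation limit
  mp <- fixation_time_moments(200, 1, 0.02, 1e-4)
  mm <- fixation_time_moments(200, 1, -0.02, 1e-4)
  expect_equal(mp$mean, mm$mean)
  # strong selection shortens fixation to the log(Ne)/s scale
  ms <- fixation_time_moments(1e6, 1, 0.1, 1e-6)
  expect_lt(ms$mean, 1e4)       # far below the neutral 2e6
  expect_gt(ms$mean, log(1e6) / 0.1)
})

test_that("Gamma moment matching is exact", {
  gf <- gamma_fit_from_moments(100, 400)
  expect_equal(gf$alpha, 25)
  expect_equal(gf$beta, 0.25)
  expect_equal(gf$alpha / gf$beta, 100)              # mean recovered
  expect_equal(gf$alpha / gf$beta^2, 400)            # variance recovered
  expect_error(gamma_fit_from_moments(0, 1), "positive")
  expect_error(gamma_fit_from_moments(1, -1), "positive")
})
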