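# Individual-based Wright-Fisher model on social networks, and its
# diffusion approximation: fixation probabilities, conditional fixation-time
# moments, Gamma moment matching and effective population sizes.

#' @useDynLib cyclefix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters of the individual-based Wright-Fisher model
#'
#' Each of `N` speakers carries an innovation frequency `x_n` in `[0, 1]`.
#' Speakers update at rate `R` per year; in an update a speaker replaces a
#' fraction `epsilon` of its stored linguistic experience with the variant
#' perceived from one interlocutor, chosen among network neighbours with
#' probability proportional to `1 + s * x_m`. With probability `eta[i]` a
#' conventional behaviour at stage `i` is perceived as the innovation. The
#' derived memory time `T_M = 1/(R * epsilon)` is the expected lifetime of
#' one stored item of linguistic experience. Configurations with
#' `epsilon > 1` are retained but flagged unphysical.
#'
#' @param N number of speakers (>= 2).
#' @param R interaction (update) rate per speaker, 1/yr.
#' @param epsilon per-interaction update impact, in (0, 1] for a physical
#'   model.
#' @param s selection strength (>= -1); `s > 0` favours the innovation.
#' @param eta innovation-perception probabilities, length 4, each in [0, 1).
#' @return an object of class `wf_params` with derived `memory_time` and
#'   `physical` flag.
#' @export
wf_params <- function(N, R, epsilon, s = 0, eta = rep(0, 4)) {
  if (is.na(N) || N < 2 || N != round(N)) stop("N must be an integer >= 2", call. = FALSE)
  if (is.na(R) || R <= 0) stop("interaction rate R must be positive", call. = FALSE)
  if (is.na(epsilon) || epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (is.na(s) || s < -1) stop("selection strength s must be >= -1", call. = FALSE)
  if (length(eta) == 1L) eta <- rep(eta, 4)
  if (length(eta) != 4L || anyNA(eta) || any(eta < 0) || any(eta >= 1)) {
    stop("eta must be 4 probabilities in [0, 1)", call. = FALSE)
  }
  structure(list(N = as.integer(N), R = as.numeric(R),
                 epsilon = as.numeric(epsilon), s = as.numeric(s),
                 eta = as.numeric(eta),
                 memory_time = 1 / (R * epsilon),
                 physical = epsilon <= 1),
            class = "wf_params")
}

#' @export
print.wf_params <- function(x, ...) {
  cat(sprintf("<wf_params> N = %d, R = %g/yr, epsilon = %g, s = %g, T_M = %g yr%s\n",
              x$N, x$R, x$epsilon, x$s, x$memory_time,
              if (!x$physical) " [unphysical: epsilon > 1]" else ""))
  invisible(x)
}

# degree-preserving rewiring that removes self loops and parallel edges
.rewire_simple <- function(el, max_iter = 400L) {
  for (it in seq_len(max_iter)) {
    key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    bad <- which(el[, 1L] == el[, 2L] | duplicated(key))
    if (!length(bad)) return(el)
    partners <- sample.int(nrow(el), length(bad), replace = TRUE)
    for (j in seq_along(bad)) {
      i <- bad[j]; p <- partners[j]
      if (p == i) next
      tmp <- el[i, 2L]
      el[i, 2L] <- el[p, 2L]
      el[p, 2L] <- tmp
    }
  }
  stop("could not realise a simple graph with the sampled degree sequence ",
       "after ", max_iter, " rewiring sweeps", call. = FALSE)
}

#' Random social network with a power-law degree distribution
#'
#' Draws degrees i.i.d. from the discrete power law `p_z ~ z^-(1+nu)` on
#' `z_min .. z_max` with the natural cutoff `z_max = z_min * N^(1/nu)`,
#' realises a configuration-model graph and removes self loops and parallel
#' edges by degree-preserving rewiring. The largest connected component is
#' returned; all moments are computed from the realised degrees. Exponents
#' `nu > 2` give effectively homogeneous networks, `nu < 2` increasingly
#' heterogeneous ones dominated by hubs.
#'
#' @param N number of nodes (>= 10) before restriction to the largest
#'   component.
#' @param nu heterogeneity exponent (> 0).
#' @param z_min minimum degree (>= 1).
#' @param seed optional integer seed.
#' @return an object of class `social_network`: fields `graph` (igraph),
#'   `degrees`, `N`, `nu`, `z_min`, `zbar`, `z2bar`.
#' @export
build_powerlaw_network <- function(N, nu, z_min = 1L, seed = NULL) {
  if (N < 10) stop("N must be >= 10", call. = FALSE)
  if (nu <= 0) stop("nu must be positive", call. = FALSE)
  if (z_min < 1) stop("z_min must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z_max <- max(z_min + 1L, min(N - 1L, round(z_min * N^(1 / nu))))
  zz <- z_min:z_max
  degs <- sample(zz, N, replace = TRUE, prob = zz^-(1 + nu))
  if (sum(degs) %% 2L == 1L) degs[which.min(degs)] <- degs[which.min(degs)] + 1L
  g <- igraph::sample_degseq(degs, method = "configuration")
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- .rewire_simple(el)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  structure(list(graph = g, degrees = as.numeric(deg),
                 N = igraph::vcount(g), nu = nu, z_min = z_min,
                 zbar = mean(deg), z2bar = mean(deg^2)),
            class = "social_network")
}

#' A regular social network
#'
#' Convenience constructor for a random `z`-regular simple graph, the
#' homogeneous reference case in which the effective population size equals
#' `N / epsilon`.
#'
#' @param N number of nodes.
#' @param z common degree.
#' @param seed optional integer seed.
#' @return a `social_network` object.
#' @export
build_regular_network <- function(N, z, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_k_regular(N, z)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  structure(list(graph = g, degrees = as.numeric(deg), N = igraph::vcount(g),
                 nu = Inf, z_min = z, zbar = mean(deg), z2bar = mean(deg^2)),
            class = "social_network")
}

#' Wrap an explicit graph as a social network
#' @param graph an igraph object (undirected); the largest component is used.
#' @return a `social_network` object.
#' @export
as_social_network <- function(graph) {
  comp <- igraph::components(graph)
  g <- igraph::induced_subgraph(graph, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  structure(list(graph = g, degrees = as.numeric(deg), N = igraph::vcount(g),
                 nu = NA_real_, z_min = min(deg), zbar = mean(deg),
                 z2bar = mean(deg^2)),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> N = %d, mean degree %.2f, (zbar^2/z2bar) = %.3f\n",
              x$N, x$zbar, x$zbar^2 / x$z2bar))
  invisible(x)
}

#' Analytic degree moments of a truncated power-law network
#'
#' For theory scans over speech communities too large to realise as graphs,
#' the degree moments of the power law `p_z ~ z^-(1+nu)` with natural cutoff
#' `z_max = z_min * N^(1/nu)` are computed in the continuum approximation.
#' The resulting effective population size scales as `N^(2 - 2/nu)` for
#' `1 < nu < 2`.
#'
#' @inheritParams build_powerlaw_network
#' @return an object of class `social_network_spec` with fields `N`, `nu`,
#'   `z_min`, `zbar`, `z2bar`.
#' @export
powerlaw_moments <- function(N, nu, z_min = 1) {
  if (N < 2 || nu <= 0 || z_min < 1) stop("invalid network specification", call. = FALSE)
  z_max <- z_min * N^(1 / nu)
  mom <- function(k) {
    if (abs(k - nu) < 1e-12) return(log(z_max / z_min))
    (z_max^(k - nu) - z_min^(k - nu)) / (k - nu)
  }
  structure(list(N = N, nu = nu, z_min = z_min,
                 zbar = mom(1) / mom(0), z2bar = mom(2) / mom(0)),
            class = "social_network_spec")
}

#' Effective population size on a social network
#'
#' The drift-governing size `N_e = N * (zbar^2 / z2bar) / epsilon`, computed
#' from the realised degree moments of a `social_network` (or the analytic
#' moments of a [powerlaw_moments()] specification). Degree heterogeneity
#' shrinks `N_e` below `N`; smaller update impacts `epsilon` inflate it.
#'
#' The default is the small-`epsilon` asymptotic convention. With
#' `discrete = TRUE` the finite-update correction `(2 - epsilon)/2` is
#' applied: the copy-update rule leaves a quasi-stationary speaker variance
#' `epsilon x(1-x)/(2 - epsilon)` which inflates the sampling noise of the
#' population mean by `2/(2 - epsilon)`, so the diffusion that matches the
#' event-driven simulator has drift size `N_e (2 - epsilon)/2` (at
#' `epsilon = 1` this is the familiar factor 2 between copy dynamics and a
#' generation-based Wright-Fisher population). The two conventions coincide
#' as `epsilon -> 0`.
#'
#' @param network a `social_network` or `social_network_spec`.
#' @param epsilon update impact in (0, 1].
#' @param discrete apply the finite-update drift correction (see Details).
#' @return effective population size (positive real).
#' @export
effective_population_size <- function(network, epsilon = 1, discrete = FALSE) {
  if (!(inherits(network, "social_network") || inherits(network, "social_network_spec"))) {
    stop("network must be a social_network or social_network_spec", call. = FALSE)
  }
  if (is.null(network$N) || network$N < 1) stop("empty network", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  ne <- network$N * (network$zbar^2 / network$z2bar) / epsilon
  if (discrete) ne <- ne * (2 - min(epsilon, 1)) / 2
  ne
}

.adj_list0 <- function(network) {
  lapply(igraph::as_adj_list(network$graph), function(v) as.integer(v) - 1L)
}

#' Simulate Wright-Fisher dynamics to absorption
#'
#' Event-driven (asynchronous exponential-clock) simulation of the update
#' rule `x_n' = (1 - epsilon) x_n + epsilon * tau` at total rate `N * R`,
#' run until the innovation is lost or fixed. The initial condition is
#' either `"single"` -- one randomly chosen speaker at frequency `epsilon`,
#' the origination convention giving population frequency `epsilon / N` --
#' or a uniform frequency given as a number in `[0, 1]`. Innovation
#' perception (`eta > 0`) precludes absorption and is rejected here.
#'
#' @param params a [wf_params()] object with `eta = 0`.
#' @param network a `social_network`.
#' @param x0 `"single"` or a numeric initial frequency applied to all
#'   speakers.
#' @param seed optional integer seed.
#' @param n_reps number of independent replicates.
#' @param record if `TRUE` (single replicate only) the trajectory of the
#'   population mean frequency is recorded every `record_every` events.
#' @param record_every event interval between trajectory records.
#' @param max_events safety cap on update events per replicate.
#' @param tol absorption tolerance on the population mean frequency.
#' @return for `n_reps = 1` a list with `fixed`, `absorption_time` (years),
#'   `events` and optionally `trajectory` (data frame `time`, `freq`);
#'   otherwise a data frame with one row per replicate.
#' @export
simulate_to_absorption <- function(params, network, x0 = "single", seed = NULL,
                                   n_reps = 1L, record = FALSE,
                                   record_every = NULL, max_events = 2e9,
                                   tol = 1e-12) {
  stopifnot(inherits(params, "wf_params"), inherits(network, "social_network"))
  if (any(params$eta > 0)) {
    stop("absorption requested with eta > 0: innovation perception keeps ",
         "reintroducing the variant, so the dynamics are not absorbing",
         call. = FALSE)
  }
  if (params$epsilon > 1) stop("epsilon > 1 is unphysical and cannot be simulated",
                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- network$N
  if (params$N != N) {
    stop("params$N (", params$N, ") does not match the network size (", N, ")",
         call. = FALSE)
  }
  x0_mode <- "uniform"; x0_value <- NA_real_
  if (identical(x0, "single")) {
    x0_mode <- "single"; x0_value <- params$epsilon
  } else {
    x0_value <- as.numeric(x0)
    if (is.na(x0_value) || x0_value < 0 || x0_value > 1) {
      stop("x0 must be \"single\" or a frequency in [0, 1]", call. = FALSE)
    }
  }
  record_every <- record_every %||% max(1L, as.integer(N))
  res <- .wf_simulate_cpp(.adj_list0(network), params$epsilon, params$s, 0,
                          params$R, x0_mode, x0_value, as.integer(n_reps),
                          tol, max_events, record && n_reps == 1L,
                          as.integer(record_every))
  if (any(res$status < 0)) {
    warning("some replicates hit max_events before absorption")
  }
  if (n_reps == 1L) {
    out <- list(fixed = res$status[1L] == 1L,
                absorption_time = res$time[1L], events = res$events[1L])
    if (record) out$trajectory <- data.frame(time = res$traj_time,
                                             freq = res$traj_freq)
    return(out)
  }
  data.frame(fixed = res$status == 1L, time = res$time, events = res$events)
}

#' Diffusion fixation probability
#'
#' Probability that an innovation starting at population frequency `x0`
#' reaches fixation, from the backward equation of the Wright-Fisher
#' diffusion: `Q = (1 - exp(-2 Ne s x0)) / (1 - exp(-2 Ne s))`, with the
#' neutral limit `Q = x0` as `s -> 0`. Computed stably for selection of
#' either sign and arbitrarily large `|2 Ne s|`.
#'
#' @param N_e effective population size (> 0).
#' @param s selection strength.
#' @param x0 initial frequency in [0, 1].
#' @return fixation probability.
#' @examples
#' fixation_probability(1000, 0.01, 0.01)
#' @export
fixation_probability <- function(N_e, s, x0) {
  if (is.na(N_e) || N_e <= 0) stop("N_e must be positive", call. = FALSE)
  if (any(x0 < 0) || any(x0 > 1)) stop("x0 must be in [0, 1]", call. = FALSE)
  sig <- 2 * N_e * s
  if (!is.finite(sig)) return(if (s > 0) rep(1, length(x0))[seq_along(x0)] else 0 * x0)
  if (abs(sig) < 1e-8) return(x0)
  if (sig > 0) {
    return(expm1(-sig * x0) / expm1(-sig))
  }
  a <- -sig
  lognum <- ifelse(a * x0 > 700, a * x0, log(expm1(a * x0)))
  logden <- if (a > 700) a else log(expm1(a))
  out <- exp(lognum - logden)
  out[x0 == 0] <- 0
  out
}

#' Conditional fixation-time moments of the Wright-Fisher diffusion
#'
#' Mean and variance of the time for an innovation starting at frequency
#' `x0` to fix, conditional on fixation, for the diffusion with drift
#' `s x(1-x)` and variance `x(1-x)/N_e` per unit diffusion time (one unit =
#' `T_M` years). Both moments are computed by Green-function quadrature of
#' the backward equation on a logit-spaced frequency grid: with `u` the
#' fixation probability and `t(x, p)` the sojourn-time kernel,
#' `E[T 1_fix](p) = int t(x,p) u(x) dx` and
#' `E[T^2 1_fix](p) = 2 int t(x,p) E[T 1_fix](x) dx`. For `s < 0` the
#' moments are computed at `|s|`, exact in the rare-innovation limit
#' `x0 -> 0` by the classical fixation-time symmetry. The neutral mean
#' approaches `2 N_e T_M` years as `x0 -> 0`; under strong selection it
#' scales as `T_M log(N_e)` (up to factors of `1/s`).
#'
#' @param N_e effective population size (>= 2).
#' @param T_M memory time in years (> 0).
#' @param s selection strength.
#' @param x0 initial frequency in (0, 1).
#' @param grid_points number of logit-spaced frequency grid points.
#' @return list with `mean` (years) and `variance` (years^2).
#' @export
fixation_time_moments <- function(N_e, T_M, s = 0, x0, grid_points = 2001L) {
  if (is.na(N_e) || N_e < 2) stop("N_e must be >= 2", call. = FALSE)
  if (is.na(T_M) || T_M <= 0) stop("T_M must be positive", call. = FALSE)
  if (is.na(x0) || x0 <= 0 || x0 >= 1) stop("x0 must be inside (0, 1)", call. = FALSE)
  sig <- abs(2 * N_e * s)           # |s| by the conditional-time symmetry
  lo <- min(1e-12, x0 / 10)
  l <- seq(stats::qlogis(lo), stats::qlogis(1 - lo), length.out = grid_points)
  x <- stats::plogis(l)
  dx <- diff(x)
  binv <- N_e / (x * (1 - x))       # 1 / b(x)

  if (sig < 1e-6) {
    u <- x
    # w1(p) = (1-p) A(p) + p B(p);  A' = 2 binv x^2, B' = -2 binv x (1-x) u / ...
    g_a <- 2 * binv * x * u          # C(x) L(x) u(x) with C = 2 binv, L = x
    g_b <- 2 * binv * (1 - x) * u    # C(x) R(x) u(x), R = 1 - x
    A <- c(0, cumsum(dx * (g_a[-1] + g_a[-length(g_a)]) / 2))
    B <- rev(c(0, cumsum(rev(dx) * (rev(g_b)[-1] + rev(g_b)[-length(g_b)]) / 2)))
    w1 <- (1 - x) * A + x * B
    g_a2 <- 2 * binv * x * w1
    g_b2 <- 2 * binv * (1 - x) * w1
    A2 <- c(0, cumsum(dx * (g_a2[-1] + g_a2[-length(g_a2)]) / 2))
    B2 <- rev(c(0, cumsum(rev(dx) * (rev(g_b2)[-1] + rev(g_b2)[-length(g_b2)]) / 2)))
    w2 <- 2 * ((1 - x) * A2 + x * B2)
    uu <- x
  } else {
    em  <- -expm1(-sig * x)          # 1 - exp(-sig x)
    emr <- -expm1(-sig * (1 - x))    # 1 - exp(-sig (1 - x))
    em1 <- -expm1(-sig)
    u <- em / em1
    # A-part needs the exponentially smoothed integral
    #   Atil(p) = int_0^p g(x) exp(-sig (p - x)) dx,
    # computed by a stable recurrence; the B-part integrand is bounded.
    smoothed <- function(g) {
      At <- numeric(length(x))
      damp <- exp(-sig * dx)
      for (k in 2:length(x)) {
        At[k] <- damp[k - 1L] * At[k - 1L] +
          dx[k - 1L] / 2 * (g[k] + g[k - 1L] * damp[k - 1L])
      }
      At
    }
    revcum <- function(g) {
      rev(c(0, cumsum(rev(dx) * (rev(g)[-1] + rev(g)[-length(g)]) / 2)))
    }
    g1 <- 2 * em^2 * binv / em1^2
    g2 <- 2 * emr * em * binv / em1^2
    w1 <- emr / sig * smoothed(g1) + em / sig * revcum(g2)
    g3 <- 2 * em * w1 * binv / em1
    g4 <- 2 * emr * w1 * binv / em1
    w2 <- 2 * (emr / sig * smoothed(g3) + em / sig * revcum(g4))
    uu <- u
  }
  w1_0 <- stats::approx(x, w1, xout = x0, rule = 2)$y
  w2_0 <- stats::approx(x, w2, xout = x0, rule = 2)$y
  u_0 <- if (sig < 1e-6) x0 else fixation_probability(1, sig / 2, x0)
  mean_t <- w1_0 / u_0 * T_M
  m2 <- w2_0 / u_0 * T_M^2
  var_t <- m2 - mean_t^2
  if (!is.finite(mean_t) || !is.finite(var_t) || mean_t <= 0 || var_t <= 0) {
    stop(sprintf(paste0("fixation-time quadrature failed (N_e = %g, T_M = %g, ",
                        "s = %g, x0 = %g): mean = %g, var = %g"),
                 N_e, T_M, s, x0, mean_t, var_t), call. = FALSE)
  }
  list(mean = mean_t, variance = var_t)
}

#' Match a Gamma law to fixation-time moments
#'
#' Shape and rate of the Gamma distribution with the given mean and
#' variance: `alpha = mean^2 / variance`, `beta = mean / variance`. This is
#' the approximation used for fixation times in the origin-fixation model.
#'
#' @param mean positive mean (years).
#' @param variance positive variance (years^2).
#' @return list with `alpha` and `beta`.
#' @export
gamma_fit_from_moments <- function(mean, variance) {
  if (is.na(mean) || mean <= 0 || is.na(variance) || variance <= 0) {
    stop("mean and variance must be positive", call. = FALSE)
  }
  list(alpha = mean^2 / variance, beta = mean / variance)
}
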