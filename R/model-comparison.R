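# Bridging individual-scale parameters to the origin-fixation scale,
# defining theory families (Poisson baseline, child-based, usage-based,
# networked variants) and comparing them on a corpus via AICc,
# overdispersion and Monte Carlo p-values.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k - 2 ln L + 2 k (k + 1) / (n - k - 1)`, where `k` is the number
#' of fitted parameters, `n` the number of observations (languages) and
#' `ln L` the maximised log-likelihood. Differences between models,
#' `delta AICc = AICc(candidate) - AICc(baseline)`, measure relative
#' plausibility; see [evidence_ratio()].
#'
#' @param k number of free parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @param log_likelihood maximised log-likelihood.
#' @return the AICc value.
#' @examples
#' aicc(1, 52, -63)
#' @export
aicc <- function(k, n, log_likelihood) {
  if (is.na(n) || is.na(k) || n <= k + 1) {
    stop("AICc requires n > k + 1", call. = FALSE)
  }
  2 * k - 2 * log_likelihood + 2 * k * (k + 1) / (n - k - 1)
}

#' Evidence ratio from an AICc difference
#'
#' `exp(delta/2)` estimates how many times less probable the model with the
#' higher AICc is than the better one; a difference of about 10 corresponds
#' to a ratio of about 150.
#'
#' @param delta_aicc AICc difference (candidate minus baseline).
#' @return the evidence ratio.
#' @export
evidence_ratio <- function(delta_aicc) exp(delta_aicc / 2)

#' Specify a theory family of individual-level language change
#'
#' A theory fixes the structural parameters of the Wright-Fisher model and
#' leaves a single rate to be profiled against the data:
#' \describe{
#'   \item{`poisson_baseline`}{language changes occur autonomously at the
#'     population level as a Poisson process with stage rates
#'     `omega_bar / (4 f_i)` and instantaneous fixation; the profiled
#'     parameter is `omega_bar`.}
#'   \item{`child_based`}{grammar updates once per human generation
#'     (`R = 0.04`/yr, i.e. every 25 years) with categorical learning
#'     (`epsilon = 1`); the profiled parameter is the mean learning-error
#'     rate `eta_bar`.}
#'   \item{`usage_based`}{updates at any rate `R` with impact
#'     `epsilon = 1 / (R * memory_time)`; configurations needing
#'     `epsilon > 1` are flagged unphysical.}
#' }
#' Selection strength `s` (possibly `Inf`) and the network exponent `nu`
#' (`"homogeneous"` for regular mixing, or a power-law exponent) are scanned
#' conditions, not fitted parameters.
#'
#' @param family `"poisson_baseline"`, `"child_based"` or `"usage_based"`.
#' @param s selection strength; `Inf` gives the infinite-selection
#'   asymptote (every innovation fixes, instantaneously on the population
#'   timescale).
#' @param nu `"homogeneous"` or a positive power-law degree exponent.
#' @param R interaction rate (1/yr); fixed at 0.04 for `child_based`.
#' @param memory_time memory time `T_M = 1/(R epsilon)` in years; for
#'   `usage_based` this fixes `epsilon` given `R`. Defaults to `1/(R
#'   epsilon)` with `epsilon = 1`.
#' @param z_min minimum degree for power-law networks.
#' @param eta_profile `"stationary"` allocates the innovation rate over
#'   stages so the emergent origination rates mirror the baseline's
#'   stationarity structure (`eta_i` proportional to `1/f_i`); `"uniform"`
#'   uses a single constant `eta`.
#' @return an object of class `theory_spec`.
#' @export
theory_spec <- function(family = c("poisson_baseline", "child_based", "usage_based"),
                        s = 0, nu = "homogeneous", R = NULL, memory_time = NULL,
                        z_min = 1, eta_profile = c("stationary", "uniform")) {
  family <- match.arg(family)
  eta_profile <- match.arg(eta_profile)
  if (is.na(s) || (!is.infinite(s) && s < -1)) stop("invalid selection strength", call. = FALSE)
  epsilon <- NA_real_
  if (family == "child_based") {
    R <- 0.04                        # one update per 25-year generation
    epsilon <- 1
    memory_time <- 1 / (R * epsilon)
  } else if (family == "usage_based") {
    if (is.null(R) || R <= 0) stop("usage_based theory needs an interaction rate R", call. = FALSE)
    memory_time <- memory_time %||% (1 / R)
    if (memory_time <= 0) stop("memory_time must be positive", call. = FALSE)
    epsilon <- 1 / (R * memory_time)
  }
  physical <- family == "poisson_baseline" || epsilon <= 1
  if (!identical(nu, "homogeneous")) {
    nu <- as.numeric(nu)
    if (is.na(nu) || nu <= 0) stop("nu must be \"homogeneous\" or positive", call. = FALSE)
  }
  structure(list(family = family, s = s, nu = nu, R = R,
                 epsilon = epsilon, memory_time = memory_time,
                 z_min = z_min, eta_profile = eta_profile,
                 physical = physical),
            class = "theory_spec")
}

#' @export
print.theory_spec <- function(x, ...) {
  cat(sprintf("<theory_spec> %s: s = %g, nu = %s%s%s\n", x$family, x$s,
              paste(x$nu),
              if (!is.null(x$R)) sprintf(", R = %g/yr, eps = %.3g, T_M = %.3g yr",
                                         x$R, x$epsilon, x$memory_time) else "",
              if (!x$physical) " [unphysical: epsilon > 1]" else ""))
  invisible(x)
}

# Stage allocation of the innovation rate: with the "stationary" profile
# eta_i = eta_bar * (1/4) * f_harm / f_i (f_harm the harmonic mean of f),
# so the emergent origination rates are proportional to 1/f_i exactly as in
# the baseline's stationarity choice; eta_bar sets the overall scale.
.eta_vector <- function(eta_bar, f, profile) {
  if (profile == "uniform") return(rep(eta_bar, 4))
  f_harm <- 4 / sum(1 / f)
  eta_bar * 0.25 * f_harm / f
}

#' Emergent origin-fixation parameters of a Wright-Fisher model
#'
#' Maps individual-scale parameters to the population scale: origination
#' rates `omega_i = N R eta_i Q(epsilon / N)` with `Q` the diffusion
#' fixation probability at the network's effective population size, and
#' fixation-time mean and variance from [fixation_time_moments()] at the
#' origination frequency `x0 = epsilon / N`. With `s = Inf` every innovation
#' fixes (`Q = 1`) instantaneously on the population timescale.
#'
#' @param wf a [wf_params()] object.
#' @param network a `social_network`, a [powerlaw_moments()] specification,
#'   or `NULL` for a homogeneous (well-mixed) population with `N_e = N /
#'   epsilon`.
#' @param eta optional override for the 4 innovation-perception rates
#'   (defaults to `wf$eta`).
#' @return an [of_params()] object.
#' @export
of_params_from_wf <- function(wf, network = NULL, eta = NULL) {
  stopifnot(inherits(wf, "wf_params"))
  eta <- eta %||% wf$eta
  if (length(eta) == 1L) eta <- rep(eta, 4)
  N <- wf$N
  if (is.infinite(wf$s)) {
    return(of_params(N * wf$R * eta, 0, 0))
  }
  N_e <- if (is.null(network)) {
    N / wf$epsilon * (2 - min(wf$epsilon, 1)) / 2
  } else {
    effective_population_size(network, wf$epsilon, discrete = TRUE)
  }
  x0 <- wf$epsilon / N
  Q <- fixation_probability(N_e, wf$s, x0)
  omega <- N * wf$R * eta * Q
  if (all(eta == 0)) return(of_params(omega, 0, 0))
  mom <- fixation_time_moments(N_e, wf$memory_time, wf$s, x0)
  of_params(omega, mom$mean, mom$variance)
}

# Per-language emergent parameters that do not depend on the profiled rate:
# effective size, fixation probability and fixation-time moments.
.language_constants <- function(theory, pop_sizes) {
  lapply(pop_sizes, function(N) {
    if (is.na(N)) stop("corpus histories need population sizes for an ",
                       "individual-based theory", call. = FALSE)
    N <- max(2, round(N))
    net <- if (identical(theory$nu, "homogeneous")) NULL
           else powerlaw_moments(N, theory$nu, theory$z_min)
    if (is.infinite(theory$s)) {
      return(list(N = N, Q = 1, mean_fix = 0, var_fix = 0))
    }
    N_e <- if (is.null(net)) {
      N / theory$epsilon * (2 - min(theory$epsilon, 1)) / 2
    } else {
      effective_population_size(net, theory$epsilon, discrete = TRUE)
    }
    x0 <- min(theory$epsilon / N, 1)
    Q <- fixation_probability(N_e, theory$s, x0)
    mom <- fixation_time_moments(N_e, theory$memory_time, theory$s, x0)
    list(N = N, Q = Q, mean_fix = mom$mean, var_fix = mom$variance)
  })
}

.per_language_params <- function(theory, consts, eta_bar, f) {
  eta <- .eta_vector(eta_bar, f, theory$eta_profile)
  lapply(consts, function(cc) {
    of_params(cc$N * theory$R * eta * cc$Q, cc$mean_fix, cc$var_fix)
  })
}

#' Fit a theory to a corpus by profiling its free rate
#'
#' Maximises the corpus log-likelihood over the theory's single free
#' parameter -- the mean origination rate `omega_bar` for the Poisson
#' baseline, the mean innovation rate `eta_bar` for the individual-based
#' families -- by bounded golden-section search on a log scale. For
#' individual-based theories the per-language emergent parameters are built
#' from each language's recorded population size.
#'
#' @param corpus a [corpus()] of language histories.
#' @param theory a [theory_spec()].
#' @param f stationary stage frequencies (length 4), as from
#'   [stationary_frequencies()].
#' @param variant likelihood variant passed to [path_probability()].
#' @param bounds search interval for the profiled rate.
#' @param tol convergence tolerance of the profile search, on log10 scale.
#' @return an object of class `comparison_result` with the maximised
#'   log-likelihood `log_likelihood`, parameter count `k`, number of
#'   languages `n`, `aicc`, the `fitted_rate`, and the per-language
#'   [of_params()] in `params` (for goodness-of-fit follow-ups).
#' @export
fit_theory <- function(corpus, theory, f,
                       variant = c("counts", "endpoint"),
                       bounds = NULL, tol = 1e-4) {
  stopifnot(inherits(corpus, "cycle_corpus"), inherits(theory, "theory_spec"))
  variant <- match.arg(variant)
  n <- length(corpus$histories)
  if (theory$family == "poisson_baseline") {
    bounds <- bounds %||% c(1e-8, 3e-2)
    objective <- function(lw) {
      params <- of_params(omega_from_mean_rate(10^lw, f))
      corpus_log_likelihood(corpus, params, variant)
    }
    opt <- stats::optimize(objective, log10(bounds), maximum = TRUE, tol = tol)
    rate <- 10^opt$maximum
    ll <- opt$objective
    params <- rep(list(of_params(omega_from_mean_rate(rate, f))), n)
  } else {
    pop <- vapply(corpus$histories, function(h) h$population_size, numeric(1))
    consts <- .language_constants(theory, pop)
    prof_max <- max(.eta_vector(1, f, theory$eta_profile))
    bounds <- bounds %||% c(1e-14, 0.99 / prof_max)
    objective <- function(le) {
      plist <- .per_language_params(theory, consts, 10^le, f)
      corpus_log_likelihood(corpus, plist, variant)
    }
    opt <- stats::optimize(objective, log10(bounds), maximum = TRUE, tol = tol)
    rate <- 10^opt$maximum
    ll <- opt$objective
    params <- .per_language_params(theory, consts, rate, f)
  }
  if (!is.finite(ll)) {
    warning("profile likelihood did not reach a finite maximum (rate = ",
            signif(rate, 4), ")")
  }
  structure(list(family = theory$family, theory = theory,
                 log_likelihood = ll, k = 1L, n = n,
                 aicc = aicc(1L, n, ll), fitted_rate = rate,
                 params = params, f = f, variant = variant),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: logL = %.3f (n = %d, k = %d), AICc = %.2f\n",
              x$family, x$log_likelihood, x$n, x$k, x$aicc))
  cat(sprintf("  fitted rate = %.4g%s\n", x$fitted_rate,
              if (x$family == "poisson_baseline") " /yr (omega_bar)" else " (eta_bar)"))
  if (!is.null(x$delta_aicc)) {
    cat(sprintf("  delta AICc vs baseline = %.2f (evidence ratio %.3g)\n",
                x$delta_aicc, evidence_ratio(x$delta_aicc)))
  }
  invisible(x)
}

#' AICc difference and evidence ratio between fits
#'
#' Annotates a candidate fit with `delta_aicc = AICc(candidate) -
#' AICc(baseline)` and the corresponding evidence ratio. Positive values
#' favour the baseline.
#'
#' @param candidate,baseline `comparison_result` objects for the same
#'   corpus.
#' @return the candidate with `delta_aicc` and `evidence_ratio` fields set.
#' @export
against_baseline <- function(candidate, baseline) {
  stopifnot(inherits(candidate, "comparison_result"),
            inherits(baseline, "comparison_result"))
  if (candidate$n != baseline$n) {
    stop("candidate and baseline were fitted to different corpora", call. = FALSE)
  }
  candidate$delta_aicc <- candidate$aicc - baseline$aicc
  candidate$evidence_ratio <- evidence_ratio(candidate$delta_aicc)
  candidate
}

#' Overdispersion goodness-of-fit statistic
#'
#' For each language, the summary `X` (the number of changes in the window,
#' or the indicator that at least one change occurred) has model mean and
#' variance estimated from `n_sims` simulated histories; the overdispersion
#' is the observed squared deviation over its expected value,
#' `O_X = (X - Xbar)^2 / Var(X)`, averaged over languages. Values near 1
#' indicate deviations of the expected size; values far above 1 indicate a
#' poor fit. Languages whose summary is (numerically) deterministic under
#' the model are excluded with a warning.
#'
#' @param corpus a [corpus()].
#' @param params an [of_params()] or per-language list, e.g. the `params`
#'   field of a [fit_theory()] result.
#' @param statistic `"counts"` or `"binary"`.
#' @param n_sims simulated histories per language.
#' @param seed optional integer seed.
#' @return list with `mean` (the averaged overdispersion), `per_language`,
#'   and `n_used`.
#' @export
overdispersion <- function(corpus, params, statistic = c("counts", "binary"),
                           n_sims = 2000L, seed = NULL) {
  stopifnot(inherits(corpus, "cycle_corpus"))
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  n <- length(corpus$histories)
  plist <- if (inherits(params, "of_params")) rep(list(params), n) else params
  per <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    h <- corpus$histories[[i]]
    t <- h$window_end - h$window_start
    dist <- count_distribution(h$initial_stage, t, plist[[i]])
    m_sim <- sample.int(length(dist), n_sims, replace = TRUE, prob = dist) - 1L
    x_sim <- if (statistic == "binary") as.numeric(m_sim >= 1L) else m_sim
    x_obs <- if (statistic == "binary") as.numeric(n_changes(h) >= 1L) else n_changes(h)
    v <- stats::var(x_sim)
    if (is.na(v) || v < 1e-12) next
    per[i] <- (x_obs - mean(x_sim))^2 / v
  }
  if (anyNA(per)) {
    warning(sum(is.na(per)), " language(s) excluded from overdispersion: ",
            "summary statistic is deterministic under the model")
  }
  list(mean = mean(per, na.rm = TRUE), per_language = per,
       n_used = sum(!is.na(per)))
}
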