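# Population-scale origin-fixation model: Poisson origination with
# stage-specific rates, Gamma-distributed fixation episodes, transition
# kernels, corpus likelihoods, sampling and Monte Carlo p-values.

#' Parameters of the origin-fixation model
#'
#' At stage `i` of the cycle, successful originations of the next stage occur
#' as a Poisson process with rate `omega[i + 1]` (per year). Each origination
#' is followed by a fixation episode whose duration is Gamma distributed with
#' mean `mean_fix` and variance `var_fix`; the population is recorded at the
#' old stage until fixation completes. `mean_fix = 0` gives the
#' instantaneous-fixation (pure Markov) model. The Gamma shape and rate are
#' `alpha = mean_fix^2 / var_fix` and `beta = mean_fix / var_fix`.
#'
#' @param omega numeric vector of 4 non-negative origination rates (1/yr).
#' @param mean_fix mean fixation time (years, >= 0).
#' @param var_fix variance of the fixation time (years^2; must be positive
#'   when `mean_fix > 0`).
#' @return an object of class `of_params`.
#' @seealso [omega_from_mean_rate()], [sample_history()], [path_probability()]
#' @export
of_params <- function(omega, mean_fix = 0, var_fix = 0) {
  if (length(omega) != 4L || anyNA(omega) || any(omega < 0)) {
    stop("omega must be 4 non-negative rates", call. = FALSE)
  }
  if (is.na(mean_fix) || mean_fix < 0) stop("mean_fix must be >= 0", call. = FALSE)
  instantaneous <- mean_fix == 0
  if (!instantaneous && (is.na(var_fix) || var_fix <= 0)) {
    stop("var_fix must be positive when mean_fix > 0", call. = FALSE)
  }
  alpha <- if (instantaneous) NA_real_ else mean_fix^2 / var_fix
  beta <- if (instantaneous) NA_real_ else mean_fix / var_fix
  structure(list(omega = as.numeric(omega), mean_fix = as.numeric(mean_fix),
                 var_fix = as.numeric(var_fix), alpha = alpha, beta = beta,
                 instantaneous = instantaneous),
            class = "of_params")
}

#' @export
print.of_params <- function(x, ...) {
  cat("<of_params> omega (1/yr):", paste(signif(x$omega, 4), collapse = ", "),
      "\n  fixation time: mean", signif(x$mean_fix, 4), "yr, var",
      signif(x$var_fix, 4), "yr^2",
      if (x$instantaneous) "(instantaneous)" else "", "\n")
  invisible(x)
}

#' Stage-specific origination rates from a mean rate
#'
#' Distributes a cycle-averaged origination rate over stages as
#' `omega_i = mean_rate / (4 f_i)`, where `f` are the stationary stage
#' frequencies. With instantaneous fixation this harmonic allocation makes
#' the stationary occupancy of the cycle equal to `f`, matching the observed
#' typological distribution.
#'
#' @param mean_rate cycle-averaged origination rate (1/yr, >= 0).
#' @param f stationary frequency vector (length 4, all positive).
#' @return numeric vector of 4 rates.
#' @examples
#' omega_from_mean_rate(6.05e-4, stationary_frequencies(article_typology()))
#' @export
omega_from_mean_rate <- function(mean_rate, f) {
  if (is.na(mean_rate) || mean_rate < 0) stop("mean_rate must be >= 0", call. = FALSE)
  if (length(f) != 4L || anyNA(f) || any(f <= 0)) {
    stop("all stationary frequencies must be positive", call. = FALSE)
  }
  mean_rate / (4 * f)
}

#' Sample a language history from the origin-fixation model
#'
#' Alternates exponential origination waits and Gamma fixation episodes,
#' recording a stage change at each moment a fixation completes. Origination
#' of the following stage only begins once the current fixation has
#' completed. The origination clock is memoryless, so starting it fresh at
#' the window start is exact for a language at stage `start` with no change
#' in progress.
#'
#' @param params an [of_params()] object.
#' @param start stage (0--3) occupied at the start of the window.
#' @param window length of the observation window in years (> 0), or a
#'   vector `c(start_year, end_year)`.
#' @param seed optional integer seed.
#' @param language name for the resulting history.
#' @param population_size optional population size to attach.
#' @return a [language_history()].
#' @export
sample_history <- function(params, start, window, seed = NULL,
                           language = "simulated", population_size = NA_real_) {
  stopifnot(inherits(params, "of_params"))
  start <- validate_stage(start)
  if (!is.null(seed)) set.seed(seed)
  if (length(window) == 1L) window <- c(0, window)
  if (diff(window) <= 0) stop("window must have positive length", call. = FALSE)
  t0 <- window[1L]; t1 <- window[2L]
  cur <- start; now <- t0
  times <- numeric(0); stages <- integer(0)
  repeat {
    w <- params$omega[cur + 1L]
    if (w == 0) break
    wait <- stats::rexp(1L, w)
    fix <- if (params$instantaneous) 0 else stats::rgamma(1L, params$alpha, params$beta)
    now <- now + wait + fix
    if (now >= t1) break
    cur <- (cur + 1L) %% N_STAGES
    times <- c(times, now); stages <- c(stages, cur)
  }
  tr <- if (length(times)) data.frame(time = times, new_stage = stages) else NULL
  language_history(language, t0, t1, start, tr, population_size)
}

#' Exact Markov transition kernel on the cycle
#'
#' For the instantaneous-fixation model the stage process is a
#' continuous-time Markov chain on the 4-cycle with generator
#' `Q[i, i] = -omega_i`, `Q[i, i+1] = omega_i`. The kernel for an elapsed
#' time `t` is the matrix exponential `expm(Q t)`.
#'
#' @param omega 4 non-negative origination rates (1/yr).
#' @param t elapsed time in years (>= 0).
#' @return 4x4 matrix of transition probabilities; rows sum to 1.
#' @export
transition_matrix_markov <- function(omega, t) {
  if (length(omega) != 4L || anyNA(omega) || any(omega < 0)) {
    stop("omega must be 4 non-negative rates", call. = FALSE)
  }
  if (is.na(t) || t < 0) stop("elapsed time t must be >= 0", call. = FALSE)
  if (t == 0) return(diag(4))
  Q <- diag(-omega)
  for (i in 1:4) Q[i, (i %% 4) + 1L] <- omega[i]
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0 & P > -1e-12] <- 0
  P / rowSums(P)
}

# ---- exact-m probabilities -------------------------------------------------

# Rates seen along a path of m transitions starting at stage i0 (0-based),
# including the rate governing the (m+1)-th origination.
.path_rates <- function(i0, m, omega) omega[((i0 + 0:m) %% 4L) + 1L]

# Deep-tail fallback: when the exact routines underflow, the log probability
# is assembled from the two series bottlenecks in log space.  The
# origination bottleneck treats each stage sojourn as exponential with its
# true mean (Poisson-style count probability; exact for uniform rates with
# instantaneous fixation).  The fixation bottleneck uses the fact that m
# completed episodes require a Gamma(m * alpha, beta) sum to fit inside the
# window, whose deep left tail pgamma evaluates stably.  A window with m
# changes needs BOTH bottlenecks passed (log probabilities add no higher
# than their min); an unchanged window needs only ONE slow sojourn (max).
.log_prob_m_fallback <- function(rates, params, t, m) {
  mean_fix <- if (inherits(params, "of_params")) params$mean_fix else 0
  mean_soj <- 1 / rates + mean_fix
  lam_bar <- (m + 1) / sum(mean_soj)
  lp_orig <- stats::dpois(m, lam_bar * t, log = TRUE)
  if (mean_fix == 0) return(lp_orig)
  a <- params$alpha; b <- params$beta
  if (m == 0L) {
    lp_fix <- stats::pgamma(t, a, b, lower.tail = FALSE, log.p = TRUE)
    return(max(lp_orig, max(-rates[1L] * t, lp_fix)))
  }
  l1 <- stats::pgamma(t, m * a, b, log.p = TRUE)
  l2 <- stats::pgamma(t, (m + 1) * a, b, log.p = TRUE)
  lp_fix <- if (l2 - l1 < -1e-12) l1 + log1p(-exp(l2 - l1)) else l1
  min(lp_orig, lp_fix)
}

# Probabilities of exactly 0..M completed transitions in a window of length t
# starting at stage i0, instantaneous fixation: read off a triangular matrix
# exponential over the jump-counting chain.
.count_probs_markov <- function(i0, t, omega, M) {
  rates <- .path_rates(i0, M, omega)
  G <- matrix(0, M + 2L, M + 2L)
  for (k in seq_len(M + 1L)) {
    G[k, k] <- -rates[k]
    G[k, k + 1L] <- rates[k]
  }
  P <- as.matrix(Matrix::expm(G * t))[1L, seq_len(M + 1L)]
  pmax(P, 0)
}

# Same for Gamma fixation times: cell-mass convolution of the stage sojourns
# (Exp origination wait + Gamma fixation) on a uniform grid over [0, t].
# Each sojourn is discretised to atoms at cell midpoints with exact CDF cell
# masses; the survival of the final sojourn is interpolated from its exact
# CDF at cell boundaries.
.count_probs_gamma <- function(i0, t, params, M, n_max = 16384L) {
  omega <- params$omega
  rates <- .path_rates(i0, M, omega)
  # Markov-limit switch: once the fixation episode is far below both the
  # origination wait and the window, its residual effect on the counts is
  # below the convolution grid's own error, and the limit kernel is the
  # more accurate evaluation.
  if (params$mean_fix * max(rates) < 1e-3 && params$mean_fix < t / 1000) {
    return(.count_probs_markov(i0, t, omega, M))
  }
  # resolve the fixation-time scale; origination waits enter through exact
  # CDF cell masses and need no resolution of 1/omega
  h_target <- min(params$mean_fix, t) / 50
  n <- 2L^max(8L, min(ceiling(log2(t / max(h_target, t / n_max))), log2(n_max)))
  h <- t / n
  edges <- seq(0, t, by = h)
  gamma_cdf <- stats::pgamma(edges, params$alpha, params$beta)

  soj_mass <- function(r) {
    # cell masses of Exp(r) + Gamma on (0, t]; mass beyond t is implicit
    if (r == 0) return(rep(0, n))
    ecdf_ <- stats::pexp(edges, r)
    me <- diff(ecdf_); mg <- diff(gamma_cdf)
    full <- stats::convolve(me, rev(mg), type = "open")[seq_len(n)]
    # atoms at midpoints i, j convolve to offset (i + j - 1); re-centre
    pmax(full, 0)
  }
  soj_cdf_at <- function(r, v) {
    # accurate CDF of Exp(r) + Gamma at a single point, Simpson quadrature
    if (r == 0 || v <= 0) return(0)
    ny <- 400L
    y <- seq(0, v, length.out = 2L * ny + 1L)
    fy <- r * exp(-r * y) * stats::pgamma(v - y, params$alpha, params$beta)
    wsimp <- c(1, rep(c(4, 2), ny - 1L), 4, 1) * (y[2L] - y[1L]) / 3
    min(sum(fy * wsimp), 1)
  }

  probs <- numeric(M + 1L)
  used <- unique(rates)
  masses <- lapply(used, soj_mass); names(masses) <- as.character(used)

  # f holds the atom masses of S_k (the sum of the first k sojourns); after
  # the k-th convolution the atom with index K sits at (K + offset - k/2) h.
  f <- 1; offset <- 0   # S_0 is the point mass at zero
  for (k in 0:M) {
    r <- rates[k + 1L]
    if (r == 0) { probs[k + 1L] <- sum(f); break }
    if (k == 0L) {
      probs[1L] <- 1 - soj_cdf_at(r, t)
    } else {
      Fk <- c(0, cumsum(masses[[as.character(r)]]))
      pos <- (seq_along(f) + offset - k / 2) * h
      keep <- pos < t & f > 0
      lag <- t - pos[keep]
      surv <- 1 - stats::approx(edges, Fk, xout = pmin(lag, t), rule = 2)$y
      probs[k + 1L] <- sum(f[keep] * surv)
    }
    if (k < M) {
      mk <- masses[[as.character(r)]]
      if (k == 0L) { f <- mk; offset <- 0 }
      else {
        f <- stats::convolve(f, rev(mk), type = "open")
        f <- f[seq_len(min(length(f), ceiling(t / h) + k + 2L))]
        offset <- offset + 1
      }
    }
  }
  pmax(pmin(probs, 1), 0)
}

#' Distribution of the number of completed changes in a window
#'
#' Probabilities `P(m)` that exactly `m` stage changes complete during an
#' observation window of length `t` for a language starting at stage `i0`,
#' under an origin-fixation parameterisation. The sequence is extended until
#' its tail mass falls below `p_tol` (or `m_max` is reached).
#'
#' @param i0 initial stage (0--3).
#' @param t window length in years.
#' @param params an [of_params()] object.
#' @param p_tol tail mass at which the enumeration stops.
#' @param m_max hard cap on the number of changes enumerated.
#' @return numeric vector `P(0), P(1), ...`.
#' @export
count_distribution <- function(i0, t, params, p_tol = 1e-10, m_max = 200L) {
  stopifnot(inherits(params, "of_params"))
  i0 <- validate_stage(i0)
  if (t <= 0) stop("window length must be positive", call. = FALSE)
  M <- 8L
  repeat {
    probs <- if (params$instantaneous) .count_probs_markov(i0, t, params$omega, M)
             else .count_probs_gamma(i0, t, params, M)
    if (sum(probs) >= 1 - p_tol || M >= m_max ||
        (length(probs) < M + 1L)) break   # truncated by a zero rate
    M <- min(2L * M, m_max)
  }
  probs
}

# Monte Carlo estimate of P(exactly m changes in t), used for deep windows
# where the convolution grid would be unwieldy.
.mc_prob_exact_m <- function(i0, t, params, m, n_mc = 2e5L) {
  tot <- numeric(n_mc); active <- rep(TRUE, n_mc); cnt <- integer(n_mc)
  k <- 0L
  while (any(active) && k <= m + 40L) {
    r <- params$omega[((i0 + k) %% 4L) + 1L]
    if (r == 0) break
    na <- sum(active)
    w <- stats::rexp(na, r)
    if (!params$instantaneous) w <- w + stats::rgamma(na, params$alpha, params$beta)
    tot[active] <- tot[active] + w
    done <- active
    done[active] <- tot[active] > t
    cnt[done] <- k
    active <- active & !done
    k <- k + 1L
  }
  cnt[active] <- k  # exhausted the cap while still inside the window
  max(mean(cnt == m), 0.5 / n_mc)
}

#' Log-probability of one observed history
#'
#' The default `"counts"` variant gives the log-probability that exactly the
#' observed number of fixations completes within the observation window,
#' ending at the observed final stage (the cycle order forces the stage
#' sequence, so transition dates carry no extra information for the
#' likelihood). The `"endpoint"` variant sums over all change counts
#' compatible with the observed start and end stages. With instantaneous
#' fixation the computation is exact (triangular matrix exponential);
#' otherwise the stage sojourns are convolved numerically, with a Monte
#' Carlo estimator taking over for windows containing more than `mc_over`
#' changes.
#'
#' @param history a [language_history()].
#' @param params an [of_params()] object.
#' @param variant `"counts"` (default) or `"endpoint"`.
#' @param mc_over change count above which the Monte Carlo estimator is used
#'   for the Gamma-fixation model.
#' @param n_mc Monte Carlo replicates for the fallback estimator.
#' @return log-probability (may be `-Inf` for structurally impossible data).
#' @export
path_probability <- function(history, params,
                             variant = c("counts", "endpoint"),
                             mc_over = 6L, n_mc = 2e5L) {
  stopifnot(inherits(history, "language_history"), inherits(params, "of_params"))
  variant <- match.arg(variant)
  t <- history$window_end - history$window_start
  i0 <- history$initial_stage
  m <- n_changes(history)
  if (variant == "endpoint") {
    probs <- count_distribution(i0, t, params)
    idx <- seq(m %% 4L, length(probs) - 1L, by = 4L) + 1L
    tail_mass <- max(0, 1 - sum(probs))
    p <- sum(probs[idx]) + tail_mass / 4  # spread unresolved tail evenly
    return(if (p > 0) log(p) else -Inf)
  }
  rates <- .path_rates(i0, m, params$omega)
  if (any(rates[seq_len(m)] == 0)) return(-Inf)  # required origination impossible
  if (params$instantaneous) {
    if (max(rates) * t > 600) return(.log_prob_m_fallback(rates, 0, t, m))
    p <- .count_probs_markov(i0, t, params$omega, m)[m + 1L]
  } else if (m > mc_over) {
    p <- .mc_prob_exact_m(i0, t, params, m, n_mc)
  } else {
    if (max(rates) * t > 600) {
      return(.log_prob_m_fallback(rates, params$mean_fix, t, m))
    }
    p <- .count_probs_gamma(i0, t, params, m)[m + 1L]
  }
  if (!is.finite(p) || p < 1e-290) {
    return(.log_prob_m_fallback(rates, params$mean_fix, t, m))
  }
  log(p)
}

#' Corpus log-likelihood under the origin-fixation model
#'
#' Languages are independent, so the corpus log-likelihood is the sum of the
#' per-language [path_probability()] values. `params` may be a single
#' [of_params()] shared by all languages or a list with one entry per
#' language (as for the individual-based theories, where the emergent
#' parameters depend on each language's population size).
#'
#' @inheritParams path_probability
#' @param corpus a [corpus()] object.
#' @param params an [of_params()] or list of them, one per language.
#' @return total log-likelihood (may be `-Inf`).
#' @export
corpus_log_likelihood <- function(corpus, params,
                                  variant = c("counts", "endpoint")) {
  stopifnot(inherits(corpus, "cycle_corpus"))
  variant <- match.arg(variant)
  n <- length(corpus$histories)
  if (n == 0L) return(0)
  plist <- if (inherits(params, "of_params")) rep(list(params), n) else params
  if (length(plist) != n) {
    stop("params must be one of_params or a list with one entry per language",
         call. = FALSE)
  }
  sum(vapply(seq_len(n), function(i) {
    path_probability(corpus$histories[[i]], plist[[i]], variant)
  }, numeric(1)))
}

#' Stationary stage occupancy of the origin-fixation model
#'
#' By renewal-reward, the long-run fraction of time spent recorded at stage
#' `i` is proportional to the mean sojourn at that stage,
#' `1/omega_i + mean_fix` (the stage is attributed to the outgoing
#' convention while a fixation is in progress). With instantaneous fixation
#' and `omega_i = mean_rate / (4 f_i)` the occupancy is exactly `f`.
#'
#' @param params an [of_params()] object with all rates positive.
#' @return frequency vector of length 4 summing to 1.
#' @export
stationary_occupancy <- function(params) {
  stopifnot(inherits(params, "of_params"))
  if (any(params$omega == 0)) {
    stop("degenerate occupancy: all origination rates must be positive",
         call. = FALSE)
  }
  w <- 1 / params$omega + params$mean_fix
  w / sum(w)
}

#' Monte Carlo goodness-of-fit p-value
#'
#' Simulates corpora from the fitted model -- matching each observed
#' language's window and initial stage -- and reports the probability of
#' data less likely than those observed: the fraction of simulated corpora
#' whose log-likelihood falls strictly below the observed corpus's, with
#' ties counted one half (mid-p convention). A low p-value signals a likely
#' departure from the model.
#'
#' @inheritParams corpus_log_likelihood
#' @param n_sims number of simulated corpora.
#' @param seed optional integer seed.
#' @return list with `p`, `log_lik_obs`, and `n_sims`.
#' @export
mc_p_value <- function(corpus, params, n_sims = 1e6L, seed = NULL,
                       variant = c("counts", "endpoint")) {
  stopifnot(inherits(corpus, "cycle_corpus"))
  variant <- match.arg(variant)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(corpus$histories)
  plist <- if (inherits(params, "of_params")) rep(list(params), n) else params
  total_sim <- numeric(n_sims)
  loglik_obs <- 0
  for (i in seq_len(n)) {
    h <- corpus$histories[[i]]
    t <- h$window_end - h$window_start
    dist <- count_distribution(h$initial_stage, t, plist[[i]])
    if (variant == "endpoint") {
      vals <- vapply(0:3, function(j) {
        idx <- seq(j, length(dist) - 1L, by = 4L) + 1L
        sum(dist[idx])
      }, numeric(1))
      obs_idx <- (final_stage(h) %% 4L) + 1L
      dist <- vals
      obs_p <- vals[obs_idx]
    } else {
      obs_m <- n_changes(h)
      obs_p <- if (obs_m < length(dist)) dist[obs_m + 1L] else 0
    }
    loglik_obs <- loglik_obs + (if (obs_p > 0) log(obs_p) else -Inf)
    lp <- ifelse(dist > 0, log(dist), -Inf)
    draw <- sample.int(length(dist), n_sims, replace = TRUE, prob = dist)
    total_sim <- total_sim + lp[draw]
  }
  if (!is.finite(loglik_obs)) {
    return(list(p = 0, log_lik_obs = loglik_obs, n_sims = n_sims))
  }
  tol <- 1e-9
  p <- mean(total_sim < loglik_obs - tol) +
    0.5 * mean(abs(total_sim - loglik_obs) <= tol)
  list(p = p, log_lik_obs = loglik_obs, n_sims = n_sims)
}
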