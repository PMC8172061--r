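---
title: "Two-scale models of article grammaticalisation cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale models of article grammaticalisation cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclefix)
```

## The problem

Definite and indefinite articles evolve through a four-stage cycle: a
language with no article (stage 0) recruits a demonstrative or the numeral
*one* for article duty (stage 1), the form then diverges from its source
(stage 2), reduces to an affix (stage 3), and is finally lost, returning the
language to stage 0. Surveys of documented histories record, per language,
an observation window of a few hundred to a few thousand years and the
dated transitions through this cycle; cross-linguistic typologies (WALS
features 37A/38A) record how many of the world's languages currently sit at
each stage. Typical change rates are of order $10^{-3}$ per year, and the
mean historical speaker populations of the surveyed languages span roughly
six orders of magnitude.

`cyclefix` asks which theory of *individual* behaviour best explains these
*population-scale* changes. It implements two connected models — a
population-level origin-fixation process and an individual-based
Wright–Fisher model on social networks — and a likelihood pipeline that
compares child-based, usage-based and network-structured theories against a
corpus of dated histories via AICc, overdispersion and Monte Carlo
p-values.

## The origin-fixation model

At stage $i$, innovations that will ultimately take over the speech
community *originate* as a Poisson process with rate $\omega_i$ (per year).
Each origination is followed by a *fixation* episode of random duration
$T_F$, after which the whole community uses the new form and the next stage
begins. $T_F$ is approximated by a Gamma law with mean $\bar T_F$ and
variance $\sigma^2_F$ (shape $\alpha = \bar T_F^2/\sigma^2_F$, rate $\beta
= \bar T_F/\sigma^2_F$); the survey classifies a language at the outgoing
stage until fixation completes, because fixation is defined as the
innovation reaching 100% of relevant contexts. Setting $\bar T_F = 0$
yields a continuous-time Markov chain on the 4-cycle (the "Poisson
baseline").

Choosing $\omega_i = \bar\omega/(4 f_i)$, with $f_i$ the fraction of
surveyed languages currently at stage $i$, makes the stationary occupancy
of the cycle equal to $f$ exactly in the instantaneous-fixation model
(renewal–reward: occupancy $\propto 1/\omega_i + \bar T_F$), so the model
is consistent with the observed typology for any overall rate $\bar\omega$.

### Likelihood

Each language contributes independently. The default (`"counts"`) variant
evaluates the probability that exactly the observed number $m$ of
fixations completes inside the window, ending at the observed final stage;
because the cycle forbids skipping, the stage sequence is determined by
$m$, and the dated transition times carry no additional likelihood
information. An `"endpoint"` variant, which sums over all $m$ compatible
with the endpoint stages, is provided for surveys that record only start
and end states. Transition dates with interval dating can carry an
uncertainty column in the corpus files; the default likelihood ignores it.

Numerically:

* With $\bar T_F = 0$ the exactly-$m$ probabilities come from a triangular
  matrix exponential over the jump-counting chain (machine precision).
* With $\bar T_F > 0$ the stage sojourns (exponential origination wait plus
  Gamma fixation) are convolved as exact-CDF cell masses on a uniform grid
  over the window, with the grid step at most $\min(\bar T_F, t)/50$
  (capped at $2^{14}$ cells) and the $m = 0$ term evaluated by Simpson
  quadrature. Against a $2\times10^5$-replicate Monte Carlo oracle the
  scheme is accurate to a few parts in $10^3$.
* When $\bar T_F$ falls below both $10^{-3}/\omega_{\max}$ and $t/1000$,
  the Markov-limit kernel is used directly: in that regime the residual
  effect of the fixation delay is smaller than the grid error, so the
  limit is the more accurate evaluation.
* Windows with more than 6 changes fall back to a Monte Carlo estimator of
  the exactly-$m$ probability.
* Deep in implausible parameter regions the probabilities underflow; the
  log-likelihood is then assembled in log space from the two series
  bottlenecks (a Poisson-style origination count and the
  $\mathrm{Gamma}(m\alpha,\beta)$ left tail for $m$ completed episodes;
  a changeless window needs only one slow sojourn, so those combine by max
  rather than min). This keeps profile searches finite and monotone; all
  fitted optima in the analyses reported here lie inside the exact regime.

The model starts each window with a fresh origination clock (exact, by
memorylessness) and treats originations of the following stage as frozen
while a fixation is in progress; the possibility that a second origination
overlaps the first is neglected. This is recorded as an approximation of
the package.

Goodness of fit uses two devices. `mc_p_value()` simulates corpora with the
observed windows and initial stages and reports the fraction whose
log-likelihood falls strictly below the observed one, counting ties one
half (mid-p convention — unbiased where the likelihood is discrete).
`overdispersion()` compares each language's observed summary (change count,
or the indicator of any change) against its simulated model mean and
variance, $O_X = (X - \bar X)^2/\mathrm{Var}(X)$, averaged over languages;
values near 1 indicate deviations of the expected size. Both are exercised
under the generating model in the test suite (mean $p \approx 0.5$, mean
$O_X \approx 1$).

## The Wright–Fisher model

Each of $N$ speakers carries an innovation frequency $x_n \in [0,1]$.
Updates occur asynchronously at total rate $NR$ (exponential clocks — this
matches a continuous interaction-rate parameter and avoids the ordering
artifacts of synchronous sweeps): the updating speaker hears one
interlocutor, chosen among network neighbours with probability
$\propto 1 + s\,x_m$ (selection strength $s$), perceives the innovation
with probability $x_m$ (plus $(1-x_m)\eta_i$ in innovation-injection
mode), and sets $x_n \leftarrow (1-\epsilon)x_n + \epsilon\tau$ with
$\tau \in \{0,1\}$ the perceived variant. The update impact $\epsilon$
defines the memory time $T_M = 1/(R\epsilon)$, the expected lifetime of
one stored item of linguistic experience. With $\epsilon = 1$ speakers are
categorical (the child-based limit); $\epsilon < 1$ gives incremental,
usage-based adjustment. The update rule is convex, so all $x_n$ stay in
$[0,1]$; with $\epsilon < 1$ exact absorption is unreachable in finite
steps and the population mean frequency is declared absorbed beyond
$10^{-12}$ of either boundary.

Social networks are configuration-model graphs whose degrees are drawn
i.i.d. from the discrete power law $p_z \propto z^{-(1+\nu)}$ with natural
cutoff $z_{\max} = z_{\min} N^{1/\nu}$; self and parallel edges are removed
by degree-preserving rewiring and the largest component is used. All
moments are computed from realised degrees — on finite graphs the realised
moments, not the nominal exponent, are the truth. For speech communities
too large to realise ($N$ up to $10^9$ in the theory scans), continuum
moments of the truncated power law are used instead (`powerlaw_moments()`),
which reproduce the same $N_e \sim N^{2-2/\nu}$ scaling.

### Diffusion approximation and the discrete-update correction

Between originations the population frequency follows the diffusion
$T_M \dot P = -s[x(1-x)P]' + \tfrac{1}{2N_e}[x(1-x)P]''$. The asymptotic
effective size is $N_e = N(\bar z^2/\overline{z^2})/\epsilon$. At finite
$\epsilon$, however, the copy-update rule leaves a quasi-stationary
speaker-level variance $\epsilon x(1-x)/(2-\epsilon)$ that inflates the
sampling noise of the population mean by $2/(2-\epsilon)$; the diffusion
that actually matches the event-driven simulator therefore has drift size
$N_e (2-\epsilon)/2$. At $\epsilon = 1$ this is the familiar factor 2
between copy/Moran-type dynamics and a generation-based Wright–Fisher
population, and it vanishes as $\epsilon \to 0$.
`effective_population_size()` returns the asymptotic convention by default
and the corrected size with `discrete = TRUE`; the bridge to the
origin-fixation scale and every simulation-versus-theory test use the
corrected size (simulated fixation probabilities and times at
$\epsilon = 1$ are otherwise off by a factor approaching 2).

Fixation probabilities follow the backward equation,
$Q(x_0) = (1-e^{-2N_e s x_0})/(1-e^{-2N_e s})$, evaluated stably for
$|2N_e s|$ up to $10^9$ and beyond. Conditional fixation-time moments are
computed by Green-function quadrature: with $u$ the fixation probability
and $t(x,p)$ the sojourn-time kernel of the backward operator,
$E[T\,1_{\rm fix}](p) = \int t(x,p)u(x)\,dx$ and
$E[T^2 1_{\rm fix}](p) = 2\int t(x,p)\,E[T\,1_{\rm fix}](x)\,dx$. The
integrals are evaluated on 2001 logit-spaced frequency points (resolving
the $O(1/2N_e s)$ boundary layers at any selection strength), with the
exponentially weighted pieces accumulated by a damped recurrence that
never forms an overflowing factor. The neutral mean reproduces the
classical closed form $-2N_e(1-p)\ln(1-p)/p$ (the test oracle) to better
than $10^{-4}$ relative; strong selection recovers the
$T_M \ln(N_e)/s$ scale. For $s < 0$ the moments are evaluated at $|s|$,
exact in the rare-innovation limit $x_0 \to 0$ by the classical
fixation-time symmetry — and the package only ever needs
$x_0 = \epsilon/N$.

Two caveats the tests make explicit: the diffusion neglects sparse-graph
pair correlations (on $z$-regular graphs the consensus time carries a
$(z-1)/(z-2)$-type correction, so simulator comparisons use degree 30,
where the correction is a few percent), and the Gamma law is an
approximation to the true fixation-time distribution — the
Kolmogorov–Smirnov distance to simulated conditional fixation times at
$N = 150$, $s = 0.01$ is about 0.05–0.09, well below the 0.15 bound the
tests assert but visibly nonzero.

## Bridging the scales and the theory families

The emergent origination rates are $\omega_i = N R \eta_i\,Q(\epsilon/N)$:
innovation attempts arise at rate $NR\eta_i$ and each survives with the
fixation probability started from one affected speaker,
$x_0 = \epsilon/N$. The fixation-time mean and variance come from the
diffusion quadrature at the same $x_0$, and the Gamma law is matched by
moments. Two structural consequences drive everything downstream: at
$s = 0$, $Q = \epsilon/N$ exactly, so $\omega_i = R\eta_i\epsilon$ is
independent of $N$ but $\bar T_F \propto N$; as $s \to \infty$, $Q \to 1$,
so $\omega_i = NR\eta_i$ grows linearly in $N$ while fixation becomes
instantaneous on the population timescale. The infinite-selection member
of each family is evaluated analytically in that limit rather than at a
huge finite $s$.

Three families are compared (`theory_spec()`):

* **Poisson baseline** — population-level Poisson changes,
  $\omega_i = \bar\omega/(4f_i)$, $T_F = 0$; profiled parameter
  $\bar\omega$.
* **Child-based** — updates once per human generation, taken as exactly 25
  years ($R = 0.04\,\mathrm{yr}^{-1}$), categorical learning
  ($\epsilon = 1$); profiled parameter the mean learning-error rate
  $\bar\eta$.
* **Usage-based** — any interaction rate $R$ at fixed memory time, with
  $\epsilon = 1/(RT_M)$; configurations requiring $\epsilon > 1$ are
  computed but flagged unphysical.

Selection strength $s$, network exponent $\nu$ and memory time $T_M$ are
scanned conditions, not fitted parameters, so every family has $k = 1$ in
AICc $= 2k - 2\ln L + 2k(k+1)/(n-k-1)$, with $n$ the number of languages.
The per-stage allocation of the innovation rate is an open design point:
the default `"stationary"` profile sets
$\eta_i = \bar\eta\,\tfrac14 f_{\rm harm}/f_i$ (harmonic mean
$f_{\rm harm}$), so the emergent $\omega_i \propto 1/f_i$ mirrors the
baseline's stationarity structure and $\bar\eta$ is a pure scale; a
`"uniform"` profile (a single constant $\eta$) is switchable. Profiling
maximises the corpus log-likelihood by golden-section search on
$\log_{10}$ of the rate; the scans re-profile the rate at every grid
point.

## The synthetic survey generator

No survey of dated histories is distributed with the package, so
`generate_corpus()` emulates one: 52 languages; window lengths log-uniform
on 200–3000 years (windows end at year 2000) — a range bracketing the
documented-history era that yields 0–5 changes per language; mean
population sizes log-uniform over $10^3$–$10^9$ (six decades); initial
stages drawn from the generating model's stationary occupancy; histories
sampled forward from an origin-fixation parameterisation, by default
$\bar\omega = 6.05\times10^{-4}\,\mathrm{yr}^{-1}$ allocated by the
definite-article typology with fixation episodes of mean 100 years (sd
50), matching the order of magnitude documented surveys suggest for
propagation times. An emergent mode instead derives each language's
parameters from an individual-based theory at its population size.
Population sizes are held constant over a language's window, mirroring the
use of per-language historical means.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: languages are generated independently
(no phylogenetic or areal correlation between histories), dating is exact
rather than interval-censored, the typology is exactly stationary, and
population sizes are uncorrelated with window length and rate. Tests
against synthetic corpora validate the machinery and the qualitative
population-size argument, not the historical point estimates.

## What the comparisons show

On synthetic corpora generated by the population-size-independent
baseline, the child-based family is heavily dispreferred across the whole
selection grid, least badly in the infinite-selection limit; its
$\Delta\mathrm{AICc}$ against the baseline grows monotonically as the
corpus's population-size spread widens from one to six decades (the
headline pattern), and shrinks — at fixed six-decade spread — when memory
times drop to hours (usage-based) or when speakers sit on heterogeneous
$\nu = 1.2$ networks, whose effective size grows only like $N^{1/3}$.
These are exactly the trends the acceptance suite asserts; the test
problem sizes (52-language corpora, $2$–$3\times10^4$ simulator
replicates, networks up to $10^5$ nodes, six replicates per size for the
scaling fit) were chosen to give comfortable Monte Carlo margins at those
assertions.

## Degenerate inputs and other numerical conventions

* Zero origination rates: histories requiring an impossible origination
  get log-probability $-\infty$ (structural zero); stationary occupancy is
  undefined and errors; the synthetic generator falls back to the
  typological frequencies for initial stages.
* $\sigma_F^2 \to 0$ degenerates to a deterministic fixation delay;
  $\bar T_F \to 0$ converges to the Markov kernel (both asserted in the
  tests).
* Languages whose summary statistic is numerically deterministic under a
  theory are excluded from the overdispersion average with a warning —
  this happens legitimately when a theory predicts essentially no change.
* All times are years, rates $\mathrm{yr}^{-1}$; windows are half-open
  $[\mathrm{start}, \mathrm{end})$ on a common-era axis.
* Every stochastic entry point takes an explicit seed, and the pipeline
  records seeds and resolved parameters in a JSON manifest; identical
  configuration and seed reproduce artifacts byte for byte.

## Limitations

Conformity bias, prestige and other socially stratified effects are out of
scope, as are speaker birth–death turnover and multi-feature joint
likelihoods (definite and indefinite articles are correlated across
languages, so their likelihoods should not be multiplied). The
second-origination overlap correction is not implemented. The $\Delta$AICc
scans emit tables, not figures.
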