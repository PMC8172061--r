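# cyclefix

Likelihood-based comparison of theories of language change on article
grammaticalisation cycles.

Articles evolve through a four-stage cycle — no article → article identical
to its source word (*that*, *one*) → distinct word → affix → loss. Documented
histories give, per language, an observation window (hundreds to thousands of
years) and the dated stage transitions inside it; WALS features 37A/38A give
the current cross-linguistic distribution over stages. `cyclefix` implements
a two-scale model of this process and asks which account of *individual*
speaker behaviour — child-based acquisition error, incremental usage-based
adjustment, or either on heterogeneous social networks — best explains the
*population-scale* record.

**Population scale.** An origin-fixation model: at stage *i*, successful
innovations originate as a Poisson process with rate ω\_i = ω̄/(4f\_i)
(which makes the stationary stage occupancy match the typological fractions
f), and each takes a Gamma-distributed fixation time T\_F (mean T̄\_F,
variance σ²\_F) to take over the community. The corpus likelihood, Monte
Carlo goodness-of-fit p-values and overdispersion statistics
O\_X = (X − X̄)²/Var(X) are computed from this process.

**Individual scale.** A Wright–Fisher model: N speakers with innovation
frequencies x\_n update at rate R by hearing a network neighbour (chosen ∝
1 + s·x\_m) and shifting x\_n ← (1−ε)x\_n + ε·τ. The emergent parameters
feed the population scale through ω\_i = N·R·η\_i·Q(ε/N), with Q the
diffusion fixation probability Q(x₀) = (1−e^{−2N\_e s x₀})/(1−e^{−2N\_e s})
at the network's effective size N\_e = N(z̄²/z̄²)/ε, and (T̄\_F, σ²\_F)
from the conditional fixation-time quadrature of the diffusion. On
power-law networks with exponent ν < 2, N\_e ~ N^{2−2/ν}.

Theories are compared by AICc = 2k − 2 ln L + 2k(k+1)/(n−k−1), with
ΔAICc = AICc(candidate) − AICc(baseline) and evidence ratio e^{ΔAICc/2}.

No survey of dated histories is distributed; a synthetic-corpus generator
(`generate_corpus()`) emulates one — 52 languages, log-uniform windows of
200–3000 years, population sizes spanning 10³–10⁹ — so the whole pipeline is
testable end to end. See the vignette
`vignettes/grammaticalisation-cycles.Rmd` for the models, numerical choices
and limitations.

## Worked example

```r
library(cyclefix)
f <- stationary_frequencies(article_typology("definite"))
cp <- generate_corpus(synthetic_config(seed = 1))
cp
#> <cycle_corpus> definite: 52 languages, 21 changes (median window 918.884 yr)

base <- fit_theory(cp, theory_spec("poisson_baseline"), f)
base
#> <comparison_result> poisson_baseline: logL = -38.044 (n = 52, k = 1), AICc = 78.17
#>   fitted rate = 0.0003982 /yr (omega_bar)

child <- against_baseline(fit_theory(cp, theory_spec("child_based", s = Inf), f), base)
child
#> <comparison_result> child_based: logL = -126.500 (n = 52, k = 1), AICc = 255.08
#>   fitted rate = 1.04e-09 (eta_bar)
#>   delta AICc vs baseline = 176.91 (evidence ratio 2.61e+38)

overdispersion(cp, base$params, "counts", n_sims = 2000, seed = 2)$mean
#> [1] 1.03
```

The baseline recovers a change rate of about 4×10⁻⁴/yr from this corpus
(one change per few thousand years per language; the generating rate was
6.05×10⁻⁴/yr with 100-year fixation episodes) and its overdispersion sits
near 1, i.e. the per-language change counts deviate by about as much as the
model expects. The child-based theory — even at its most favourable,
infinite-selection setting — is ~10³⁸ times less probable: its fixation
times and origination rates inherit the languages' population sizes, which
span six orders of magnitude, while the data carry no such signal.

The same pipeline is scriptable from a shell via the thin wrapper
`inst/cli/cyclefix` (commands `synth`, `fit-baseline`, `scan-child`,
`scan-usage`, `scan-network`, `validate`; YAML config, seeds recorded in a
JSON manifest, deterministic artifacts per seed).

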