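# Shared fixtures: all built in code at test time.

def_freqs <- function() stationary_frequencies(article_typology("definite"))

# a small hand-built corpus with known change counts
tiny_corpus <- function() {
  corpus(list(
    language_history("alpha", 1000, 2000, 0,
                     data.frame(time = c(1200, 1700), new_stage = c(1, 2)),
                     population_size = 1e5),
    language_history("beta", 800, 1800, 2, population_size = 1e4),
    language_history("gamma", 1500, 2000, 3,
                     data.frame(time = 1900, new_stage = 0),
                     population_size = 1e6)
  ), feature = "definite")
}

# uniform-rate instantaneous-fixation parameters
unif_params <- function(rate = 1e-3) of_params(rep(rate, 4))
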