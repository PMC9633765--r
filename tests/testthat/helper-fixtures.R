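# Stationary 2-state Markov fixture: a single chunk with a fixed matrix.
# Used for the model-reduction checks, where the jump and fixed learners
# are only equivalent in the absence of change-point evidence.
stationary_sequence <- function(n, p_h_given_l, p_h_given_h, seed) {
  set.seed(seed)
  h <- logical(n)
  h[1] <- runif(1) < 0.5
  for (t in 2:n) {
    p <- if (h[t - 1]) p_h_given_h else p_h_given_l
    h[t] <- runif(1) < p
  }
  ifelse(h, "H", "L")
}

# Small volatile sequence for observer fixtures
fixture_sequence <- function(n_trials = 200L, seed = 7L) {
  generate_sequence(
    generator_config(n_blocks = 1L, n_trials_per_block = n_trials),
    seed = seed
  )
}

# One synthetic subject: volatile sequence plus noisy observer ratings
synthetic_subject <- function(model, params, noise_sd = 0.1,
                              seed = 1L, n_blocks = 5L,
                              n_trials_per_block = 300L, subject = 1L) {
  s <- generate_sequence(
    generator_config(n_blocks = n_blocks,
                     n_trials_per_block = n_trials_per_block),
    seed = seed
  )
  r <- simulate_observer_ratings(s, model, params, noise_sd = noise_sd,
                                 subject = subject)
  list(seq = s, ratings = r)
}
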