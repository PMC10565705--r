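# Builders for small hand-constructed trial tables and light simulated
# (delta, error, loc) datasets used across the tests.

# A minimal valid trial table; any column can be overridden by name.
make_trials <- function(n = 10, participant = "P01", session = 1, ...) {
  base <- data.frame(
    participant_id = participant,
    session = session,
    trial_index = seq_len(n),
    location_condition = rep(c("random", "fixed"), length.out = n),
    distractor_present = FALSE,
    distractor_orientation = NA_real_,
    distractor_location = NA_integer_,
    probe_orientation = seq(5, by = 13, length.out = n) %% 180,
    reported_orientation = seq(7, by = 13, length.out = n) %% 180,
    discrimination_correct = TRUE,
    discrimination_rt = 500,
    adjustment_rt = 1500,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Random valid trial table (for I/O round-trip property tests).
random_trials <- function(n = 25, participants = 2) {
  per <- ceiling(n / participants)
  do.call(rbind, lapply(seq_len(participants), function(p) {
    present <- runif(per) < 0.5
    make_trials(per, participant = sprintf("P%02d", p),
                distractor_present = present,
                distractor_orientation = ifelse(present,
                                                sample(seq(0, 160, 20), per, TRUE),
                                                NA_real_),
                distractor_location = ifelse(present,
                                             sample.int(4, per, TRUE),
                                             NA_integer_),
                probe_orientation = runif(per, 0, 180),
                reported_orientation = runif(per, 0, 180),
                discrimination_rt = runif(per, 250, 900),
                adjustment_rt = runif(per, 800, 4000))
  }))
}

# Pooled (delta, error, loc) triples from known kernels + Gaussian noise:
# the lightweight generative model for fit-level tests.
gen_triples <- function(n, attract_peak = 0, attract_width = 25,
                        repulse_peak = 0, repulse_width = 60,
                        noise_sd = 10) {
  delta <- runif(n, -90, 90)
  loc <- rbinom(n, 1, 0.5)
  error <- dog_kernel(delta, attract_peak, attract_width) +
    (if (repulse_peak != 0) dog_kernel(delta, repulse_peak, repulse_width) else 0) +
    rnorm(n, 0, noise_sd)
  data.frame(delta = delta, error = error, loc = loc)
}
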