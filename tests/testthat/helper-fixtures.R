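# shared fixture builders; all randomness is seeded by the caller

# a hand-made rating profile
make_profile <- function(health, taste, decision) {
  data.frame(stimulus_id = sprintf("s%02d", seq_along(health)),
             health = as.integer(health), taste = as.integer(taste),
             decision = as.integer(decision), stringsAsFactors = FALSE)
}

# a profile with exactly orthogonal, mean-zero health/taste ratings
orthogonal_profile <- function(n_rep = 5) {
  h <- rep(c(-2, -1, 1, 2), n_rep)
  t <- rep(c(1, -1, -1, 1), n_rep)
  make_profile(h, t, sign(h))
}

# regular events with constant reaction time and microtime-aligned onsets
regular_events <- function(profile, block = "decision", rt = 2, spacing = 20,
                           start = 10) {
  n <- nrow(profile)
  data.frame(onset = start + (seq_len(n) - 1) * spacing, duration = rt,
             trial_type = block, stimulus_id = profile$stimulus_id,
             response = switch(block, health = profile$health,
                               taste = profile$taste, profile$decision),
             stringsAsFactors = FALSE)
}

# quick noise-free config for behavioural closure tests
quiet_config <- function(...) {
  sim_config(rating_noise_sd = 0, decision_noise_sd = 0, missing_prob = 0,
             ...)
}

# simulate events + truth design + bold for one subject over given voxels
simulate_subject_run <- function(config, stimuli, true_class, block,
                                 labels, voxels, with_coupling = FALSE) {
  profile <- simulate_subject(config, stimuli, true_class)
  timing <- simulate_timing(config$n_stimuli, config)
  ev <- scfmri:::make_events(block, profile, timing,
                             sample(config$n_stimuli))
  td <- scfmri:::truth_design(ev, profile, config)
  run <- simulate_bold(td, labels, config, true_class, voxels = voxels,
                       with_coupling = with_coupling)
  list(profile = profile, events = ev, truth = td, bold = run$data,
       motion = run$motion, seed_neural = run$seed_neural)
}
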