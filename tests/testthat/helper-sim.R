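# shared fixture builders

zt_design <- function(replicates = 3, timepoints = c(4, 8, 12, 16, 20, 24)) {
  rep(timepoints, each = replicates)
}

# paired reference/test expression simulations whose rhythmic genes differ
# only by a fixed acrophase offset (test peaks `offset` hours earlier)
offset_pair <- function(n_genes, offset, seed) {
  set.seed(seed)
  M <- stats::runif(n_genes, 50, 150)
  phi <- stats::runif(n_genes, 0, 24)
  ref_specs <- lapply(seq_len(n_genes), function(i)
    rhythm_spec(M[i], M[i] / 2, phi[i], noise_sd = 0.1 * M[i]))
  test_specs <- lapply(seq_len(n_genes), function(i)
    rhythm_spec(M[i], M[i] / 2, (phi[i] - offset) %% 24, noise_sd = 0.1 * M[i]))
  ref <- simulate_expression_timecourse(
    expression_sim_config(n_genes, 0, rhythm_specs = ref_specs, seed = seed + 1))
  test <- simulate_expression_timecourse(
    expression_sim_config(n_genes, 0, rhythm_specs = test_specs, seed = seed + 2))
  list(ref = ref, test = test)
}

# five simulated animals recorded for `days` days, one event stream
cohort_events <- function(n_subjects = 5, days = 3, capacity_modulation = 0.4,
                          jitter = 10, seed0 = 0) {
  evs <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sim <- simulate_void_events(void_sim_config(
      days = days, capacity_modulation = capacity_modulation,
      event_jitter_sd = jitter, seed = seed0 + s))
    ev <- sim$events
    ev$subject <- paste0("m", s)
    ev
  }))
  attr(evs, "start_zt") <- 14
  evs
}
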