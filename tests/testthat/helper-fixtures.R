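# Programmatic fixtures shared across test files.

make_trials <- function(n = 6, conditions = rep(c("congruent", "incongruent"),
                                                length.out = n)) {
  trial_table(
    trial_id = seq_len(n),
    scene_id = sprintf("scene_%04d", seq_len(n)),
    object_label = sprintf("concept_%04d", seq_len(n)),
    condition = conditions
  )
}

make_epochs <- function(n_trials = 6, n_channels = 4, times = seq(-100, 100, 25),
                        seed = 1, subject_id = "sub-01",
                        trials = make_trials(n_trials)) {
  data <- scenersa:::with_seed(seed, {
    array(rnorm(n_trials * n_channels * length(times)),
          c(n_trials, n_channels, length(times)))
  })
  epoch_set(subject_id, data, times,
            sprintf("ch_%03d", seq_len(n_channels)),
            sfreq = 1000 / diff(times[1:2]), trials = trials)
}

make_norms <- function(n_concepts = 8, n_features = 12, seed = 3,
                       concept_names = sprintf("concept_%04d",
                                               seq_len(n_concepts))) {
  generate_feature_norms(n_concepts, n_features, density = 0.4, seed = seed,
                         concept_names = concept_names)
}

# small simulation config whose windows fit the reduced grid; ... overrides
small_cfg <- function(...) {
  args <- list(n_subjects = 4, n_scenes = 12, n_channels = 8,
               time_start = -100, time_stop = 300, time_step = 20,
               congruency_window = c(100, 220),
               semantic_window_congruent = c(0, 100),
               semantic_window_incongruent = c(0, 200),
               seed = 11)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
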