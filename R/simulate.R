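#' Simulation configuration for the synthetic EEG study
#'
#' Collects every parameter of the synthetic-data generator. Defaults
#' emulate the target study design: 152 scenes per participant split 76/76
#' between congruent and incongruent scene-object pairings, counterbalanced
#' across two participant groups; 64 channels; epochs from -200 to 900 ms
#' at 5 ms steps (221 timepoints, 200 Hz); sparse binary property norms;
#' a congruency pattern injected at 290-450 ms; semantic geometry injected
#' at 150-235 ms for congruent and 150-360 ms for incongruent trials
#' (semantic processing extended in time for incongruent objects); unit
#' Gaussian sensor noise.
#'
#' @param n_subjects number of participants (split into two
#'   counterbalancing groups).
#' @param n_scenes scenes per participant; must be even.
#' @param n_channels EEG channels.
#' @param time_start,time_stop,time_step epoch time grid in ms.
#' @param n_concepts concepts in the synthetic norms; defaults to
#'   `2 * n_scenes` so each scene has a distinct congruent and incongruent
#'   object concept.
#' @param n_features features in the synthetic norms.
#' @param feature_density Bernoulli probability of a concept having a
#'   feature, in (0, 1).
#' @param n_categories latent concept categories planted in the norms
#'   (0 = none).
#' @param category_mixing probability that a concept copies its category
#'   prototype's feature value rather than drawing independently.
#' @param congruency_window,congruency_amplitude latency window (ms) and
#'   amplitude (microvolts) of the injected congruency pattern.
#' @param semantic_window_congruent,semantic_window_incongruent latency
#'   windows of the injected per-condition semantic geometry.
#' @param semantic_amplitude_congruent,semantic_amplitude_incongruent
#'   amplitudes of the injected semantic patterns.
#' @param noise_sd standard deviation of the Gaussian sensor noise
#'   (microvolts).
#' @param ar_coef optional AR(1) coefficient of the noise along time
#'   (0 = white); marginal variance is held at `noise_sd^2`.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20, n_scenes = 152, n_channels = 64,
                       time_start = -200, time_stop = 900, time_step = 5,
                       n_concepts = 2 * n_scenes, n_features = 300,
                       feature_density = 0.1, n_categories = 0,
                       category_mixing = 0.5,
                       congruency_window = c(290, 450),
                       congruency_amplitude = 1,
                       semantic_window_congruent = c(150, 235),
                       semantic_window_incongruent = c(150, 360),
                       semantic_amplitude_congruent = 1,
                       semantic_amplitude_incongruent = 1,
                       noise_sd = 1, ar_coef = 0, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_scenes = as.integer(n_scenes),
              n_channels = as.integer(n_channels),
              time_start = time_start, time_stop = time_stop,
              time_step = time_step,
              n_concepts = as.integer(n_concepts),
              n_features = as.integer(n_features),
              feature_density = feature_density,
              n_categories = as.integer(n_categories),
              category_mixing = category_mixing,
              congruency_window = congruency_window,
              congruency_amplitude = congruency_amplitude,
              semantic_window_congruent = semantic_window_congruent,
              semantic_window_incongruent = semantic_window_incongruent,
              semantic_amplitude_congruent = semantic_amplitude_congruent,
              semantic_amplitude_incongruent = semantic_amplitude_incongruent,
              noise_sd = noise_sd, ar_coef = ar_coef,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_scenes %% 2L != 0L) {
    stop_scenersa("n_scenes must be even for a 50/50 condition split",
                  class = "scenersa_config_error")
  }
  if (cfg$feature_density <= 0 || cfg$feature_density >= 1) {
    stop_scenersa("feature_density must lie in (0, 1)",
                  class = "scenersa_config_error")
  }
  if (cfg$n_concepts < 2L * cfg$n_scenes) {
    stop_scenersa("need n_concepts >= 2 * n_scenes so every scene has ",
                  "distinct congruent and incongruent object concepts",
                  class = "scenersa_config_error")
  }
  times <- sim_times(cfg)
  for (w in list(cfg$congruency_window, cfg$semantic_window_congruent,
                 cfg$semantic_window_incongruent)) {
    if (w[1L] < times[1L] - 1e-9 || w[2L] > times[length(times)] + 1e-9) {
      stop_scenersa("injection window [", w[1L], ", ", w[2L],
                    "] ms outside the epoch time grid",
                    class = "scenersa_config_error")
    }
  }
  if (cfg$congruency_amplitude < 0 || cfg$semantic_amplitude_congruent < 0 ||
      cfg$semantic_amplitude_incongruent < 0 || cfg$noise_sd < 0) {
    stop_scenersa("amplitudes and noise_sd must be non-negative",
                  class = "scenersa_config_error")
  }
  if (abs(cfg$ar_coef) >= 1) {
    stop_scenersa("ar_coef must lie in (-1, 1)",
                  class = "scenersa_config_error")
  }
  invisible(cfg)
}

sim_times <- function(cfg) seq(cfg$time_start, cfg$time_stop, cfg$time_step)

#' Names of the synthetic concept pool
#' @param n_concepts pool size.
#' @return character vector `concept_0001`, ...
#' @export
concept_pool <- function(n_concepts) {
  sprintf("concept_%04d", seq_len(n_concepts))
}

#' Generate a counterbalanced scene-object design
#'
#' Each scene appears exactly once, paired with either its congruent or its
#' incongruent object so that exactly half the trials are congruent. The
#' two counterbalancing groups receive complementary assignments: a scene
#' shown with its congruent object to group A is shown with its incongruent
#' object to group B. Scene `s` is deterministically associated with two
#' distinct concepts from the synthetic pool — `concept_{2s-1}` when
#' congruent, `concept_{2s}` when incongruent — so object identity follows
#' from scene and condition.
#'
#' @param n_scenes even number of scenes.
#' @param group `"A"` or `"B"`.
#' @param seed integer seed; both groups must be generated from the same
#'   seed for complementarity to hold.
#' @return a `trial_table` with `n_scenes` rows, 50/50 conditions.
#' @export
generate_design <- function(n_scenes, group = c("A", "B"), seed) {
  group <- match.arg(group)
  if (n_scenes %% 2L != 0L) {
    stop_scenersa("n_scenes must be even", class = "scenersa_config_error")
  }
  congruent_in_A <- with_seed(seed,
                              sample(seq_len(n_scenes), n_scenes / 2L))
  is_congruent <- seq_len(n_scenes) %in% congruent_in_A
  if (group == "B") is_congruent <- !is_congruent
  pool <- concept_pool(2L * n_scenes)
  s <- seq_len(n_scenes)
  object_label <- ifelse(is_congruent, pool[2L * s - 1L], pool[2L * s])
  trial_table(
    trial_id = s,
    scene_id = sprintf("scene_%04d", s),
    object_label = object_label,
    condition = ifelse(is_congruent, "congruent", "incongruent")
  )
}

#' Generate sparse binary property norms
#'
#' Independent Bernoulli(`density`) feature indicators per concept; any
#' concept that draws an all-zero feature vector is resampled until it has
#' at least one feature. With `n_categories > 0`, concepts are assigned
#' round-robin to latent categories, each category has a Bernoulli
#' prototype, and each concept copies the prototype's value with
#' probability `mixing` (drawing independently otherwise), which makes
#' within-category cosine distances smaller than between-category ones in
#' expectation.
#'
#' @param n_concepts,n_features matrix dimensions.
#' @param density Bernoulli probability in (0, 1); `density * n_features`
#'   should be at least 1.
#' @param seed integer seed.
#' @param n_categories number of planted categories (0 = unstructured).
#' @param mixing prototype-copy probability in \[0, 1\].
#' @param concept_names optional concept names (default `concept_0001`...).
#' @return a `feature_norms`.
#' @export
generate_feature_norms <- function(n_concepts, n_features, density, seed,
                                   n_categories = 0, mixing = 0.5,
                                   concept_names = NULL) {
  if (density <= 0 || density >= 1) {
    stop_scenersa("density must lie in (0, 1)",
                  class = "scenersa_config_error")
  }
  if (density * n_features < 1) {
    stop_scenersa("expected features per concept below 1; increase density ",
                  "or n_features", class = "scenersa_config_error")
  }
  concept_names <- concept_names %||% concept_pool(n_concepts)
  stopifnot(length(concept_names) == n_concepts)
  vals <- with_seed(seed, {
    m <- matrix(stats::rbinom(n_concepts * n_features, 1L, density),
                n_concepts, n_features)
    if (n_categories > 0) {
      cat_of <- rep_len(seq_len(n_categories), n_concepts)
      proto <- matrix(stats::rbinom(n_categories * n_features, 1L, density),
                      n_categories, n_features)
      copy <- matrix(stats::runif(n_concepts * n_features) < mixing,
                     n_concepts, n_features)
      m[copy] <- proto[cat_of, ][copy]
    }
    for (i in which(rowSums(m) == 0)) {
      while (sum(m[i, ]) == 0) {
        m[i, ] <- stats::rbinom(n_features, 1L, density)
      }
    }
    m
  })
  feature_norms(vals, concepts = concept_names,
                features = sprintf("feature_%04d", seq_len(n_features)))
}

# injection mask on the grid: 1 inside the window, ramped to 0.5 at the
# window's first and last grid point (one-grid-step on/off ramp); exactly 0
# outside the window
window_mask <- function(times, window) {
  idx <- window_idx(times, window[1L], window[2L])
  m <- numeric(length(times))
  m[idx] <- 1
  if (length(idx) >= 2L) {
    m[idx[1L]] <- 0.5
    m[idx[length(idx)]] <- 0.5
  }
  m
}

#' Generate one participant's synthetic epochs
#'
#' Data are Gaussian sensor noise plus two kinds of injected signal, each
#' confined to its latency window with a one-grid-step on/off ramp:
#'
#' * Congruency signal: a fixed random channel pattern (drawn once per
#'   subject, unit RMS per channel), added with `+amplitude` on congruent
#'   and `-amplitude` on incongruent trials inside the congruency window.
#'   The bipolar coding makes the cross-trial pattern geometry match the
#'   binary congruency model RDM exactly at high SNR.
#' * Semantic signal: each trial's concept feature vector (unit-normalised)
#'   is projected to channels through a fixed per-subject random
#'   projection; the projected pattern, scaled by that condition's
#'   amplitude, is added inside that condition's semantic window, so the
#'   cross-trial similarity inside the window mirrors the cosine structure
#'   of the norms.
#'
#' In expectation the congruency model fit is positive only inside the
#' congruency window, and each condition's semantic model fit is positive
#' only inside that condition's window — the testable contract the
#' generator is built around.
#'
#' @param config a `sim_config`.
#' @param design a `trial_table` (see [generate_design()]); all object
#'   labels must resolve in `norms`.
#' @param norms a `feature_norms` covering the design's object labels.
#' @param subject_id subject identifier string.
#' @param seed integer seed for this subject's noise and patterns.
#' @return an `epoch_set`.
#' @export
generate_epochs <- function(config, design, norms, subject_id, seed) {
  validate_sim_config(config)
  validate_trial_table(design)
  times <- sim_times(config)
  nt <- length(times)
  n_tr <- nrow(design)
  n_ch <- config$n_channels
  labels_lc <- tolower(design$object_label)
  missing_lab <- setdiff(labels_lc, concepts(norms))
  if (length(missing_lab)) {
    stop_scenersa("design labels not in norms: ",
                  paste(utils::head(missing_lab, 5L), collapse = ", "),
                  class = "scenersa_config_error")
  }

  data <- with_seed(seed, {
    noise <- array(stats::rnorm(n_tr * n_ch * nt, sd = config$noise_sd),
                   c(n_tr, n_ch, nt))
    if (config$ar_coef != 0 && config$noise_sd > 0) {
      a <- config$ar_coef
      scale <- sqrt(1 - a^2)
      for (i in seq_len(n_tr)) {
        for (ch in seq_len(n_ch)) {
          e <- noise[i, ch, ]
          x <- as.numeric(stats::filter(e * scale, a, method = "recursive"))
          # stationary start
          x[1L] <- e[1L]
          noise[i, ch, ] <- x
        }
      }
    }

    cong_pattern <- stats::rnorm(n_ch)
    cong_pattern <- cong_pattern / sqrt(mean(cong_pattern^2))
    proj <- matrix(stats::rnorm(config$n_features * n_ch), config$n_features,
                   n_ch) / sqrt(config$n_features)

    cong_mask <- window_mask(times, config$congruency_window)
    sem_mask <- list(
      congruent = window_mask(times, config$semantic_window_congruent),
      incongruent = window_mask(times, config$semantic_window_incongruent)
    )
    sem_amp <- c(congruent = config$semantic_amplitude_congruent,
                 incongruent = config$semantic_amplitude_incongruent)

    code <- ifelse(design$condition == "congruent", 1, -1)
    for (i in seq_len(n_tr)) {
      sig <- outer(cong_pattern,
                   config$congruency_amplitude * code[i] * cong_mask)
      f <- norms$values[labels_lc[i], ]
      f <- f / sqrt(sum(f^2))
      sem_pat <- as.vector(f %*% proj)
      sem_pat <- sem_pat / sqrt(mean(sem_pat^2))
      cond <- design$condition[i]
      sig <- sig + outer(sem_pat, sem_amp[[cond]] * sem_mask[[cond]])
      noise[i, , ] <- noise[i, , ] + sig
    }
    noise
  })

  epoch_set(
    subject_id = subject_id,
    data = data,
    times = times,
    channel_names = sprintf("ch_%03d", seq_len(n_ch)),
    sfreq = 1000 / config$time_step,
    trials = design
  )
}

#' Simulate a full multi-subject cohort
#'
#' Generates one shared set of property norms, the two complementary
#' counterbalanced designs, and one `epoch_set` per subject (subjects
#' alternate between counterbalancing groups A and B). All randomness
#' derives from `config$seed`; the output is fully deterministic. With
#' `out_dir` set, each subject's epochs are written to the HDF5 container
#' and the norms to TSV, and file paths are returned.
#'
#' @param config a `sim_config`.
#' @param out_dir optional output directory.
#' @return list with `epochs` (list of `epoch_set`), `norms`, `config`,
#'   and — when `out_dir` is given — `paths` (subject files) and
#'   `norms_path`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, config$n_subjects + 2L)
  norms <- generate_feature_norms(config$n_concepts, config$n_features,
                                  config$feature_density, seed = seeds[1L],
                                  n_categories = config$n_categories,
                                  mixing = config$category_mixing)
  design_seed <- seeds[2L]
  groups <- rep_len(c("A", "B"), config$n_subjects)
  epochs <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    design <- generate_design(config$n_scenes, groups[i], seed = design_seed)
    sid <- sprintf("sub-%02d", i)
    epochs[[i]] <- generate_epochs(config, design, norms, sid,
                                   seed = seeds[i + 2L])
  }
  out <- list(epochs = epochs, norms = norms, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- vapply(epochs, function(e) {
      p <- file.path(out_dir, paste0(e$subject_id, "_epochs.h5"))
      write_epochs(e, p)
      p
    }, character(1L))
    out$norms_path <- write_feature_norms(
      norms, file.path(out_dir, "norms.tsv"))
  }
  out
}
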