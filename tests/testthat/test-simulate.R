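test_that("generated designs are counterbalanced, 50/50 and deterministic", {
  a <- generate_design(152, "A", seed = 5)
  expect_equal(nrow(a), 152L)
  expect_equal(sum(a$condition == "congruent"), 76L)
  expect_equal(sum(a$condition == "incongruent"), 76L)
  expect_equal(anyDuplicated(a$scene_id), 0L)

  # group B is the exact complement, scene by scene
  b <- generate_design(152, "B", seed = 5)
  expect_true(all(a$condition != b$condition))
  expect_true(all(a$object_label != b$object_label))

  # a scene's congruent and incongruent objects are distinct concepts
  both <- rbind(a, b)
  per_scene <- split(both$object_label, both$scene_id)
  expect_true(all(vapply(per_scene, function(x) length(unique(x)) == 2L,
                         logical(1))))

  expect_identical(as.data.frame(generate_design(152, "A", seed = 5)),
                   as.data.frame(a))
  expect_false(identical(generate_design(152, "A", seed = 6)$condition,
                         a$condition))
  expect_error(generate_design(151, "A", seed = 1), "even")
})

test_that("synthetic norms match the binomial expectation and never have empty concepts", {
  n <- generate_feature_norms(100, 300, density = 0.1, seed = 9)
  expect_equal(dim(n$values), c(100L, 300L))
  expect_true(all(n$values %in% c(0, 1)))
  expect_true(all(rowSums(n$values) > 0))
  # mean row sum approx n_features * density, within 3 binomial SEs of the mean
  se <- sqrt(300 * 0.1 * 0.9 / 100)
  expect_lt(abs(mean(rowSums(n$values)) - 30), 3 * se)
})

test_that("planted categories pull within-category cosine distances below between-category", {
  deltas <- vapply(1:20, function(seed) {
    n <- generate_feature_norms(20, 60, density = 0.2, seed = seed,
                                n_categories = 2, mixing = 0.5)
    cat_of <- rep_len(1:2, 20)
    d <- matrix(NA_real_, 20, 20)
    for (i in 1:19) for (j in (i + 1):20) {
      d[i, j] <- cosine_distance(n$values[i, ], n$values[j, ])
    }
    same <- outer(cat_of, cat_of, "==")
    mean(d[upper.tri(d)][!same[upper.tri(same)]]) -
      mean(d[upper.tri(d)][same[upper.tri(same)]])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("epoch generation is fully deterministic under (config, seed)", {
  cfg <- small_cfg()
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1$norms$values, coh2$norms$values)
  for (i in seq_along(coh1$epochs)) {
    expect_identical(coh1$epochs[[i]]$data, coh2$epochs[[i]]$data)
  }
  # and byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_cohort(cfg, out_dir = d1)$paths[1]
  p2 <- simulate_cohort(cfg, out_dir = d2)$paths[1]
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("with zero noise the injected signal is confined to its windows", {
  cfg <- small_cfg(noise_sd = 0)
  design <- generate_design(cfg$n_scenes, "A", seed = 3)
  norms <- generate_feature_norms(cfg$n_concepts, cfg$n_features,
                                  cfg$feature_density, seed = 4)
  e <- generate_epochs(cfg, design, norms, "sub-01", seed = 5)
  times <- e$times
  in_any <- times >= -1e-9 + min(cfg$congruency_window[1],
                                 cfg$semantic_window_congruent[1],
                                 cfg$semantic_window_incongruent[1]) &
            times <= 1e-9 + max(cfg$congruency_window[2],
                                cfg$semantic_window_congruent[2],
                                cfg$semantic_window_incongruent[2])
  expect_equal(max(abs(e$data[, , !in_any])), 0)
  expect_gt(max(abs(e$data[, , in_any])), 0)
})

test_that("a noiseless congruency-only cohort reproduces the binary model exactly at peak", {
  cfg <- small_cfg(noise_sd = 0,
                   semantic_amplitude_congruent = 0,
                   semantic_amplitude_incongruent = 0,
                   congruency_window = c(-100, 300))  # cover the whole epoch
  design <- generate_design(cfg$n_scenes, "A", seed = 3)
  norms <- generate_feature_norms(cfg$n_concepts, cfg$n_features,
                                  cfg$feature_density, seed = 4)
  e <- generate_epochs(cfg, design, norms, "sub-01", seed = 5)
  s <- neural_rdm_series(e)
  model <- build_congruency_rdm(e$trials)
  ts <- rsa_timeseries(s, model)
  # patterns are +/- one fixed channel vector at every timepoint (the edge
  # ramp only rescales them): neural RDM entries are exactly 0 (same
  # condition) or 2 (different), a monotone transform of the binary model
  expect_true(all(ts$rho == 1))
})

test_that("recovered congruency effect strength increases with injected amplitude", {
  mass_at <- function(amp) {
    mean(vapply(1:4, function(k) {
      cfg <- small_cfg(congruency_amplitude = amp, n_subjects = 6,
                       seed = 100 + k)
      coh <- simulate_cohort(cfg)
      fits <- lapply(coh$epochs, function(e) {
        rsa_timeseries(neural_rdm_series(e), build_congruency_rdm(e$trials),
                       e$subject_id)
      })
      tv <- group_tvalues(stack_rsa(fits))
      cl <- find_clusters(tv, df = 5, alpha = 0.05)
      if (nrow(cl)) max(abs(cl$mass)) else 0
    }, numeric(1)))
  }
  masses <- c(mass_at(0.25), mass_at(0.75), mass_at(2))
  expect_true(masses[1] <= masses[2] + 1e-9)
  expect_true(masses[2] <= masses[3] + 1e-9)
})

test_that("design labels absent from the norms are a configuration error", {
  cfg <- small_cfg()
  design <- generate_design(cfg$n_scenes, "A", seed = 3)
  norms <- make_norms(n_concepts = 4)   # far too few concepts
  expect_error(generate_epochs(cfg, design, norms, "s", seed = 1),
               "not in norms")
})
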