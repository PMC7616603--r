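test_that("epoch container round-trips an epoch_set bit-exactly", {
  e <- make_epochs(n_trials = 4, n_channels = 3, times = seq(0, 40, 10))
  e$trials$keep[2] <- FALSE
  path <- withr::local_tempfile(fileext = ".h5")
  write_epochs(e, path)
  e2 <- read_epochs(path)
  expect_identical(e2$data, e$data)          # float64 storage: bit-exact
  expect_identical(e2$times, e$times)
  expect_identical(e2$channel_names, e$channel_names)
  expect_identical(e2$subject_id, e$subject_id)
  expect_equal(e2$sfreq, e$sfreq)
  expect_identical(as.data.frame(e2$trials), as.data.frame(e$trials))
})

test_that("containers violating the shape invariants are rejected with named diagnostics", {
  e <- make_epochs(n_trials = 4, n_channels = 3, times = seq(0, 40, 10))
  path <- withr::local_tempfile(fileext = ".h5")
  write_epochs(e, path)

  # trials table longer than the data's trial axis
  bad <- as.data.frame(make_trials(5))
  bad$keep <- as.integer(bad$keep)
  rhdf5::h5delete(path, "trials")
  rhdf5::h5write(bad, path, "trials")
  rhdf5::h5closeAll()
  expect_error(read_epochs(path), "5 rows but data has 4 trials")

  # missing dataset
  path2 <- withr::local_tempfile(fileext = ".h5")
  write_epochs(e, path2)
  rhdf5::h5delete(path2, "times")
  rhdf5::h5closeAll()
  expect_error(read_epochs(path2), "missing dataset /times")
})

test_that("epoch_set construction enforces axis, finiteness and trial invariants", {
  tm <- seq(0, 40, 10)
  dat <- array(0, c(2, 3, 5))
  tt <- make_trials(2)
  expect_s3_class(epoch_set("s", dat, tm, letters[1:3], 100, tt), "epoch_set")
  # non-uniform times
  expect_error(epoch_set("s", dat, c(0, 10, 20, 35, 40), letters[1:3], 100, tt),
               "uniformly spaced")
  # times inconsistent with sfreq
  expect_error(epoch_set("s", dat, tm, letters[1:3], 250, tt),
               "inconsistent with")
  # non-finite amplitude
  dat2 <- dat; dat2[2, 1, 3] <- NaN
  expect_error(epoch_set("s", dat2, tm, letters[1:3], 100, tt),
               "non-finite amplitude at trial 2, channel 1, timepoint 3")
  # zero trials
  expect_error(epoch_set("s", array(0, c(0, 3, 5)), tm, letters[1:3], 100,
                         make_trials(2)[0, ]),
               "at least one trial")
  # unknown condition
  expect_error(trial_table(1:2, c("a", "b"), c("x", "y"),
                           c("congruent", "weird")),
               "unknown condition 'weird'")
  # duplicate trial ids
  expect_error(trial_table(c(1, 1), c("a", "b"), c("x", "y"),
                           c("congruent", "congruent")),
               "unique")
})

test_that("a container emulating the full study design yields 221 timepoints", {
  e <- make_epochs(n_trials = 8, n_channels = 4, times = seq(-200, 900, 5),
                   trials = make_trials(8))
  expect_length(e$times, 221)
  path <- withr::local_tempfile(fileext = ".h5")
  write_epochs(e, path)
  expect_length(read_epochs(path)$times, 221)
})

test_that("trial table TSV round-trips", {
  tt <- make_trials(5)
  tt$keep[4] <- FALSE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tt, path)
  expect_identical(as.data.frame(read_trial_table(path)), as.data.frame(tt))
})

test_that("baseline correction zeroes the window mean and preserves post-stimulus structure", {
  tm <- seq(-200, 200, 50)
  tt <- make_trials(2)
  # constant trace cancels entirely
  e <- epoch_set("s", array(5, c(2, 3, length(tm))), tm, letters[1:3],
                 sfreq = 20, tt)
  b <- baseline_correct(e, -200, 0)
  expect_equal(max(abs(b$data)), 0)

  # a post-stimulus bump on top of a flat baseline is preserved exactly
  bump <- c(rep(0, 5), 1, 3, 2, 0)
  dat <- array(rep(7 + bump, each = 6), c(2, 3, length(tm)))
  e2 <- epoch_set("s", dat, tm, letters[1:3], sfreq = 20, tt)
  b2 <- baseline_correct(e2, -200, 0)
  expect_equal(b2$data[1, 1, ], bump)
  # corrected baseline mean is 0 within tolerance
  expect_lt(max(abs(apply(b2$data[, , 1:5, drop = FALSE], 1:2, mean))), 1e-9)
  # idempotence
  b3 <- baseline_correct(b2, -200, 0)
  expect_equal(b3$data, b2$data, tolerance = 1e-9)

  expect_error(baseline_correct(e2, 500, 400), "empty window")
  expect_error(baseline_correct(e2, 300, 400), "no grid timepoints")
})

test_that("noisy-trial rejection flags exactly the trials the direct computation flags", {
  e <- make_epochs(n_trials = 10, n_channels = 4, seed = 5)
  e$data[7, , ] <- e$data[7, , ] * 10   # one spiking trial
  flagged <- suppressMessages(reject_noisy_trials(e, ptp_threshold_uv = 15,
                                                  zvar_threshold = 4))

  # oracle: recompute both rules directly
  ptp <- vapply(1:10, function(i) {
    max(apply(e$data[i, , ], 1, function(ch) max(ch) - min(ch)))
  }, numeric(1))
  lv <- log(vapply(1:10, function(i) var(as.vector(e$data[i, , ])),
                   numeric(1)))
  z <- (lv - mean(lv)) / sd(lv)
  expect_bad <- ptp > 15 | z > 4
  expect_true(expect_bad[7])
  expect_identical(flagged$trials$keep, !expect_bad)
  # amplitudes untouched
  expect_identical(flagged$data, e$data)
})

test_that("noisy-trial rejection is quiet on homogeneous data and errors when everything is rejected", {
  # all-identical clean trials: nothing flagged
  tm <- seq(0, 40, 10)
  dat <- array(rep(sin(seq_len(5)), each = 12), c(4, 3, 5))
  e <- epoch_set("s", dat, tm, letters[1:3], 100, make_trials(4))
  kept <- suppressMessages(reject_noisy_trials(e, 200, 4))
  expect_true(all(kept$trials$keep))

  # degenerate threshold rejects everything -> analysis impossible
  e2 <- make_epochs(n_trials = 4, n_channels = 3, times = tm)
  expect_error(reject_noisy_trials(e2, ptp_threshold_uv = 0.001,
                                   zvar_threshold = 4),
               "all 4 trials rejected")
})
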