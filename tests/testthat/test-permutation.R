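# rho matrices with a planted positive window, for exercising the
# permutation machinery
planted_rhos <- function(n_subj, n_time, window, effect = 0.3, sd = 0.1,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_subj * n_time, sd = sd), n_subj, n_time)
  m[, window] <- m[, window] + effect
  attr(m, "times") <- seq(0, by = 10, length.out = n_time)
  m
}

test_that("permutation p-values respect the +1 floor, determinism and mass monotonicity", {
  rhos <- planted_rhos(12, 30, 10:18, effect = 0.5, sd = 0.05)
  fit <- signflip_cluster_test(rhos, alpha = 0.01, n_perm = 500, seed = 7)
  expect_gt(nrow(fit$clusters), 0)
  expect_true(all(fit$clusters$p_value >= 1 / 501))
  expect_true(all(fit$clusters$p_value <= 1))

  # overwhelming effect: observed mass above every permutation maximum
  big <- fit$clusters[which.max(abs(fit$clusters$mass)), ]
  if (abs(big$mass) > max(fit$perm_max)) {
    expect_equal(big$p_value, 1 / 501)
  }

  # same seed, same everything
  fit2 <- signflip_cluster_test(rhos, alpha = 0.01, n_perm = 500, seed = 7)
  expect_identical(fit$clusters, fit2$clusters)
  expect_identical(fit$perm_max, fit2$perm_max)

  # within one test, a larger |mass| never has a larger p
  rhos2 <- planted_rhos(12, 60, c(5:12, 35:55), effect = 0.25, sd = 0.15,
                        seed = 3)
  fit3 <- signflip_cluster_test(rhos2, alpha = 0.05, n_perm = 300, seed = 9)
  cl <- fit3$clusters
  if (nrow(cl) >= 2) {
    o <- order(abs(cl$mass), decreasing = TRUE)
    expect_true(all(diff(cl$p_value[o]) >= 0))
  }
})

test_that("reported clusters are suprathreshold runs of common sign within the axis", {
  rhos <- planted_rhos(10, 40, 8:20, effect = 0.3, sd = 0.2, seed = 5)
  fit <- signflip_cluster_test(rhos, alpha = 0.05, n_perm = 200, seed = 1)
  for (k in seq_len(nrow(fit$clusters))) {
    idx <- fit$clusters$start_idx[k]:fit$clusters$end_idx[k]
    tv <- fit$t[idx]
    expect_true(all(abs(tv) > fit$threshold))
    expect_true(all(sign(tv) == sign(fit$clusters$mass[k])))
    expect_true(fit$clusters$start_time[k] >= fit$times[1])
    expect_true(fit$clusters$end_time[k] <= fit$times[length(fit$times)])
  }
})

test_that("the permutation distribution is invariant to globally negating all subjects", {
  rhos <- planted_rhos(8, 25, 5:12, effect = 0.4, sd = 0.1, seed = 11)
  fit_pos <- signflip_cluster_test(rhos, alpha = 0.01, n_perm = 400, seed = 13)
  fit_neg <- signflip_cluster_test(-rhos, alpha = 0.01, n_perm = 400, seed = 13)
  expect_equal(fit_neg$perm_max, fit_pos$perm_max)
  expect_equal(fit_neg$clusters$mass, -fit_pos$clusters$mass)
  expect_equal(fit_neg$clusters$p_value, fit_pos$clusters$p_value)
})

test_that("Monte-Carlo p-values agree with exhaustive sign-flip enumeration (n = 10)", {
  rhos <- planted_rhos(10, 20, 6:12, effect = 0.35, sd = 0.25, seed = 17)
  fit <- signflip_cluster_test(rhos, alpha = 0.05, n_perm = 4000, seed = 19)
  expect_gt(nrow(fit$clusters), 0)

  thr <- qt(1 - 0.05 / 2, 9)
  all_max <- bf_exhaustive_max_masses(rhos, thr)   # all 2^10 sign patterns
  for (k in seq_len(nrow(fit$clusters))) {
    p_ex <- mean(all_max >= abs(fit$clusters$mass[k]))
    se <- sqrt(p_ex * (1 - p_ex) / fit$n_perm)
    expect_lt(abs(fit$clusters$p_value[k] - p_ex), 3 * se + 2 / fit$n_perm)
  }
})

test_that("the paired test is bit-identical to the one-sample test on differences", {
  a <- planted_rhos(9, 30, 10:20, effect = 0.3, sd = 0.2, seed = 23)
  b <- planted_rhos(9, 30, 10:14, effect = 0.3, sd = 0.2, seed = 29)
  paired <- paired_cluster_test(a, b, alpha = 0.05, n_perm = 300, seed = 31)
  onesmp <- signflip_cluster_test(a - b, times = attr(a, "times"),
                                  alpha = 0.05, n_perm = 300, seed = 31)
  expect_identical(paired$clusters, onesmp$clusters)
  expect_identical(paired$perm_max, onesmp$perm_max)
  expect_identical(paired$type, "paired")

  # identical conditions -> no clusters
  same <- paired_cluster_test(a, a, alpha = 0.05, n_perm = 100, seed = 1)
  expect_equal(nrow(same$clusters), 0L)

  rownames(a) <- paste0("s", 1:9)
  b2 <- b; rownames(b2) <- paste0("x", 1:9)
  expect_error(paired_cluster_test(a, b2, seed = 1), "different subjects")
})

test_that("time-course correlation matches the closed-form t-distribution p-value", {
  x <- c(0.1, 0.3, 0.2, 0.6, 0.4, 0.8, 0.5)
  expect_equal(timecourse_correlation(x, x)$r, 1)
  expect_equal(timecourse_correlation(x, -x + 2)$r, -1)

  set.seed(47)
  y <- 0.5 * x + rnorm(7, sd = 0.2)
  got <- timecourse_correlation(x, y)
  r <- bf_pearson(x, y)
  tstat <- r * sqrt((7 - 2) / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tstat), 7 - 2), tolerance = 1e-12)

  # windowing on a time axis
  times <- seq(-100, 500, 100)
  got2 <- timecourse_correlation(x, y, times = times, window = c(0, 300))
  expect_equal(got2$n, 4)
  expect_equal(got2$r, bf_pearson(x[2:5], y[2:5]))

  expect_error(timecourse_correlation(x, rep(1, 7)), "constant time course")
})

test_that("fitted-test methods expose coefficients, summaries and plots", {
  rhos <- planted_rhos(8, 25, 5:12, effect = 0.4, sd = 0.1, seed = 11)
  fit <- signflip_cluster_test(rhos, alpha = 0.01, n_perm = 100, seed = 13)
  expect_equal(unname(coef(fit)), colMeans(rhos))
  expect_output(print(fit), "sign-flip cluster-mass")
  tab <- summary(fit)
  expect_s3_class(tab, "data.frame")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
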