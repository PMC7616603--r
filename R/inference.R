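#' Spearman correlation between two RDMs
#'
#' Correlates the strictly-lower-triangle vectorisations (diagonal
#' excluded) of two RDMs sharing labels in identical order, using average
#' ranks for ties — the standard model-to-neural comparison statistic.
#'
#' @param rdm_a,rdm_b `rdm` objects with identical labels in identical
#'   order and at least 3 item pairs.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(rdm_a, rdm_b) {
  if (!identical(rdm_a$labels, rdm_b$labels)) {
    stop_scenersa("RDM labels differ or are ordered differently",
                  class = "scenersa_rdm_error")
  }
  a <- lower_triangle(rdm_a)
  b <- lower_triangle(rdm_b)
  if (length(a) < 3L) {
    stop_scenersa("need at least 3 item pairs for Spearman correlation",
                  class = "scenersa_rdm_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_scenersa("RDM with constant dissimilarities: Spearman undefined",
                  class = "scenersa_rdm_error")
  }
  stats::cor(a, b, method = "spearman")
}

#' RSA time series: model fit at every timepoint
#'
#' Spearman-correlates a model RDM with the neural RDM at each timepoint.
#' When the model covers a subset of the neural series' trials (as for
#' per-condition semantic models), the series is subset to the model's
#' labels automatically.
#'
#' @param series an `rdm_series` of neural RDMs.
#' @param model an `rdm`; labels must be a subset of the series labels.
#' @param subject_id optional subject identifier carried into the result.
#' @return object of class `rsa_timeseries`: list with `subject_id`,
#'   `times` and `rho` (one Spearman correlation per timepoint).
#' @export
rsa_timeseries <- function(series, model, subject_id = NA_character_) {
  if (!identical(model$labels, series$labels)) {
    series <- subset_rdm_series(series, model$labels)
  }
  tri <- series_triangles(series)            # pairs x time
  if (nrow(tri) < 3L) {
    stop_scenersa("need at least 3 item pairs for Spearman correlation",
                  class = "scenersa_rdm_error")
  }
  mv <- lower_triangle(model)
  if (stats::sd(mv) == 0) {
    stop_scenersa("model RDM has constant dissimilarities: Spearman undefined",
                  class = "scenersa_rdm_error")
  }
  csd <- apply(tri, 2L, stats::sd)
  if (any(csd == 0)) {
    stop_scenersa("neural RDM has constant dissimilarities at timepoint ",
                  series$times[which(csd == 0)[1L]], " ms",
                  class = "scenersa_rdm_error")
  }
  rm <- rank(mv)
  rt <- apply(tri, 2L, rank)
  rho <- as.vector(stats::cor(rm, rt))
  structure(list(subject_id = subject_id, times = series$times, rho = rho),
            class = "rsa_timeseries")
}

#' @export
print.rsa_timeseries <- function(x, ...) {
  cat(sprintf("<rsa_timeseries> subject %s, %d timepoints, rho in [%.3f, %.3f]\n",
              x$subject_id, length(x$times), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Stack per-subject RSA time series into a subject x time matrix
#' @param fits list of `rsa_timeseries` sharing one time axis.
#' @return numeric matrix with subject ids as row names and an attribute
#'   `times`.
#' @export
stack_rsa <- function(fits) {
  stopifnot(length(fits) >= 1L)
  times <- fits[[1L]]$times
  for (f in fits) {
    if (!isTRUE(all.equal(f$times, times))) {
      stop_scenersa("subjects have different time axes",
                    class = "scenersa_axis_error")
    }
  }
  m <- do.call(rbind, lapply(fits, `[[`, "rho"))
  rownames(m) <- vapply(fits, `[[`, character(1L), "subject_id")
  attr(m, "times") <- times
  m
}

#' One-sample group t statistics per timepoint
#'
#' `t = mean / (sd / sqrt(n))` across subjects at each timepoint, sd with
#' the n-1 denominator. A timepoint with zero between-subject variance
#' yields +/-Inf (sign of the mean; 0 when the mean is also 0), which any
#' finite cluster-forming threshold treats as suprathreshold.
#'
#' @param rhos subject x time matrix without missing values, >= 3 subjects.
#' @return numeric vector of t values, one per timepoint.
#' @export
group_tvalues <- function(rhos) {
  rhos <- as.matrix(rhos)
  n <- nrow(rhos)
  if (n < 3L) {
    stop_scenersa("need >= 3 subjects for a random-effects t-test",
                  class = "scenersa_inference_error")
  }
  if (anyNA(rhos)) {
    stop_scenersa("missing values in the subject x time matrix",
                  class = "scenersa_inference_error")
  }
  m <- colMeans(rhos)
  s <- sqrt((colSums(rhos^2) - n * m^2) / (n - 1))
  s[s < 0] <- 0  # guard tiny negative from cancellation
  t <- ifelse(s > 0, m / (s / sqrt(n)), sign(m) * Inf)
  t[s == 0 & m == 0] <- 0
  t
}

#' Find suprathreshold clusters in a t time series
#'
#' Contiguous runs of timepoints exceeding the cluster-forming threshold
#' (two-tailed critical t at `alpha`, or one-tailed positive when
#' `tail = "pos"`), split wherever the sign of t changes. Cluster mass is
#' the sum of t within the run (signed).
#'
#' @param t numeric vector of t values.
#' @param df degrees of freedom (subjects - 1).
#' @param alpha cluster-forming alpha in (0, 1).
#' @param tail `"two"` (default) or `"pos"`.
#' @return data.frame with columns start_idx, end_idx, mass (0 rows when no
#'   point is suprathreshold); p_value left unset here.
#' @export
find_clusters <- function(t, df, alpha = 0.01, tail = c("two", "pos")) {
  tail <- match.arg(tail)
  stopifnot(alpha > 0, alpha < 1)
  thr <- cluster_threshold(df, alpha, tail)
  s <- integer(length(t))
  if (tail == "two") {
    supra <- abs(t) > thr
    s[supra] <- sign(t[supra])
  } else {
    s[t > thr] <- 1L
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  use <- r$values != 0L
  out <- data.frame(start_idx = starts[use], end_idx = ends[use])
  out$mass <- vapply(seq_len(nrow(out)), function(k) {
    sum(t[out$start_idx[k]:out$end_idx[k]])
  }, numeric(1L))
  out
}

cluster_threshold <- function(df, alpha, tail) {
  if (tail == "two") stats::qt(1 - alpha / 2, df) else stats::qt(1 - alpha, df)
}

# max |cluster mass| of one permuted t series (0 when no cluster); inlined
# hot loop of the permutation test
perm_max_mass <- function(t, thr, tail) {
  s <- integer(length(t))
  if (tail == "two") {
    supra <- abs(t) > thr
    s[supra] <- sign(t[supra])
  } else {
    s[t > thr] <- 1L
  }
  if (!any(s != 0L)) return(0)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  use <- which(r$values != 0L)
  mx <- 0
  for (k in use) {
    m <- abs(sum(t[starts[k]:ends[k]]))
    if (m > mx) mx <- m
  }
  mx
}

#' Sign-flip cluster-mass permutation test on RSA time series
#'
#' The group-level random-effects test: per-timepoint one-sample t tests
#' against zero are thresholded at the cluster-forming alpha, contiguous
#' suprathreshold runs of common sign form clusters whose mass is the sum
#' of t values, and family-wise-corrected p values come from a sign-flip
#' permutation distribution. On each permutation an independent random +/-1
#' multiplies each subject's whole time series, t tests are recomputed, and
#' the maximum absolute cluster mass enters the reference distribution (0
#' when a permutation yields no cluster). Each observed cluster's p value
#' is the proportion of the `n_perm` permutation maxima, plus the observed
#' cluster itself, at or above the observed absolute mass:
#' `p = (count + 1) / (n_perm + 1)`.
#'
#' @param rhos subject x time matrix of per-subject model fits (e.g. from
#'   [stack_rsa()]); an attribute or argument `times` supplies the axis.
#' @param times numeric time axis in ms (default: `attr(rhos, "times")`).
#' @param alpha cluster-forming alpha (default 0.01, two-tailed).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed; required for a reproducible report.
#' @param tail `"two"` (default) or `"pos"` for a one-tailed positive
#'   cluster-forming threshold.
#' @return object of class `rsa_cluster_test`; see [print.rsa_cluster_test()].
#' @export
signflip_cluster_test <- function(rhos, times = attr(rhos, "times"),
                                  alpha = 0.01, n_perm = 10000, seed,
                                  tail = c("two", "pos")) {
  tail <- match.arg(tail)
  rhos <- as.matrix(rhos)
  n <- nrow(rhos)
  nt <- ncol(rhos)
  if (missing(seed) || !is_scalar_number(seed)) {
    stop_scenersa("a single integer seed is required",
                  class = "scenersa_config_error")
  }
  if (!is_scalar_number(n_perm) || n_perm < 1) {
    stop_scenersa("n_perm must be a positive integer",
                  class = "scenersa_config_error")
  }
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(times)) times <- seq_len(nt)
  stopifnot(length(times) == nt)

  tobs <- group_tvalues(rhos)
  df <- n - 1L
  thr <- cluster_threshold(df, alpha, tail)
  clusters <- find_clusters(tobs, df, alpha, tail)

  signs <- with_seed(seed,
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            nrow = n_perm, ncol = n))
  meansq <- colMeans(rhos^2)
  mp <- (signs %*% rhos) / n                         # n_perm x time means
  varp <- sweep(-mp^2, 2L, meansq, "+") * n / (df)   # sample variance
  varp[varp < 0] <- 0
  tp <- mp / sqrt(varp / n)
  tp[varp == 0] <- sign(mp[varp == 0]) * Inf
  tp[varp == 0 & mp == 0] <- 0
  perm_max <- vapply(seq_len(n_perm), function(i) {
    perm_max_mass(tp[i, ], thr, tail)
  }, numeric(1L))

  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$mass, function(m) {
      (sum(perm_max >= abs(m)) + 1) / (n_perm + 1)
    }, numeric(1L))
    clusters$start_time <- times[clusters$start_idx]
    clusters$end_time <- times[clusters$end_idx]
    clusters <- clusters[order(clusters$start_idx),
                         c("start_time", "end_time", "start_idx", "end_idx",
                           "mass", "p_value")]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(start_time = numeric(0), end_time = numeric(0),
                           start_idx = integer(0), end_idx = integer(0),
                           mass = numeric(0), p_value = numeric(0))
  }

  structure(list(times = times, rho = rhos, t = tobs, df = df,
                 alpha = alpha, tail = tail, threshold = thr,
                 clusters = clusters, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), perm_max = perm_max,
                 type = "one-sample"),
            class = "rsa_cluster_test")
}

#' Paired cluster-mass permutation test
#'
#' Tests the per-timepoint difference between two conditions measured in
#' the same subjects by applying the sign-flip machinery to the per-subject
#' difference time series — per-timepoint paired t tests with sign-flip
#' cluster-mass correction. Bit-identical to
#' `signflip_cluster_test(rhos_a - rhos_b, ...)` at the same seed.
#'
#' @param rhos_a,rhos_b subject x time matrices with identical dimensions
#'   and subject order (row names checked when present).
#' @inheritParams signflip_cluster_test
#' @return an `rsa_cluster_test` with `type = "paired"`.
#' @export
paired_cluster_test <- function(rhos_a, rhos_b,
                                times = attr(rhos_a, "times"),
                                alpha = 0.01, n_perm = 10000, seed,
                                tail = c("two", "pos")) {
  rhos_a <- as.matrix(rhos_a)
  rhos_b <- as.matrix(rhos_b)
  if (!identical(dim(rhos_a), dim(rhos_b))) {
    stop_scenersa("condition matrices have different dimensions",
                  class = "scenersa_inference_error")
  }
  if (!is.null(rownames(rhos_a)) && !is.null(rownames(rhos_b)) &&
      !identical(rownames(rhos_a), rownames(rhos_b))) {
    stop_scenersa("condition matrices have different subjects or order",
                  class = "scenersa_inference_error")
  }
  fit <- signflip_cluster_test(rhos_a - rhos_b, times = times, alpha = alpha,
                               n_perm = n_perm, seed = seed, tail = tail)
  fit$type <- "paired"
  fit
}

#' Pearson correlation between two model-fit time courses
#'
#' Correlates two time-indexed curves (e.g. the group-mean congruency model
#' fit and the group-mean difference in semantic model fit) over the full
#' axis or a closed ms window, with the two-tailed p value from the t
#' distribution with n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @param times time axis in ms; required when `window` is given.
#' @param window optional `c(start_ms, end_ms)` closed window.
#' @return list with `r`, `p`, `n` (timepoints used) and `window`.
#' @export
timecourse_correlation <- function(x, y, times = NULL, window = NULL) {
  stopifnot(length(x) == length(y))
  sel <- seq_along(x)
  if (!is.null(window)) {
    if (is.null(times)) {
      stop_scenersa("a time axis is required to apply a window",
                    class = "scenersa_config_error")
    }
    sel <- window_idx(times, window[1L], window[2L])
  }
  if (length(sel) < 3L) {
    stop_scenersa("need at least 3 timepoints for a correlation",
                  class = "scenersa_inference_error")
  }
  if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) {
    stop_scenersa("constant time course: correlation undefined",
                  class = "scenersa_inference_error")
  }
  ct <- stats::cor.test(x[sel], y[sel])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(sel),
       window = window)
}
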