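# Independent brute-force reference implementations used to check the
# package's vectorised code paths. Deliberately naive: explicit loops and
# textbook formulas only.

bf_pearson <- function(p, q) {
  mp <- mean(p); mq <- mean(q)
  sum((p - mp) * (q - mq)) /
    sqrt(sum((p - mp)^2) * sum((q - mq)^2))
}

bf_correlation_distance <- function(p, q) 1 - bf_pearson(p, q)

bf_cosine_distance <- function(u, v) {
  1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

bf_euclidean <- function(a, b) sqrt(sum((a - b)^2))

# average ranks with explicit tie handling
bf_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bf_spearman <- function(a, b) bf_pearson(bf_rank(a), bf_rank(b))

# one-sample t per column, textbook formula
bf_tvalues <- function(m) {
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    mean(x) / (sd(x) / sqrt(n))
  }, numeric(1))
}

# clusters: contiguous |t| > thr runs split on sign change; list of
# (indices, mass)
bf_clusters <- function(t, thr) {
  out <- list()
  cur <- integer(0)
  cur_sign <- 0
  flush <- function() {
    if (length(cur)) out[[length(out) + 1]] <<- list(idx = cur,
                                                    mass = sum(t[cur]))
    cur <<- integer(0)
    cur_sign <<- 0
  }
  for (i in seq_along(t)) {
    if (abs(t[i]) > thr) {
      s <- sign(t[i])
      if (length(cur) && s != cur_sign) flush()
      cur <- c(cur, i)
      cur_sign <- s
    } else {
      flush()
    }
  }
  flush()
  out
}

bf_max_cluster_mass <- function(t, thr) {
  cl <- bf_clusters(t, thr)
  if (!length(cl)) return(0)
  max(vapply(cl, function(c) abs(c$mass), numeric(1)))
}

# exhaustive sign-flip reference distribution for small n: max |cluster
# mass| for every one of the 2^n sign patterns
bf_exhaustive_max_masses <- function(rhos, thr) {
  n <- nrow(rhos)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  apply(patterns, 1, function(s) {
    bf_max_cluster_mass(bf_tvalues(s * rhos), thr)
  })
}
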