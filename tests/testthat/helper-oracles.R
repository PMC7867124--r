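# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

# Pincus ApEn: direct template counting, self-matches included.
apen_oracle <- function(x, m, r) {
  phi <- function(m) {
    n <- length(x)
    nv <- n - m + 1
    logs <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nv)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Correlation sums over all embedded pairs, Euclidean distance.
corr_sums_oracle <- function(x, emb_dim, delay, radii) {
  np <- length(x) - (emb_dim - 1) * delay
  emb <- sapply(seq_len(emb_dim), function(k) x[(seq_len(np)) + (k - 1) * delay])
  d <- as.matrix(dist(emb))
  pairs <- d[upper.tri(d)]
  vapply(radii, function(r) mean(pairs <= r), numeric(1))
}

# Hampel filter with truncated centered windows.
hampel_oracle <- function(x, window, n_mad) {
  h <- (window - 1) / 2
  y <- x
  for (i in seq_along(x)) {
    win <- x[max(1, i - h):min(length(x), i + h)]
    med <- median(win)
    mad_w <- 1.4826 * median(abs(win - med))
    if (abs(x[i] - med) > n_mad * mad_w) y[i] <- med
  }
  y
}

# Textbook one-way ANOVA F from explicit sums of squares.
anova_F_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  k <- nlevels(groups)
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(values, groups, function(g) sum((g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Exhaustive-distance KNN with majority vote (no standardization).
knn_oracle <- function(train_x, train_y, query, k) {
  d <- apply(train_x, 1, function(row) sqrt(sum((row - query)^2)))
  nn <- order(d)[seq_len(k)]
  votes <- table(train_y[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) top else train_y[nn[train_y[nn] %in% top][1]]
}

# Small, fast synthetic cohort for structural tests.
tiny_cohort_spec <- function(seed = 42, duration_s = 8,
                             n_healthy = 2, n_tremor = 2,
                             n_bradykinesia = 2) {
  cohort_spec(n_healthy = n_healthy, n_tremor = n_tremor,
              n_bradykinesia = n_bradykinesia, duration_s = duration_s,
              seed = seed)
}

# Welch band power of one channel of a (raw or filtered) recording.
rec_band_power <- function(rec, channel, lo, hi, segment = 256) {
  est <- welch_psd(rec[[channel]], attr(rec, "sampling_rate_hz"),
                   segment_length = min(segment, nrow(rec)))
  sel <- est$frequency >= lo & est$frequency <= hi
  sum(diff(est$frequency[sel]) *
        (head(est$psd[sel], -1) + est$psd[sel][-1]) / 2)
}
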