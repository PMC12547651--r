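# Independent oracles and fixture builders shared across the suite.
# Every oracle is a direct, naive transcription of the defining formula,
# kept independent of the package's vectorised implementations.

# Naive per-spike evaluation of the adaptive-coincidence synchronization.
sync_oracle <- function(a, b, w) {
  a <- sort(a[a >= w[1] & a < w[2]])
  b <- sort(b[b >= w[1] & b < w[2]])
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  isis <- function(x) {
    n <- length(x)
    list(prev = c(x[1] - w[1], if (n > 1) diff(x)),
         nxt = c(if (n > 1) diff(x), w[2] - x[n]))
  }
  ia <- isis(a)
  ib <- isis(b)
  count <- 0
  for (i in seq_along(a)) {
    j <- which.min(abs(a[i] - b))
    tau <- 0.5 * min(ia$prev[i], ia$nxt[i], ib$prev[j], ib$nxt[j])
    if (abs(a[i] - b[j]) < tau) count <- count + 1
  }
  for (j in seq_along(b)) {
    i <- which.min(abs(b[j] - a))
    tau <- 0.5 * min(ib$prev[j], ib$nxt[j], ia$prev[i], ia$nxt[i])
    if (abs(b[j] - a[i]) < tau) count <- count + 1
  }
  count / (length(a) + length(b))
}

# Direct O(n) summation of the Gaussian-kernel density estimate.
kde_oracle <- function(x, samples, h) {
  n <- length(samples)
  vapply(x, function(xx) {
    sum(exp(-((xx - samples) / h)^2 / 2) / sqrt(2 * pi)) / (n * h)
  }, numeric(1))
}

# Pairwise-concordance AUC: every (positive, negative) pair, ties one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exact Mann-Whitney p by full enumeration of all choose(n1+n2, n1)
# assignments of the pooled (tie-free) values to group a.
mw_exact_oracle <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

# Kruskal-Wallis H from the rank-sum formula (no ties assumed).
kw_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  offsets <- cumsum(c(0, head(lengths(groups), -1)))
  h <- 0
  for (g in seq_along(groups)) {
    idx <- offsets[g] + seq_len(lengths(groups)[g])
    h <- h + sum(r[idx])^2 / lengths(groups)[g]
  }
  unname(12 / (n * (n + 1)) * h - 3 * (n + 1))
}

# Small labeled feature table with two well-separated classes, grouped into
# wells, for classifier tests.
make_blobs <- function(n_per_class = 50, n_wells = 8, shift = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  tibble::tibble(
    well_id = sample(rep_len(sprintf("W%02d", seq_len(n_wells)), n)),
    unit_id = sprintf("u%03d", seq_len(n)),
    mfr_hz = c(rnorm(n_per_class, 1), rnorm(n_per_class, 1 + shift)),
    isicv = c(rnorm(n_per_class, 1, 0.3), rnorm(n_per_class, 1 + shift, 0.3)),
    sync_median = runif(n, 0, 1),
    sync_skewness = rnorm(n),
    label = rep(c("non-nociceptor", "nociceptor"), each = n_per_class)
  )
}

# Tiny deterministic session: a few hand-placed units in one or two wells.
make_session <- function(units, condition = "treated",
                         baseline = c(0, 300), treatment = c(300, 600)) {
  spikes <- purrr::imap_dfr(units, function(ts, nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    tibble::tibble(well_id = parts[1], unit_id = parts[2], timestamp_s = ts)
  })
  mea_session(spikes, condition, baseline, treatment)
}

# Regular (periodic) train covering [t0, t1) at the given rate.
periodic_train <- function(rate, t0 = 0, t1 = 300, phase = 0.5) {
  seq(t0 + phase / rate, t1 - 1e-9, by = 1 / rate)
}
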