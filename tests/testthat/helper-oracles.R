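# Independent brute-force oracles used to validate the package's
# implementations on small instances.  Deliberately naive and written
# against the definitions, not the package code paths.

# AUPRC by direct enumeration of all distinct score thresholds: classify
# score >= threshold as positive, collect (recall, precision) points in
# increasing recall order, and accumulate the step integral.
auprc_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels)
  rec <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp <- sum(pred & labels == 1)
    rec[i] <- tp / npos
    prec[i] <- tp / sum(pred)
  }
  sum(diff(c(0, rec)) * prec)
}

# AUROC by exhaustive pair counting, ties worth 1/2.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact expectation of the tie-grouped step AUPRC (average precision) of a
# random ranking: sum over the joint law of (position r, true-positive
# count k at r) of k/r, positives placed uniformly without replacement.
exact_random_auprc <- function(n, K) {
  E <- 0
  for (r in seq_len(n)) {
    ks <- max(1, K - (n - r)):min(K, r)
    lp <- lchoose(r - 1, ks - 1) + lchoose(n - r, K - ks) - lchoose(n, K)
    E <- E + sum(ks / r * exp(lp))
  }
  E / K
}

# Ward agglomeration on Manhattan distances by direct Lance-Williams
# recursion over the full distance matrix: at each step merge the pair
# with the smallest current dissimilarity and update the others.
ward_merge_heights <- function(x) {
  d <- as.matrix(dist(x, method = "manhattan"))
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bestd
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        ((size[i] + size[k]) * d[i, k] + (size[j] + size[k]) * d[j, k] -
           size[k] * bestd) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# Log-rank observed-minus-expected and variance accumulated event time by
# event time, straight from the definition.
logrank_oracle <- function(time, status, arm) {
  ev_times <- sort(unique(time[status == 1]))
  OE <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & arm == 1)
    n0 <- sum(at_risk & arm == 0)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & arm == 1)
    N <- n1 + n0
    OE <- OE + d1 - d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (n0 / N) * (N - d) / (N - 1)
  }
  OE^2 / V
}

# Small helper: a single-trial cohort config for focused tests.
one_trial_config <- function(n, rate, seed, ...) {
  cohort_config(trial_specs = data.frame(trial = "T1", n = n, rate = rate),
                seed = seed, ...)
}
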