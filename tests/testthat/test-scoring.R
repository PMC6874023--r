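test_that("tie-grouped PR curve matches hand examples and rejects degenerate input", {
  pr <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(pr$auprc, (1 + 2 / 3) / 2)
  expect_equal(pr$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3, 1 / 2))

  # perfect separation
  y <- c(1, 1, 0, 0, 0)
  expect_equal(auprc(y, y), 1)
  # all scores tied: single threshold, precision = prevalence at recall 1
  expect_equal(auprc(rep(3.2, 10), c(1, rep(0, 9))), 0.1)
  pr_tied <- pr_curve(rep(1, 4), c(1, 0, 1, 0))
  expect_equal(length(pr_tied$recall), 1L)
  expect_equal(pr_tied$precision, 0.5)

  expect_error(pr_curve(1:3, c(0, 0, 0)), "no positive")
  expect_error(pr_curve(1:3, c(1, 0)), "equal length")
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUPRC and AUROC agree with brute-force enumeration on all small instances", {
  set.seed(41)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    # coarse score support forces frequent ties
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(auprc(scores, labels), auprc_oracle(scores, labels))
    if (any(labels == 0))
      expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
  }
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(1, 6), c(1, 1, 0, 0, 0, 0)), 0.5)
  expect_equal(auroc(c(5, 4, 1, 2), c(1, 1, 0, 0)), 1)
})

test_that("random-model null mean matches the exact combinatorial expectation", {
  n <- 200L
  reps <- 400L
  for (K in c(10L, 50L, 100L)) {
    nd <- random_null(n, K, replicates = reps, seed = 11 + K)
    expect_equal(nd$replicates, reps)
    expect_true(all(nd$auprc_samples > 0 & nd$auprc_samples <= 1))
    E <- exact_random_auprc(n, K)
    mc_band <- 3 * sd(nd$auprc_samples) / sqrt(reps)
    expect_lt(abs(nd$mean_auprc - E), mc_band)
    # the expectation tracks the prevalence level (small upward bias)
    expect_lt(abs(nd$mean_auprc - K / n), 0.05)
  }
  expect_error(random_null(100, 0, 10), "n_positives")
  # determinism under seed
  expect_identical(random_null(50, 5, 3, seed = 9)$auprc_samples,
                   random_null(50, 5, 3, seed = 9)$auprc_samples)
})

test_that("empirical p-values follow the add-one rule", {
  null <- list(auprc_samples = seq(0.001, 0.999, length.out = 999))
  class(null) <- "null_dist"
  expect_equal(empirical_pvalue(1.0, null), 1 / 1000)
  expect_equal(empirical_pvalue(0.0005, null), 1)
  # observed at the null median of an odd-length null
  expect_equal(empirical_pvalue(null$auprc_samples[500], null), 501 / 1000)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bootstrap Bayes factors: self-comparison, reciprocity, and separation", {
  set.seed(7)
  y <- rbinom(40, 1, 0.4)
  y[1:2] <- c(1, 0)
  a <- runif(40)
  expect_equal(bayes_factor(a, a, y), 1)
  expect_equal(bayes_factor(a, exp(3 * a), y), 1)  # same ranking

  b <- runif(40)
  f_ab <- bayes_factor(a, b, y, replicates = 400, seed = 3)
  f_ba <- bayes_factor(b, a, y, replicates = 400, seed = 3)
  # shared resamples: the two ratios are reciprocal when both sides win
  expect_equal(f_ab * f_ba, 1, tolerance = 1e-12)

  # perfect vs anti-perfect: every informative resample favours a
  y2 <- rep(c(1, 0), 20)
  expect_equal(bayes_factor(y2, 1 - y2, y2, replicates = 1000, seed = 5),
               1000)
  expect_error(bayes_factor(a, b, rep(1, 40)), "both")
})

test_that("scoring statistics are invariant to strictly increasing score transforms", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    s <- rnorm(n)
    g <- function(x) exp(2 * x) + 1   # strictly increasing
    expect_equal(auprc(s, y), auprc(g(s), y))
    expect_equal(auroc(s, y), auroc(g(s), y))
    expect_equal(bayes_factor(s, rev(s), y, replicates = 50, seed = i),
                 bayes_factor(g(s), g(rev(s)), y, replicates = 50, seed = i))
  }
})

test_that("leaderboard orders models, bounds p-values, and handles a single model", {
  set.seed(19)
  co <- generate_cohort(one_trial_config(400, 0.15, seed = 3))
  y <- as.integer(co$discontinued_early)
  sm <- generate_team_scores(co, team_profiles(c(0.8, 0.4, 0.0)), seed = 4)
  lb <- rank_teams(sm, y, replicates = 200, null_replicates = 500, seed = 6)
  expect_s3_class(lb, "leaderboard")
  expect_equal(lb$model_id[1], "team_01")
  expect_true(all(diff(lb$auprc) <= 0))
  expect_true(all(lb$p_adjusted >= lb$p_value))
  expect_equal(lb$bayes_factor_vs_top[1], 1)
  expect_true(all(lb$bayes_factor_vs_top >= 0))

  # singleton: top performer iff adjusted p below the cut
  one <- sm[, c("patient_id", "team_01")]
  lb1 <- rank_teams(one, y, replicates = 100, null_replicates = 500, seed = 6)
  expect_equal(nrow(lb1), 1L)
  expect_equal(lb1$top_performer, lb1$p_adjusted < 0.10)
  expect_error(rank_teams(sm[, "patient_id", drop = FALSE], y), "empty")
})

test_that("all-random teams are flagged significant at most at the FDR level", {
  set.seed(23)
  labels <- c(rep(1L, 49), rep(0L, 421))  # held-out composition, 470 patients
  frac <- vapply(1:10, function(r) {
    sm <- matrix(runif(470 * 20), 470,
                 dimnames = list(NULL, sprintf("m%02d", 1:20)))
    lb <- rank_teams(sm, labels, replicates = 50, null_replicates = 400,
                     seed = 100 + r)
    mean(lb$p_adjusted < 0.10)
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("the planted strong tier is recovered as the top-performer set", {
  # 34-team field, 7 strong / 27 weak (generator defaults), large cohort:
  # the flagged set should be exactly the strong tier in >= 90% of runs
  exact <- vapply(1:10, function(rep) {
    co <- generate_cohort(cohort_config(
      trial_specs = data.frame(trial = "VAL", n = 2000L, rate = 0.104),
      seed = 100 + rep))
    sm <- generate_team_scores(co, default_team_profiles(), seed = 200 + rep)
    lb <- rank_teams(sm, as.integer(co$discontinued_early),
                     replicates = 400, null_replicates = 1000,
                     seed = 300 + rep)
    identical(sort(lb$model_id[lb$top_performer]),
              sprintf("team_%02d", 1:7))
  }, logical(1))
  expect_gte(mean(exact), 0.9)
})
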