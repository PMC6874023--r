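test_that("cohort config rejects invalid specifications", {
  expect_error(cohort_config(trial_specs = data.frame(
    trial = "A", n = -5, rate = 0.1)), "positive")
  expect_error(cohort_config(trial_specs = data.frame(
    trial = "A", n = 100, rate = 1.2)), "rates")
  expect_error(cohort_config(death_rate_3mo = -0.1), "death_rate_3mo")
  expect_error(cohort_config(horizon_days = 0), "horizon_days")
  expect_error(cohort_config(beta = 1:3), "length")
})

test_that("printed four-trial structure: 2,070 patients, 1,600/470 split", {
  co <- generate_cohort(cohort_config(seed = 5))
  expect_equal(nrow(co), 2070L)
  expect_equal(as.integer(table(co$trial)[c("ASCENT2", "VENICE", "MAINSAIL",
                                            "ENTHUSE33")]),
               c(476L, 598L, 526L, 470L))
  sp <- split_train_validation(co, "ENTHUSE33")
  expect_equal(nrow(sp$train), 1600L)
  expect_equal(nrow(sp$validation), 470L)
  expect_true(all(sp$validation$trial == "ENTHUSE33"))
  # exhaustive, disjoint partition
  expect_equal(nrow(sp$train) + nrow(sp$validation), nrow(co))
  expect_length(intersect(sp$train$patient_id, sp$validation$patient_id), 0)
  expect_error(split_train_validation(co, "NO_SUCH_TRIAL"), "unknown trial")

  one <- co[co$trial == "ASCENT2", ]
  expect_error(split_train_validation(one, "ASCENT2"), "empty training")
})

test_that("cohort invariants: label rule, event times, one event type", {
  cfg <- cohort_config(seed = 8, death_rate_3mo = 0.08)
  co <- generate_cohort(cfg)
  expect_true(all(co$event_time_days >= 0))
  expect_true(all(co$event_type %in%
                    c("discontinuation_AE", "death", "censored")))
  expect_equal(co$discontinued_early,
               co$event_type == "discontinuation_AE" &
                 co$event_time_days <= cfg$horizon_days)
  # deaths occur within the horizon; censoring at follow-up
  expect_true(all(co$event_time_days[co$event_type == "death"] <=
                    cfg$horizon_days))
  expect_true(all(co$event_time_days[co$event_type == "censored"] ==
                    cfg$followup_days))
})

test_that("degenerate zero rate yields no discontinuation events", {
  cfg <- cohort_config(trial_specs = data.frame(
    trial = c("A", "B"), n = c(200L, 300L), rate = c(0, 0)), seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$event_type == "discontinuation_AE"), 0L)
  expect_false(any(co$discontinued_early))
})

test_that("empirical rates recover targets within binomial error at large n", {
  n <- 50000L
  rate <- 0.104
  cfg <- one_trial_config(n, rate, seed = 21, death_rate_3mo = 0.05)
  co <- generate_cohort(cfg)
  # direct Bernoulli counting against 3 standard binomial errors
  expect_lt(abs(mean(co$discontinued_early) - rate),
            3 * sqrt(rate * (1 - rate) / n))
  died <- co$event_type == "death"
  n_at_risk <- sum(!co$discontinued_early)
  expect_lt(abs(sum(died) / n_at_risk - 0.05),
            3 * sqrt(0.05 * 0.95 / n_at_risk))
  # latent risk is monotonically related to discontinuation probability
  q <- cut(co$latent_risk, quantile(co$latent_risk, 0:5 / 5),
           include.lowest = TRUE)
  expect_true(all(diff(tapply(co$discontinued_early, q, mean)) > 0))
})

test_that("generation is deterministic and substream-stable under the master seed", {
  cfg <- cohort_config(seed = 77)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  pr3 <- team_profiles(c(0.5, 0.3, 0.1))
  pr4 <- team_profiles(c(0.5, 0.3, 0.1, 0.9))
  s3 <- generate_team_scores(co1, pr3, seed = 11)
  s4 <- generate_team_scores(co1, pr4, seed = 11)
  # adding a team perturbs neither the cohort nor the other teams' scores
  expect_identical(s3[, 1:4], s4[, 1:4])
  expect_identical(generate_team_scores(co1, pr3, seed = 11), s3)
})

test_that("team score model honours its limiting cases", {
  co <- generate_cohort(one_trial_config(800, 0.12, seed = 31))
  # skill 1, no noise: ranking identical to the latent risk
  s <- generate_team_scores(co, team_profiles(1, 0), seed = 2)
  expect_equal(order(s[[2]]), order(co$latent_risk))
  # shared noise weight 1 with equal skill: identical scores
  s2 <- generate_team_scores(
    co, team_profiles(c(0.4, 0.4), shared_noise_weight = 1), seed = 3)
  expect_equal(cor(rank(s2[[2]]), rank(s2[[3]])), 1)
  # skill 0: mean AUPRC over replicates sits at the random-model level
  y <- as.integer(co$discontinued_early)
  au0 <- vapply(1:100, function(r) {
    sc <- generate_team_scores(co, team_profiles(0, 0.5), seed = 100 + r)
    auprc(sc[[2]], y)
  }, numeric(1))
  E <- exact_random_auprc(nrow(co), sum(y))
  expect_lt(abs(mean(au0) - E), 3 * sd(au0) / sqrt(length(au0)))
})

test_that("mean validation AUPRC is nondecreasing in team skill", {
  co <- generate_cohort(one_trial_config(470, 0.104, seed = 41))
  y <- as.integer(co$discontinued_early)
  skills <- c(0, 0.25, 0.6, 0.95)
  mean_au <- vapply(skills, function(a) {
    mean(vapply(1:200, function(r) {
      sc <- generate_team_scores(co, team_profiles(a, 0.5), seed = 500 + r)
      auprc(sc[[2]], y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_au) > 0))
})

test_that("cohort and score-matrix CSV round trips preserve content", {
  co <- generate_cohort(one_trial_config(60, 0.2, seed = 9))
  sm <- generate_team_scores(co, team_profiles(c(0.5, 0.1)), seed = 4)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(co, f1)
  write_score_matrix(sm, f2)
  co2 <- read_cohort(f1)
  sm2 <- read_score_matrix(f2)
  expect_equal(co2$patient_id, co$patient_id)
  expect_equal(co2$event_time_days, co$event_time_days, tolerance = 1e-12)
  expect_equal(co2$discontinued_early, co$discontinued_early)
  expect_equal(sm2$team_01, sm$team_01, tolerance = 1e-12)
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:3, b = 4:6), f3, row.names = FALSE)
  expect_error(read_score_matrix(f3), "patient_id")
  unlink(c(f1, f2, f3))
})
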