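test_that("rank normalization follows the average-tie convention", {
  m <- cbind(a = c(0.9, 0.1, 0.5))
  expect_equal(as.numeric(rank_normalize(m)), c(1, 1 / 3, 2 / 3))
  tied <- cbind(a = rep(2.5, 6))
  expect_equal(as.numeric(rank_normalize(tied)), rep(7 / 12, 6))
  # invariance to strictly increasing per-model transforms
  set.seed(5)
  for (i in 1:20) {
    col <- cbind(a = rnorm(30))
    expect_equal(rank_normalize(col), rank_normalize(exp(col)))
  }
  df <- data.frame(patient_id = c("p1", "p2"), m1 = c(2, 1))
  rm <- rank_normalize(df)
  expect_equal(rownames(rm), c("p1", "p2"))
  expect_error(rank_normalize(matrix(numeric(0), 0, 1)), "empty")
})

test_that("Ward/Manhattan clustering matches the naive Lance-Williams oracle", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    x <- matrix(runif(n * 3), n)
    hc <- stats::hclust(stats::dist(x, method = "manhattan"),
                        method = "ward.D")
    expect_equal(hc$height, ward_merge_heights(x), tolerance = 1e-10)
  }
})

test_that("clustering recovers planted structure and handles degenerate cases", {
  # identical pair merges first
  x <- rbind(c(0.1, 0.1), c(0.9, 0.9), c(0.1, 0.1))
  lab <- hierarchical_cluster(x, 2)
  expect_equal(lab[1], lab[3])
  expect_true(lab[2] != lab[1])
  expect_equal(unname(hierarchical_cluster(x, 1)), rep(1L, 3))
  expect_error(hierarchical_cluster(x, 5), "k must lie")

  # planted two-block rank matrix: perfect recovery
  set.seed(23)
  blk <- rbind(matrix(runif(40 * 4, 0.75, 1), 40),
               matrix(runif(40 * 4, 0, 0.25), 40))
  lab2 <- hierarchical_cluster(blk, 2)
  expect_equal(length(unique(lab2[1:40])), 1L)
  expect_equal(length(unique(lab2[41:80])), 1L)
  expect_true(lab2[1] != lab2[41])
})

test_that("elbow rule finds three planted clusters and flags structureless data", {
  set.seed(31)
  planted <- rbind(
    matrix(runif(50 * 5, 0.8, 1.0), 50),
    matrix(runif(50 * 5, 0.0, 0.2), 50),
    matrix(runif(50 * 5, 0.4, 0.6), 50))
  eb <- elbow_k(planted, k_max = 10)
  expect_equal(eb$k, 3L)
  expect_false(eb$low_confidence)
  expect_true(all(diff(eb$dispersion) <= 1e-9))  # nonincreasing in k

  # single spherical cloud: no pronounced elbow
  cloud <- matrix(runif(120 * 5), 120)
  eb0 <- elbow_k(cloud, k_max = 10)
  expect_true(eb0$low_confidence)
  expect_equal(eb0$k, 2L)

  expect_equal(length(elbow_k(planted, k_max = 3)$curvature), 1L)
  expect_error(elbow_k(planted[1:5, ], k_max = 10), "fewer patients")
})

test_that("risk-group labelling identifies high, low, and discordant clusters", {
  set.seed(37)
  n_models <- 6
  high <- matrix(runif(30 * n_models, 0.85, 1), 30)
  low <- matrix(runif(40 * n_models, 0, 0.15), 40)
  # discordant: half the models call each patient high risk, half low,
  # with the split varying by patient — far from both concordant blocks
  disc <- t(vapply(1:50, function(i) {
    hi_models <- sample(n_models, n_models / 2)
    row <- runif(n_models, 0, 0.15)
    row[hi_models] <- runif(length(hi_models), 0.85, 1)
    row
  }, numeric(n_models)))
  rm <- rbind(high, low, disc)
  labels <- hierarchical_cluster(rm, 3)
  lg <- label_risk_groups(rm, labels)
  expect_equal(as.character(lg$group[1:30]), rep("high", 30))
  expect_equal(as.character(lg$group[31:70]), rep("low", 40))
  expect_equal(as.character(lg$group[71:120]), rep("discordant", 50))
  cs <- lg$cluster_summary
  expect_equal(cs$dispersion[cs$group == "discordant"], max(cs$dispersion))

  # model-column permutation leaves the grouping unchanged
  perm <- rm[, c(4, 2, 6, 1, 3, 5)]
  lg2 <- label_risk_groups(perm, hierarchical_cluster(perm, 3))
  expect_equal(lg2$group, lg$group)

  expect_error(label_risk_groups(rm, rep(1L, nrow(rm))), "k = 3")
  same <- matrix(0.5, 20, 4)
  expect_error(label_risk_groups(same, rep(1:3, length.out = 20)),
               "not separated")
})

test_that("Aalen-Johansen cumulative incidence matches the hand example", {
  # day 1 discontinuation, day 2 death, day 3 discontinuation
  cif <- cumulative_incidence(c(1, 2, 3),
                              c("discontinuation_AE", "death",
                                "discontinuation_AE"))
  expect_equal(cif_at(cif, "discontinuation_AE", c(0.5, 1, 2.9, 3)),
               c(0, 1 / 3, 1 / 3, 2 / 3))
  expect_equal(cif_at(cif, "death", c(1.5, 2, 10)), c(0, 1 / 3, 1 / 3))
  # probability conservation at every time point
  tot <- tapply(cif$cif, list(cif$time, cif$group), sum)
  expect_true(all(tot <= 1 + 1e-12, na.rm = TRUE))
  expect_error(cumulative_incidence(c(-1, 2), c("death", "death")),
               "negative")
  expect_error(cumulative_incidence(1, "exploded"), "event_types")
})

test_that("with no competing events the CIF reduces to one minus Kaplan-Meier", {
  set.seed(41)
  n <- 150
  times <- rexp(n, 1 / 50)
  types <- ifelse(runif(n) < 0.7, "discontinuation_AE", "censored")
  cif <- cumulative_incidence(times, types)
  sub <- cif[cif$event_type == "discontinuation_AE", ]
  expect_equal(sub$cif, sub$naive_1mkm, tolerance = 1e-12)
  # and with no censoring either, to the empirical CDF
  cif2 <- cumulative_incidence(times, rep("discontinuation_AE", n))
  sub2 <- cif2[cif2$event_type == "discontinuation_AE", ]
  expect_equal(cif_at(cif2, "discontinuation_AE", sort(times)),
               ecdf(times)(sort(times)), tolerance = 1e-12)
  expect_true(all(diff(sub2$cif) >= 0))
})

test_that("baseline comparisons: calibration, separation, constants", {
  set.seed(43)
  groups <- sample(c("high", "low", "discordant"), 300, replace = TRUE)
  # null variables: raw p-values uniform, so ~5% fall below 0.05
  nullvars <- as.data.frame(matrix(rnorm(300 * 200), 300))
  names(nullvars) <- paste0("x", 1:200)
  tab <- compare_baseline(nullvars, groups, variables = names(nullvars))
  frac_raw <- mean(tab$p_value < 0.05)
  expect_lt(abs(frac_raw - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(mean(tab$significant), 0.05)

  # perfect separation: adjusted p near the attainable minimum
  df <- data.frame(x1 = as.numeric(factor(groups)), b1 = rbinom(300, 1, 0.5),
                   x2 = 1)
  tab2 <- compare_baseline(df, groups, variables = c("x1", "b1", "x2"))
  expect_lt(tab2$p_adjusted[tab2$variable == "x1"], 1e-10)
  expect_equal(tab2$type[tab2$variable == "b1"], "binary")
  expect_equal(tab2$note[tab2$variable == "x2"], "constant variable excluded")
  expect_true(is.na(tab2$p_value[tab2$variable == "x2"]))
  expect_error(compare_baseline(df, rep("high", 300)), "two groups")
})
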