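#' Configuration for the synthetic multi-trial cohort generator
#'
#' Describes a set of trials (comparator arms) to emulate: per-trial sample
#' size and target early-discontinuation rate, a baseline covariate model
#' driving a shared latent risk, a competing short-term death rate, and the
#' labelling horizon.  Defaults reproduce the four-trial metastatic
#' castration-resistant prostate cancer structure commonly used for
#' discontinuation-prediction benchmarking: trials of 476/598/526/470
#' patients with early-discontinuation counts 105/51/41/49 (rates
#' 22.1%/8.5%/7.8%/10.4%), and the 91.5-day (3-month) labelling rule.
#'
#' The latent risk is a linear predictor over `n_continuous` standard-normal
#' and `n_binary` Bernoulli(0.5) baseline covariates with coefficients
#' `beta`; a per-trial intercept is solved numerically so that the mean
#' logistic discontinuation probability matches the trial's target rate.
#'
#' @param trial_specs data frame with columns `trial`, `n`, `rate` (target
#'   early-discontinuation rate in \[0, 1\]).
#' @param n_continuous,n_binary counts of continuous and binary baseline
#'   covariates (defaults 5 and 2).
#' @param beta coefficients of the covariates on the latent risk scale, of
#'   length `n_continuous + n_binary`.
#' @param death_rate_3mo probability of death within the horizon for a
#'   patient who does not discontinue early (default 0.05).
#' @param death_risk_cor weight in \[0, 1\] tying short-term death risk to
#'   the same latent predictor (0 = independent, the default exposes the
#'   association as a knob rather than asserting one).
#' @param horizon_days labelling horizon in days (default 91.5).
#' @param followup_days administrative censoring time for event-free
#'   patients (default 365).
#' @param death_mean_days mean of the (truncated) exponential death-time
#'   distribution within the horizon (default 60).
#' @param seed master integer seed; per-trial and per-team substreams are
#'   derived from it so adding a team never perturbs the cohort.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(trial_specs = default_trial_specs(),
                          n_continuous = 5L, n_binary = 2L,
                          beta = c(0.8, 0.6, 0.4, 0.3, 0.2, 0.7, 0.5),
                          death_rate_3mo = 0.05, death_risk_cor = 0,
                          horizon_days = 91.5, followup_days = 365,
                          death_mean_days = 60, seed = 1L) {
  trial_specs <- as.data.frame(trial_specs)
  stopifnot(all(c("trial", "n", "rate") %in% names(trial_specs)))
  if (any(trial_specs$n <= 0 | trial_specs$n %% 1 != 0))
    stop("all trial sizes must be positive integers")
  if (any(trial_specs$rate < 0 | trial_specs$rate > 1))
    stop("all discontinuation rates must lie in [0, 1]")
  if (death_rate_3mo < 0 || death_rate_3mo > 1)
    stop("death_rate_3mo must lie in [0, 1]")
  if (death_risk_cor < 0 || death_risk_cor > 1)
    stop("death_risk_cor must lie in [0, 1]")
  if (horizon_days <= 0) stop("horizon_days must be positive")
  if (followup_days < horizon_days)
    stop("followup_days must be at least horizon_days")
  if (length(beta) != n_continuous + n_binary)
    stop("beta must have length n_continuous + n_binary")
  structure(
    list(trial_specs = trial_specs, n_continuous = as.integer(n_continuous),
         n_binary = as.integer(n_binary), beta = as.numeric(beta),
         death_rate_3mo = death_rate_3mo, death_risk_cor = death_risk_cor,
         horizon_days = horizon_days, followup_days = followup_days,
         death_mean_days = death_mean_days, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Printed four-trial specification
#'
#' The comparator-arm sizes and early-discontinuation counts of the four
#' source phase III trials: ASCENT2 (105/476), VENICE (51/598), MAINSAIL
#' (41/526), ENTHUSE 33 (49/470); 2,070 patients in total.
#'
#' @return data frame with columns `trial`, `n`, `rate`.
#' @export
default_trial_specs <- function() {
  data.frame(
    trial = c("ASCENT2", "VENICE", "MAINSAIL", "ENTHUSE33"),
    n = c(476L, 598L, 526L, 470L),
    rate = c(105, 51, 41, 49) / c(476, 598, 526, 470))
}

#' Generate a synthetic cohort
#'
#' Draws one record per patient: baseline covariates, a latent risk (linear
#' predictor, ground truth available only in synthetic data), the
#' early-discontinuation outcome through a logistic link with a per-trial
#' intercept solved to hit the target rate, a competing death event within
#' the horizon for non-discontinuers, and an event time.  Early
#' discontinuation times are uniform on (0, horizon\]; death times follow a
#' truncated exponential within the horizon; all other patients are
#' administratively censored at `followup_days`.
#'
#' @param config a [cohort_config()].
#' @return data frame of class `"cohort"` with columns `patient_id`,
#'   `trial`, `latent_risk`, `discontinued_early`, `event_time_days`,
#'   `event_type` (one of `discontinuation_AE`, `death`, `censored`) and the
#'   baseline covariates `x1..x<k>`, `b1..b<m>`.
#' @examples
#' co <- generate_cohort(cohort_config(seed = 7))
#' nrow(co)         # 2070
#' table(co$trial, co$discontinued_early)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$trial_specs
  per_trial <- lapply(seq_len(nrow(specs)), function(i) {
    with_seed(derive_seed(config$seed, "trial", i), {
      n <- specs$n[i]
      xc <- matrix(stats::rnorm(n * config$n_continuous), n)
      xb <- matrix(stats::rbinom(n * config$n_binary, 1L, 0.5), n)
      colnames(xc) <- paste0("x", seq_len(config$n_continuous))
      colnames(xb) <- paste0("b", seq_len(config$n_binary))
      lp <- drop(cbind(xc, xb) %*% config$beta)
      target <- specs$rate[i]
      p_disc <- if (target == 0) rep(0, n) else if (target == 1) rep(1, n)
        else stats::plogis(solve_intercept(lp, target) + lp)
      disc <- stats::rbinom(n, 1L, p_disc) == 1L
      # competing death for non-early-discontinuers; risk optionally tied to
      # the same latent predictor
      p_death <- if (config$death_rate_3mo %in% c(0, 1))
        rep(config$death_rate_3mo, n)
      else stats::plogis(
        solve_intercept(config$death_risk_cor * lp, config$death_rate_3mo) +
          config$death_risk_cor * lp)
      death <- !disc & stats::rbinom(n, 1L, p_death) == 1L
      type <- ifelse(disc, "discontinuation_AE",
                     ifelse(death, "death", "censored"))
      t_disc <- stats::runif(n, 0, config$horizon_days)
      t_death <- rexp_trunc(n, 1 / config$death_mean_days,
                            config$horizon_days)
      time <- ifelse(disc, t_disc,
                     ifelse(death, t_death, config$followup_days))
      data.frame(trial = specs$trial[i], latent_risk = lp,
                 discontinued_early = disc, event_time_days = time,
                 event_type = type, xc, xb)
    })
  })
  out <- do.call(rbind, per_trial)
  out <- cbind(patient_id = sprintf("P%04d", seq_len(nrow(out))), out)
  attr(out, "config") <- config
  class(out) <- c("cohort", "data.frame")
  out
}

# Solve the logistic intercept c so that mean(plogis(c + lp)) == target.
solve_intercept <- function(lp, target) {
  span <- 30 + max(abs(lp))
  stats::uniroot(function(c0) mean(stats::plogis(c0 + lp)) - target,
                 lower = -span, upper = span, tol = 1e-10)$root
}

# Exponential draw truncated to (0, upper] by inverse CDF.
rexp_trunc <- function(n, rate, upper) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

#' Team profiles for synthetic risk-score generation
#'
#' A team's score is a mixture of the standardized latent risk (weight set
#' by `skill`, the correlation of the score with the latent risk), a noise
#' component shared across teams (weight set by `shared_noise_weight`,
#' controlling inter-team score correlation), and idiosyncratic noise.
#' The default roster emulates a challenge field of 7 stronger and 27
#' weaker teams with partially shared errors.
#'
#' @param skill numeric vector in \[0, 1\], one per team.
#' @param shared_noise_weight numeric in \[0, 1\], recycled across teams.
#' @param team_id optional identifiers (default `team_01`, ...).
#' @return data frame of class `"team_profiles"` with columns `team_id`,
#'   `skill`, `shared_noise_weight`, `seed_offset`.
#' @export
team_profiles <- function(skill, shared_noise_weight = 0.5,
                          team_id = NULL) {
  if (any(skill < 0 | skill > 1) ||
      any(shared_noise_weight < 0 | shared_noise_weight > 1))
    stop("skill and shared_noise_weight must lie in [0, 1]")
  k <- length(skill)
  if (is.null(team_id)) team_id <- sprintf("team_%02d", seq_len(k))
  out <- data.frame(team_id = team_id, skill = skill,
                    shared_noise_weight = rep_len(shared_noise_weight, k),
                    seed_offset = seq_len(k))
  class(out) <- c("team_profiles", "data.frame")
  out
}

#' @rdname team_profiles
#' @param n_strong,n_weak sizes of the strong and weak tiers (defaults 7
#'   and 27).
#' @param skill_strong,skill_weak tier skills (defaults 0.40 and 0.05).
#' @param shared_noise_weight shared-noise weight for every team (default
#'   0.97: the strong tier's errors are strongly correlated, which is what
#'   keeps near-equal models within the Bayes-factor indistinguishability
#'   cut and yields a stable top set).
#' @export
default_team_profiles <- function(n_strong = 7L, n_weak = 27L,
                                  skill_strong = 0.40, skill_weak = 0.05,
                                  shared_noise_weight = 0.97) {
  team_profiles(c(rep(skill_strong, n_strong), rep(skill_weak, n_weak)),
                shared_noise_weight = shared_noise_weight)
}

#' Generate a risk-score matrix for synthetic teams
#'
#' Each team's score is `a * z + b * shared + c * own`, where `z` is the
#' standardized latent risk, `shared` is one standard-normal noise vector
#' common to all teams, `own` is team-specific noise, `a = skill`, and the
#' noise weights split the residual variance `1 - skill^2` according to
#' `shared_noise_weight` so every score has unit variance.  With skill 1
#' the score ordering equals the latent-risk ordering; with skill 0 the
#' score is independent of the outcome; two teams with equal skill and
#' `shared_noise_weight = 1` produce identical scores.
#'
#' @param cohort a `"cohort"` data frame from [generate_cohort()].
#' @param profiles a [team_profiles()] data frame.
#' @param seed integer seed (independent of the cohort seed).
#' @return data frame of class `"score_matrix"`: `patient_id` followed by
#'   one numeric column per team.
#' @export
generate_team_scores <- function(cohort, profiles, seed = 1L) {
  stopifnot(nrow(cohort) > 0, nrow(profiles) > 0)
  if (!all(c("team_id", "skill", "shared_noise_weight") %in% names(profiles)))
    stop("profiles must carry team_id, skill and shared_noise_weight")
  n <- nrow(cohort)
  z <- as.numeric(scale(cohort$latent_risk))
  shared <- with_seed(derive_seed(seed, "shared", 0L), stats::rnorm(n))
  cols <- lapply(seq_len(nrow(profiles)), function(j) {
    a <- profiles$skill[j]
    w <- profiles$shared_noise_weight[j]
    resid <- sqrt(max(0, 1 - a^2))
    b <- resid * sqrt(w)
    cc <- resid * sqrt(1 - w)
    own <- with_seed(derive_seed(seed, "team", profiles$seed_offset[j]),
                     stats::rnorm(n))
    a * z + b * shared + cc * own
  })
  out <- data.frame(patient_id = cohort$patient_id, cols)
  names(out) <- c("patient_id", profiles$team_id)
  class(out) <- c("score_matrix", "data.frame")
  out
}

#' Split a cohort into training and validation sets by trial
#'
#' The validation set is exactly the named trial; all remaining trials form
#' the training set (the challenge combined three trials, n = 1,600, and
#' held out the fourth, n = 470).  The partition is exhaustive and
#' disjoint.
#'
#' @param cohort a `"cohort"` data frame.
#' @param validation_trial trial name to hold out.
#' @return list with elements `train` and `validation`.
#' @export
split_train_validation <- function(cohort, validation_trial) {
  if (!validation_trial %in% cohort$trial)
    stop("unknown trial: ", validation_trial)
  val <- cohort[cohort$trial == validation_trial, , drop = FALSE]
  tr <- cohort[cohort$trial != validation_trial, , drop = FALSE]
  if (nrow(tr) == 0L)
    stop("holding out '", validation_trial, "' leaves an empty training set")
  list(train = tr, validation = val)
}

# Stable per-component substream derivation from a master seed; arithmetic
# in doubles (exact below 2^53) keeps the result inside 32-bit range for
# any master seed below 2^31.
derive_seed <- function(seed, what, index) {
  h <- sum(utf8ToInt(what)) %% 1000
  as.integer((as.numeric(seed) * 10007 + h * 131 + as.numeric(index)) %%
               2147483647)
}

#' Read/write the cohort and score-matrix CSV dialects
#'
#' Cohorts and score matrices are interchanged as headered CSV, one row per
#' patient; a score matrix has `patient_id` first and one column per model.
#'
#' @param x object to write.
#' @param path file path.
#' @return `read_cohort()` and `read_score_matrix()` return the classed
#'   data frame; the writers return `path` invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

#' @rdname write_cohort
#' @export
write_score_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_score_matrix <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(out)[1] != "patient_id")
    stop("score matrix CSV must have patient_id as its first column")
  class(out) <- c("score_matrix", "data.frame")
  out
}
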