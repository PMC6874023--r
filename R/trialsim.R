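#' Configuration for discontinuation-screened trial simulations
#'
#' Describes a balanced two-arm randomized controlled trial with a survival
#' endpoint in which a fraction `disc_rate` of patients are latent early
#' discontinuers who, if randomized to the treatment arm, retain only a
#' fraction `dilution` of the log-hazard treatment benefit (default 0:
#' no benefit — the intention-to-treat dilution that motivates screening).
#' Before randomization, a prediction model screens out true discontinuers
#' with sensitivity `accuracy` (specificity 1 by default; a false-exclusion
#' rate for non-discontinuers is available).  Baseline survival is Weibull
#' (shape 1 = exponential); censoring combines an administrative horizon
#' with optional exponential dropout.
#'
#' @param hr_grid hazard ratios examined (default 1.3 to 2.0 by 0.1).
#' @param accuracy_grid screening sensitivities (default 0, 0.25, 0.5,
#'   0.75, 1).
#' @param alpha two-sided false-positive rate (default 0.05).
#' @param target_power required power (default 0.80).
#' @param disc_rate fraction of would-be early discontinuers (default 0.10).
#' @param dilution fraction of the log-hazard effect retained by a
#'   discontinuer in the treatment arm (default 0).
#' @param false_exclusion probability a non-discontinuer is wrongly
#'   screened out (default 0).
#' @param weibull_shape,weibull_scale baseline Weibull parameters (defaults
#'   1 and 500 days).
#' @param admin_horizon administrative censoring time in days (default
#'   1095, i.e. 3 years).
#' @param dropout_rate exponential dropout hazard per day (default 0).
#' @param replicates simulated datasets per power estimate (default 100).
#' @param seed integer seed.
#' @return list of class `"trial_sim_config"`.
#' @export
trial_sim_config <- function(hr_grid = seq(1.3, 2.0, by = 0.1),
                             accuracy_grid = c(0, 0.25, 0.5, 0.75, 1),
                             alpha = 0.05, target_power = 0.80,
                             disc_rate = 0.10, dilution = 0,
                             false_exclusion = 0, weibull_shape = 1,
                             weibull_scale = 500, admin_horizon = 1095,
                             dropout_rate = 0, replicates = 100L,
                             seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)")
  if (any(hr_grid <= 1)) stop("hazard ratios must exceed 1")
  if (any(accuracy_grid < 0 | accuracy_grid > 1))
    stop("accuracies must lie in [0, 1]")
  if (disc_rate < 0 || disc_rate > 1) stop("disc_rate must lie in [0, 1]")
  if (dilution < 0 || dilution > 1) stop("dilution must lie in [0, 1]")
  if (false_exclusion < 0 || false_exclusion >= 1)
    stop("false_exclusion must lie in [0, 1)")
  if (weibull_shape <= 0 || weibull_scale <= 0 || admin_horizon <= 0)
    stop("Weibull parameters and admin_horizon must be positive")
  structure(
    list(hr_grid = hr_grid, accuracy_grid = accuracy_grid, alpha = alpha,
         target_power = target_power, disc_rate = disc_rate,
         dilution = dilution, false_exclusion = false_exclusion,
         weibull_shape = weibull_shape, weibull_scale = weibull_scale,
         admin_horizon = admin_horizon, dropout_rate = dropout_rate,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "trial_sim_config")
}

#' Simulate one screened, balanced two-arm survival trial
#'
#' Randomizes exactly `n` patients 1:1.  Screening with sensitivity
#' `accuracy` thins the latent discontinuers before randomization, so the
#' discontinuer fraction among randomized patients is
#' `disc_rate (1 - accuracy) / (1 - disc_rate * accuracy - (1 - disc_rate) *
#' false_exclusion)`; screened-out patients are not enrolled and are not
#' charged to `n`.  Treatment-arm non-discontinuers experience hazard
#' reduced by the full hazard ratio `hr`; treatment-arm discontinuers by
#' `hr^dilution`.  Event times are Weibull; censoring is administrative
#' plus optional exponential dropout.
#'
#' @param n randomized sample size (even, >= 2).
#' @param hr hazard ratio (control over treatment; > 1 favours treatment).
#' @param accuracy screening sensitivity in \[0, 1\].
#' @param config a [trial_sim_config()].
#' @param seed integer seed.
#' @return data frame with columns `arm` (0 control / 1 treatment),
#'   `discontinuer`, `time`, `status` (1 event / 0 censored).
#' @export
simulate_trial <- function(n, hr, accuracy, config, seed = 1L) {
  stopifnot(inherits(config, "trial_sim_config"))
  if (n < 2 || n %% 2 != 0) stop("n must be even and at least 2")
  if (hr < 1) stop("hr must be at least 1")
  p <- config$disc_rate
  # post-screening discontinuer fraction by binomial thinning
  keep_disc <- p * (1 - accuracy)
  keep_non <- (1 - p) * (1 - config$false_exclusion)
  p_post <- keep_disc / (keep_disc + keep_non)
  with_seed(seed, {
    # uniform-threshold draw consumes a fixed number of variates, so runs
    # differing only in screening accuracy share all downstream randomness
    disc <- stats::runif(n) < p_post
    arm <- sample(rep(c(0L, 1L), n / 2))
    loghr <- log(hr)
    eff <- ifelse(arm == 1L, ifelse(disc, config$dilution * loghr, loghr), 0)
    # Weibull with proportional hazards: scale multiplied by HR^(1/shape)
    sc <- config$weibull_scale * exp(eff / config$weibull_shape)
    t_event <- stats::rweibull(n, shape = config$weibull_shape, scale = sc)
    t_cens <- if (config$dropout_rate > 0)
      pmin(config$admin_horizon, stats::rexp(n, config$dropout_rate))
    else rep(config$admin_horizon, n)
    data.frame(arm = arm, discontinuer = disc,
               time = pmin(t_event, t_cens),
               status = as.integer(t_event <= t_cens))
  })
}

#' Two-sided log-rank test between trial arms
#'
#' Standard log-rank chi-squared statistic and p-value comparing the two
#' arms of a simulated trial.
#'
#' @param trial data frame from [simulate_trial()] (columns `arm`, `time`,
#'   `status`).
#' @return list with `statistic` (chi-squared, 1 df) and `p_value`.
#' @export
logrank_test <- function(trial) {
  if (length(unique(trial$arm)) < 2) stop("both arms must be nonempty")
  if (sum(trial$status) == 0) stop("log-rank test requires at least 1 event")
  fit <- survival::survdiff(survival::Surv(time, status) ~ arm, data = trial)
  list(statistic = fit$chisq,
       p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Monte-Carlo power of the log-rank test at a given sample size
#'
#' Fraction of `config$replicates` simulated trials whose two-sided
#' log-rank p-value falls below `config$alpha`, with its binomial
#' Monte-Carlo standard error.
#'
#' @inheritParams simulate_trial
#' @return list with `power`, `mc_se`, `replicates`.
#' @export
estimate_power <- function(n, hr, accuracy, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  R <- config$replicates
  rej <- vapply(seq_len(R), function(r) {
    tr <- simulate_trial(n, hr, accuracy, config,
                         seed = derive_seed(seed, "trial", r))
    logrank_test(tr)$p_value < config$alpha
  }, logical(1))
  p <- mean(rej)
  list(power = p, mc_se = sqrt(p * (1 - p) / R), replicates = R)
}

#' Schoenfeld approximation to the required number of events
#'
#' Analytic event count for a 1:1 two-arm trial to detect hazard ratio
#' `hr` with two-sided level `alpha` and the given power:
#' `d = ceiling(4 (z_{1-alpha/2} + z_power)^2 / log(hr)^2)`.
#' Used to anchor the simulation-based sample-size search and as an
#' independent oracle for it.
#'
#' @param hr hazard ratio (> 1).
#' @param alpha two-sided false-positive rate (default 0.05).
#' @param power target power (default 0.80).
#' @return integer number of events.
#' @export
schoenfeld_events <- function(hr, alpha = 0.05, power = 0.80) {
  if (hr <= 1) stop("hr must exceed 1")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(ceiling(4 * (za + zb)^2 / log(hr)^2))
}

#' Smallest randomized sample size achieving the target power
#'
#' Bisection search over even sample sizes for the smallest `n` whose
#' Monte-Carlo power meets `config$target_power`, initialized from the
#' Schoenfeld event count scaled by the expected event fraction and by the
#' dilution of the average treatment-arm log-hazard effect.  Achieved power
#' and its Monte-Carlo standard error are attached.
#'
#' @inheritParams simulate_trial
#' @param n_max search cap on the randomized sample size (default 50000).
#' @return one-row data frame: `hr`, `accuracy`, `required_n`,
#'   `achieved_power`, `power_mc_se`.
#' @export
required_sample_size <- function(hr, accuracy, config, seed = NULL,
                                 n_max = 50000L) {
  if (is.null(seed)) seed <- config$seed
  # anchor: effective average log HR in the treatment arm after screening
  p <- config$disc_rate
  keep_disc <- p * (1 - accuracy)
  keep_non <- (1 - p) * (1 - config$false_exclusion)
  p_post <- keep_disc / (keep_disc + keep_non)
  eff_loghr <- (1 - p_post) * log(hr) + p_post * config$dilution * log(hr)
  d <- schoenfeld_events(exp(eff_loghr), config$alpha, config$target_power)
  ev_frac <- expected_event_fraction(config)
  n0 <- even_ceiling(d / ev_frac)
  power_at <- function(n)
    estimate_power(n, hr, accuracy, config,
                   seed = derive_seed(seed, "power", n))$power
  # expand upward until target met
  hi <- max(4L, n0)
  while (power_at(hi) < config$target_power) {
    hi <- even_ceiling(hi * 1.5)
    if (hi > n_max) stop("sample-size search cap exceeded")
  }
  lo <- 2L
  while (hi - lo > max(2L, round(0.02 * hi))) {
    mid <- even_ceiling((lo + hi) / 2)
    if (power_at(mid) >= config$target_power) hi <- mid else lo <- mid
  }
  pw <- estimate_power(hi, hr, accuracy, config,
                       seed = derive_seed(seed, "final", hi))
  data.frame(hr = hr, accuracy = accuracy, required_n = as.integer(hi),
             achieved_power = pw$power, power_mc_se = pw$mc_se)
}

# Probability a randomized patient's event is observed before censoring
# (numerical integral under the baseline hazard; treatment effects shift
# this only modestly and the search self-corrects).
expected_event_fraction <- function(config) {
  sh <- config$weibull_shape
  sc <- config$weibull_scale
  p_admin <- stats::pweibull(config$admin_horizon, sh, sc)
  if (config$dropout_rate <= 0) return(max(p_admin, 1e-3))
  f <- function(t) stats::dweibull(t, sh, sc) *
    exp(-config$dropout_rate * t)
  max(stats::integrate(f, 0, config$admin_horizon)$value, 1e-3)
}

even_ceiling <- function(x) {
  n <- as.integer(ceiling(x))
  if (n %% 2L == 1L) n + 1L else n
}

#' Sample-size sweep over hazard-ratio and screening-accuracy grids
#'
#' Runs [required_sample_size()] for every (hr, accuracy) cell of the
#' configured grids.  Deterministic under the config seed.
#'
#' @param config a [trial_sim_config()].
#' @return data frame of class `"sample_size_table"` with one row per
#'   grid cell: `hr`, `accuracy`, `required_n`, `achieved_power`,
#'   `power_mc_se`.
#' @export
trial_sweep <- function(config) {
  grid <- expand.grid(accuracy = config$accuracy_grid, hr = config$hr_grid)
  # one seed stream per hazard ratio: accuracies within a row share their
  # random numbers, sharpening the screening contrast (and making the
  # accuracy column irrelevant by construction when disc_rate = 0)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    required_sample_size(grid$hr[i], grid$accuracy[i], config,
                         seed = derive_seed(config$seed, "hr",
                                            round(1000 * grid$hr[i])))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_size_table", "data.frame")
  out
}
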