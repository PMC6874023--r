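#' Default end-to-end configuration
#'
#' A complete configuration list for [run_pipeline()], mirroring the study
#' conditions the package emulates: the printed four-trial cohort
#' structure, a 34-team field (7 stronger, 27 weaker), challenge scoring on
#' the held-out trial, lift analysis, consensus clustering, the
#' 70/30-weighted ensemble, and the hazard-ratio x screening-accuracy
#' sample-size sweep.  Any element can be overridden before validation.
#'
#' @param seed master seed for every stage.
#' @return nested list understood by [validate_config()] and
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      trials = default_trial_specs(),
      death_rate_3mo = 0.05,
      horizon_days = 91.5,
      followup_days = 365),
    teams = list(
      n_strong = 7L, n_weak = 27L,
      skill_strong = 0.40, skill_weak = 0.05,
      shared_noise_weight = 0.97),
    scoring = list(
      validation_trial = "ENTHUSE33",
      replicates = 1000L, null_replicates = 5000L,
      fdr_cut = 0.10, bf_cut = 3),
    lift = list(grid_step = 0.01),
    consensus = list(k_max = 10L),
    ensemble = list(split_fraction = 0.7, n_repeats = 10L),
    trialsim = list(
      hr_grid = seq(1.3, 2.0, by = 0.1),
      accuracy_grid = c(0, 0.25, 0.5, 0.75, 1),
      alpha = 0.05, target_power = 0.80, disc_rate = 0.10,
      dilution = 0, weibull_shape = 1, weibull_scale = 500,
      admin_horizon = 1095, dropout_rate = 0, replicates = 100L))
}

#' Validate a pipeline configuration
#'
#' Type- and range-checks every field of a configuration list (or YAML
#' file) against the schemas of the stage configs; unknown keys are
#' flagged.  Returns a character vector of problems, empty when the
#' configuration is valid.
#'
#' @param config configuration list, or path to a YAML file.
#' @return character vector of validation messages (empty = valid), with
#'   each message naming the offending field.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))
  known <- c("seed", "cohort", "teams", "scoring", "lift", "consensus",
             "ensemble", "trialsim")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) note("unknown top-level key(s): ",
                              paste(extra, collapse = ", "))
  num_in <- function(x, lo, hi, field, open = FALSE) {
    bad <- !is.numeric(x) || anyNA(x) ||
      (if (open) any(x <= lo | x >= hi) else any(x < lo | x > hi))
    if (bad) note(field, ": must lie in ", if (open) "(" else "[",
                  lo, ", ", hi, if (open) ")" else "]")
  }
  co <- config$cohort
  if (!is.null(co)) {
    tr <- as.data.frame(co$trials)
    if (!all(c("trial", "n", "rate") %in% names(tr)))
      note("cohort.trials: needs columns trial, n, rate")
    else {
      if (any(tr$n <= 0)) note("cohort.trials.n: must be positive")
      num_in(tr$rate, 0, 1, "cohort.trials.rate")
    }
    num_in(co$death_rate_3mo, 0, 1, "cohort.death_rate_3mo")
    if (!is.null(co$horizon_days) && co$horizon_days <= 0)
      note("cohort.horizon_days: must be positive")
  }
  te <- config$teams
  if (!is.null(te)) {
    num_in(te$skill_strong, 0, 1, "teams.skill_strong")
    num_in(te$skill_weak, 0, 1, "teams.skill_weak")
    num_in(te$shared_noise_weight, 0, 1, "teams.shared_noise_weight")
  }
  sc <- config$scoring
  if (!is.null(sc)) {
    num_in(sc$fdr_cut, 0, 1, "scoring.fdr_cut", open = TRUE)
    if (!is.null(sc$bf_cut) && sc$bf_cut < 1) note("scoring.bf_cut: must be >= 1")
  }
  ts <- config$trialsim
  if (!is.null(ts)) {
    num_in(ts$alpha, 0, 1, "trialsim.alpha", open = TRUE)
    num_in(ts$target_power, 0, 1, "trialsim.target_power", open = TRUE)
    if (!is.null(ts$hr_grid) && any(ts$hr_grid <= 1))
      note("trialsim.hr_grid: hazard ratios must exceed 1")
    num_in(ts$accuracy_grid, 0, 1, "trialsim.accuracy_grid")
    num_in(ts$disc_rate, 0, 1, "trialsim.disc_rate")
    num_in(ts$dilution, 0, 1, "trialsim.dilution")
  }
  problems
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order — cohort generation, team score
#' generation, challenge leaderboard, lift analysis, consensus risk
#' grouping, ensemble, trial sample-size sweep — writing every artifact as
#' headered CSV under `output_dir` and returning a run manifest.  A stage
#' subset is honoured provided each requested stage's upstream artifacts
#' already exist in `output_dir`.  All randomness flows from the master
#' seed through documented per-stage substreams, so identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config configuration list or YAML path (see
#'   [default_pipeline_config()]).
#' @param output_dir writable output directory (created if absent).
#' @param stages character subset of `c("cohort", "scores", "leaderboard",
#'   "lift", "consensus", "ensemble", "trialsim")`; default all.
#' @param seed optional master-seed override.
#' @return manifest list (also written as `manifest.yaml`): config
#'   snapshot, master seed, per-stage seeds, artifact paths, stage status.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir, stages = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  all_stages <- c("cohort", "scores", "leaderboard", "lift", "consensus",
                  "ensemble", "trialsim")
  if (is.null(stages)) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)
  need <- function(stage, file) {
    if (!file.exists(path(file)))
      stop("stage '", stage, "' requires missing upstream artifact: ", file)
  }
  ms <- config$seed
  stage_seeds <- stats::setNames(
    vapply(seq_along(all_stages), function(i)
      derive_seed(ms, all_stages[i], i), numeric(1)), all_stages)
  manifest <- list(config = config, master_seed = ms,
                   stage_seeds = as.list(stage_seeds),
                   artifacts = list(), status = list())
  tconf <- with(config$teams, team_profiles(
    c(rep(skill_strong, n_strong), rep(skill_weak, n_weak)),
    shared_noise_weight = shared_noise_weight))

  if ("cohort" %in% stages) {
    cc <- cohort_config(
      trial_specs = as.data.frame(config$cohort$trials),
      death_rate_3mo = config$cohort$death_rate_3mo,
      horizon_days = config$cohort$horizon_days,
      followup_days = config$cohort$followup_days,
      seed = stage_seeds[["cohort"]])
    write_cohort(generate_cohort(cc), path("cohort.csv"))
    manifest$artifacts$cohort <- path("cohort.csv")
    manifest$status$cohort <- "done"
  }
  if ("scores" %in% stages) {
    need("scores", "cohort.csv")
    cohort <- read_cohort(path("cohort.csv"))
    sm <- generate_team_scores(cohort, tconf, seed = stage_seeds[["scores"]])
    write_score_matrix(sm, path("scores.csv"))
    manifest$artifacts$scores <- path("scores.csv")
    manifest$status$scores <- "done"
  }
  val_of <- function(cohort, sm) {
    val <- split_train_validation(
      cohort, config$scoring$validation_trial)$validation
    list(cohort = val,
         scores = sm[match(val$patient_id, sm$patient_id), , drop = FALSE])
  }
  if ("leaderboard" %in% stages) {
    need("leaderboard", "cohort.csv"); need("leaderboard", "scores.csv")
    v <- val_of(read_cohort(path("cohort.csv")),
                read_score_matrix(path("scores.csv")))
    lb <- rank_teams(v$scores, as.integer(v$cohort$discontinued_early),
                     replicates = config$scoring$replicates,
                     null_replicates = config$scoring$null_replicates,
                     fdr_cut = config$scoring$fdr_cut,
                     bf_cut = config$scoring$bf_cut,
                     seed = stage_seeds[["leaderboard"]])
    utils::write.csv(lb, path("leaderboard.csv"), row.names = FALSE)
    manifest$artifacts$leaderboard <- path("leaderboard.csv")
    manifest$status$leaderboard <- "done"
  }
  if ("lift" %in% stages) {
    need("lift", "cohort.csv"); need("lift", "scores.csv")
    v <- val_of(read_cohort(path("cohort.csv")),
                read_score_matrix(path("scores.csv")))
    ls <- lift_summary(v$scores, as.integer(v$cohort$discontinued_early),
                       grid = seq(config$lift$grid_step, 1,
                                  by = config$lift$grid_step))
    utils::write.csv(ls, path("lift_summary.csv"), row.names = FALSE)
    manifest$artifacts$lift <- path("lift_summary.csv")
    manifest$status$lift <- "done"
  }
  if ("consensus" %in% stages) {
    need("consensus", "cohort.csv"); need("consensus", "scores.csv")
    need("consensus", "leaderboard.csv")
    lb <- utils::read.csv(path("leaderboard.csv"))
    top_ids <- lb$model_id[lb$top_performer]
    if (length(top_ids) < 2) top_ids <- utils::head(lb$model_id, 7L)
    v <- val_of(read_cohort(path("cohort.csv")),
                read_score_matrix(path("scores.csv")))
    cg <- consensus_groups(
      v$scores[, c("patient_id", top_ids), drop = FALSE], k = 3L,
      k_max = config$consensus$k_max)
    groups <- data.frame(patient_id = v$cohort$patient_id,
                         cluster = cg$labels, group = cg$group)
    utils::write.csv(groups, path("risk_groups.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(k = seq_along(cg$elbow$dispersion),
                 dispersion = cg$elbow$dispersion),
      path("dispersion_curve.csv"), row.names = FALSE)
    cif <- cumulative_incidence(v$cohort$event_time_days,
                                v$cohort$event_type, groups = cg$group)
    utils::write.csv(cif, path("cif_by_group.csv"), row.names = FALSE)
    bl <- compare_baseline(v$cohort, cg$group)
    utils::write.csv(bl, path("baseline_comparison.csv"), row.names = FALSE)
    manifest$artifacts$consensus <- path("risk_groups.csv")
    manifest$status$consensus <- "done"
  }
  if ("ensemble" %in% stages) {
    need("ensemble", "cohort.csv"); need("ensemble", "scores.csv")
    need("ensemble", "leaderboard.csv")
    cohort <- read_cohort(path("cohort.csv"))
    sm <- read_score_matrix(path("scores.csv"))
    lb <- utils::read.csv(path("leaderboard.csv"))
    top_ids <- lb$model_id[lb$top_performer]
    if (length(top_ids) < 2) top_ids <- utils::head(lb$model_id, 7L)
    split <- split_train_validation(cohort, config$scoring$validation_trial)
    prof <- tconf[match(top_ids, tconf$team_id), , drop = FALSE]
    ho <- holdout_performance(split$train, prof,
                              split_fraction = config$ensemble$split_fraction,
                              n_repeats = config$ensemble$n_repeats,
                              seed = stage_seeds[["ensemble"]])
    w <- compute_weights(ho)
    utils::write.csv(data.frame(model_id = names(w), holdout_auprc = ho,
                                weight = as.numeric(w)),
                     path("ensemble_weights.csv"), row.names = FALSE)
    v <- val_of(cohort, sm)
    ens <- ensemble_scores(v$scores[, c("patient_id", top_ids)], w)
    out <- data.frame(patient_id = v$cohort$patient_id, ensemble = ens)
    utils::write.csv(out, path("ensemble_scores.csv"), row.names = FALSE)
    manifest$artifacts$ensemble <- path("ensemble_scores.csv")
    manifest$status$ensemble <- "done"
  }
  if ("trialsim" %in% stages) {
    ts <- config$trialsim
    tc <- trial_sim_config(
      hr_grid = ts$hr_grid, accuracy_grid = ts$accuracy_grid,
      alpha = ts$alpha, target_power = ts$target_power,
      disc_rate = ts$disc_rate, dilution = ts$dilution,
      weibull_shape = ts$weibull_shape, weibull_scale = ts$weibull_scale,
      admin_horizon = ts$admin_horizon, dropout_rate = ts$dropout_rate,
      replicates = ts$replicates, seed = stage_seeds[["trialsim"]])
    tab <- trial_sweep(tc)
    utils::write.csv(tab, path("sample_size_table.csv"), row.names = FALSE)
    manifest$artifacts$trialsim <- path("sample_size_table.csv")
    manifest$status$trialsim <- "done"
  }
  manifest$config$cohort$trials <- as.data.frame(config$cohort$trials)
  yaml::write_yaml(
    list(master_seed = manifest$master_seed,
         stage_seeds = manifest$stage_seeds,
         artifacts = manifest$artifacts, status = manifest$status),
    path("manifest.yaml"))
  invisible(manifest)
}
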