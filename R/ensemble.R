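#' Holdout performance of synthetic teams on training data
#'
#' Emulates the post-challenge weighting procedure: repeatedly draw a
#' stratified random split of the training cohort (70% fit / 30% holdout by
#' default), let each synthetic team emit risk scores on the held-out
#' patients, and average each team's holdout AUPRC across repeats.  Splits
#' are stratified by trial and outcome so the rare positives appear in
#' every holdout; a holdout without positives is redrawn (retry-capped).
#'
#' @param training_cohort a `"cohort"` data frame (e.g. the `train` element
#'   of [split_train_validation()]).
#' @param profiles a [team_profiles()] data frame.
#' @param split_fraction fraction of patients used for "training" in each
#'   repeat (default 0.7; scores are evaluated on the remaining 30%).
#' @param n_repeats number of random splits averaged (default 10; 1
#'   reproduces a single 70/30 draw).
#' @param seed integer seed.
#' @return named numeric vector of mean holdout AUPRC, one per team.
#' @export
holdout_performance <- function(training_cohort, profiles,
                                split_fraction = 0.7, n_repeats = 10L,
                                seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, n_repeats >= 1)
  n <- nrow(training_cohort)
  strata <- interaction(training_cohort$trial,
                        training_cohort$discontinued_early, drop = TRUE)
  acc <- matrix(NA_real_, n_repeats, nrow(profiles))
  for (r in seq_len(n_repeats)) {
    holdout <- NULL
    for (try in 1:100) {
      idx <- with_seed(derive_seed(seed, "split", r * 100L + try), {
        unlist(lapply(split(seq_len(n), strata), function(s) {
          k <- max(1L, round(length(s) * split_fraction))
          if (length(s) == 1L) s else sample(s, k)
        }), use.names = FALSE)
      })
      ho <- setdiff(seq_len(n), idx)
      if (length(ho) > 0 && any(training_cohort$discontinued_early[ho])) {
        holdout <- ho
        break
      }
    }
    if (is.null(holdout)) stop("could not draw a holdout with positives")
    sub <- training_cohort[holdout, , drop = FALSE]
    sm <- generate_team_scores(sub, profiles,
                               seed = derive_seed(seed, "emit", r))
    y <- as.integer(sub$discontinued_early)
    acc[r, ] <- apply(as_score_matrix(sm), 2, auprc, labels = y)
  }
  stats::setNames(colMeans(acc), profiles$team_id)
}

#' Ensemble weights from holdout performance
#'
#' Normalizes per-model holdout AUPRC to a probability vector
#' (`weight_i = auprc_i / sum(auprc)`).  With `baseline` set to the
#' training prevalence, the excess AUPRC over the random-model expectation
#' is normalized instead (models at or below baseline get weight 0, and at
#' least one model must exceed it).
#'
#' @param holdout_auprc named numeric vector of positive AUPRC values.
#' @param baseline nonnegative AUPRC subtracted before normalization
#'   (default 0).
#' @return named numeric weights summing to 1.
#' @export
compute_weights <- function(holdout_auprc, baseline = 0) {
  if (length(holdout_auprc) == 0L) stop("no models to weight")
  if (any(holdout_auprc <= 0)) stop("holdout AUPRC values must be positive")
  w <- pmax(holdout_auprc - baseline, 0)
  if (sum(w) <= 0) stop("no model exceeds the baseline AUPRC")
  w / sum(w)
}

#' Weighted-average ensemble risk scores
#'
#' Rank-normalizes each member model's scores to (0, 1\] (so arbitrary raw
#' score scales are commensurable) and combines them as the weighted mean
#' per patient.
#'
#' @param score_matrix patients x models scores; columns must cover the
#'   weight names.
#' @param weights named weights from [compute_weights()].
#' @return numeric ensemble score vector, one per patient (named by
#'   patient when ids are available).
#' @export
ensemble_scores <- function(score_matrix, weights) {
  rm <- rank_normalize(score_matrix)
  missing <- setdiff(names(weights), colnames(rm))
  if (length(missing) > 0)
    stop("score matrix lacks model column(s): ",
         paste(missing, collapse = ", "))
  drop(rm[, names(weights), drop = FALSE] %*% weights)
}
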