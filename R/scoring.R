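#' Precision-recall curve with tie-grouped step integration
#'
#' Computes the precision-recall curve of a continuous risk score against a
#' binary outcome, grouping tied scores so that all patients sharing a score
#' enter the curve at a single threshold.  The area under the curve (AUPRC)
#' is the step integral of precision over recall (the average-precision
#' form), which is deterministic under ties and is the form commonly used to
#' score community challenges on imbalanced outcomes: for a random ranking
#' its expectation equals the positive-class prevalence.
#'
#' @param scores numeric vector of risk scores (higher = higher predicted
#'   risk).
#' @param labels binary vector (0/1 or logical) of the same length; 1 marks
#'   an early-discontinuation event.
#' @return An object of class `"pr_curve"`: a list with `thresholds`
#'   (descending score cut-points, one per tie group), `recall`
#'   (nondecreasing, ending at 1), `precision`, and `auprc`.
#' @examples
#' pr <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' pr$auprc  # (1 + 2/3) / 2
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  if (sum(labels) == 0L)
    stop("precision-recall curve undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at the end of each tie group
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / sum(labels)
  d_rec <- diff(c(0, rec))
  structure(
    list(thresholds = s[grp_end], recall = rec, precision = prec,
         auprc = sum(d_rec * prec)),
    class = "pr_curve")
}

#' Area under the precision-recall curve
#'
#' Convenience wrapper around [pr_curve()] returning only the area.
#'
#' @inheritParams pr_curve
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) pr_curve(scores, labels)$auprc

#' Area under the receiver operating characteristic curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counting one half.
#'
#' @inheritParams pr_curve
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  if (n1 == 0L || n0 == 0L)
    stop("AUROC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Null distribution of AUPRC under a random prediction model
#'
#' Draws `replicates` independent random score vectors (uniform scores,
#' equivalent to random rank permutations), scores each against a fixed
#' label vector with the given class composition, and collects the AUPRC
#' samples.  The mean converges to slightly above the prevalence
#' `n_positives / n_patients` as the number of patients grows; on a
#' validation cohort of 470 patients with 49 events the mean is about
#' 0.104.
#'
#' @param n_patients number of patients.
#' @param n_positives number of positive labels (0 < n_positives <
#'   n_patients).
#' @param replicates number of random models to draw (default 5000).
#' @param seed integer seed.
#' @return An object of class `"null_dist"`: list with `n_patients`,
#'   `n_positives`, `replicates`, `auprc_samples`, `mean_auprc`.
#' @export
random_null <- function(n_patients, n_positives, replicates = 5000L,
                        seed = 1L) {
  stopifnot(n_patients >= 2, n_positives > 0, n_positives < n_patients,
            replicates >= 1)
  labels <- c(rep(1L, n_positives), rep(0L, n_patients - n_positives))
  samples <- with_seed(seed, vapply(
    seq_len(replicates),
    function(i) auprc(stats::runif(n_patients), labels),
    numeric(1)))
  structure(
    list(n_patients = as.integer(n_patients),
         n_positives = as.integer(n_positives),
         replicates = as.integer(replicates),
         auprc_samples = samples, mean_auprc = mean(samples)),
    class = "null_dist")
}

#' One-sided empirical p-value against a null distribution
#'
#' `p = (1 + #\{null >= observed\}) / (1 + replicates)`: the probability of
#' observing an AUPRC under the null at least as large as the one obtained,
#' with the add-one correction standard for permutation tests so that p is
#' never exactly zero.
#'
#' @param observed_auprc observed AUPRC.
#' @param null a `"null_dist"` from [random_null()], or a numeric vector of
#'   null samples.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_auprc, null) {
  samples <- if (inherits(null, "null_dist")) null$auprc_samples else null
  stopifnot(length(samples) >= 1)
  (1 + sum(samples >= observed_auprc)) / (1 + length(samples))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (monotone-enforced, capped at 1).
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Paired-bootstrap Bayes factor between two risk models
#'
#' Resamples patients with replacement and recomputes both models' AUPRC on
#' each resample.  The Bayes factor is the ratio of resamples in which model
#' A strictly outperforms model B to those in which B outperforms A — a
#' Bayes factor of 3 means A beat B at a 3-to-1 ratio; values below 3 are
#' conventionally read as statistically indistinguishable.  Ties count for
#' neither model; if B never wins the ratio is reported as the number of A
#' wins (capped at `replicates`).  Identical score vectors return 1.
#'
#' @param scores_a,scores_b numeric score vectors of equal length.
#' @param labels binary outcome vector.
#' @param replicates number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param paired if `TRUE` (default) both models are evaluated on shared
#'   patient resamples; if `FALSE` each model's bootstrap performance
#'   distribution is drawn on its own resamples and the two distributions
#'   are compared draw by draw.  The unpaired form asks whether the models'
#'   performance distributions overlap and is the forgiving comparison used
#'   to delimit a top set among correlated models; the paired form tests
#'   the per-resample difference and is far stricter when models are
#'   highly correlated.
#' @return Bayes factor of model A over model B.
#' @export
bayes_factor <- function(scores_a, scores_b, labels, replicates = 1000L,
                         seed = 1L, paired = TRUE) {
  labels <- check_scores_labels(scores_a, labels)
  check_scores_labels(scores_b, labels)
  if (sum(labels) == 0L || sum(labels) == length(labels))
    stop("Bayes factor requires both outcome classes")
  if (identical(rank(scores_a), rank(scores_b))) return(1)
  if (paired) {
    boot <- bootstrap_auprc(cbind(a = scores_a, b = scores_b), labels,
                            replicates, seed)
  } else {
    boot <- cbind(
      a = bootstrap_auprc(cbind(a = scores_a), labels, replicates, seed)[, 1],
      b = bootstrap_auprc(cbind(b = scores_b), labels, replicates,
                          seed + 1L)[, 1])
  }
  wins_a <- sum(boot[, "a"] > boot[, "b"])
  wins_b <- sum(boot[, "b"] > boot[, "a"])
  wins_a / max(wins_b, 1)
}

# Bootstrap AUPRC for columns of a score matrix on shared resamples.
# Resamples without both classes are redrawn (retry-capped).
bootstrap_auprc <- function(score_matrix, labels, replicates, seed,
                            columns = seq_len(ncol(score_matrix))) {
  score_matrix <- score_matrix[, columns, drop = FALSE]
  n <- length(labels)
  with_seed(seed, {
    out <- matrix(NA_real_, replicates, ncol(score_matrix),
                  dimnames = list(NULL, colnames(score_matrix)))
    for (r in seq_len(replicates)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(labels[idx]) %in% c(0L, n)) next
        break
      }
      yb <- labels[idx]
      out[r, ] <- apply(score_matrix[idx, , drop = FALSE], 2, auprc,
                        labels = yb)
    }
    out
  })
}

#' Rank risk models challenge-style and flag the top-performer set
#'
#' Scores every model (column of the score matrix) against the outcome,
#' ranks by AUPRC, attaches one-sided empirical p-values against a shared
#' random-model null, Benjamini-Hochberg adjusted p-values, and a bootstrap
#' Bayes factor of the top-ranked model against each other model.  Each
#' model's bootstrap AUPRC distribution is drawn on its own patient
#' resamples and the distributions are compared draw by draw (the unpaired
#' comparison; see [bayes_factor()]), so closely correlated, near-equal
#' models stay within the indistinguishability cut.  A model is flagged a
#' top performer when its adjusted p-value falls below `fdr_cut` and its
#' Bayes factor versus the best model is below `bf_cut` (the best model's
#' own Bayes factor is 1, a self-comparison).
#'
#' @param score_matrix numeric matrix or data frame, patients x models, with
#'   model identifiers as column names (a leading `patient_id` column in a
#'   data frame is dropped).
#' @param labels binary outcome vector, one per patient.
#' @param replicates bootstrap resamples for Bayes factors (default 1000).
#' @param null_replicates random-model draws for the null (default 5000).
#' @param fdr_cut significance cut on the adjusted p-value (default 0.10).
#' @param bf_cut Bayes-factor cut for indistinguishability (default 3).
#' @param seed integer seed.
#' @return A data frame of class `"leaderboard"` sorted by AUPRC
#'   (descending) with columns `model_id`, `auprc`, `auroc`, `p_value`,
#'   `p_adjusted`, `bayes_factor_vs_top`, `top_performer`.
#' @export
rank_teams <- function(score_matrix, labels, replicates = 1000L,
                       null_replicates = 5000L, fdr_cut = 0.10, bf_cut = 3,
                       seed = 1L) {
  m <- as_score_matrix(score_matrix)
  labels <- check_scores_labels(m[, 1], labels)
  if (ncol(m) == 0L) stop("empty score matrix")
  au <- apply(m, 2, auprc, labels = labels)
  ro <- apply(m, 2, auroc, labels = labels)
  null <- random_null(length(labels), sum(labels),
                      replicates = null_replicates, seed = seed + 1L)
  p <- vapply(au, empirical_pvalue, numeric(1), null = null)
  p_adj <- bh_adjust(p)
  ord <- order(au, decreasing = TRUE)
  top <- ord[1]
  boot <- vapply(seq_len(ncol(m)), function(j)
    bootstrap_auprc(m, labels, replicates, seed + 2L + j,
                    columns = j)[, 1],
    numeric(replicates))
  bf <- vapply(seq_len(ncol(m)), function(j) {
    if (j == top) return(1)
    wins_top <- sum(boot[, top] > boot[, j])
    wins_j <- sum(boot[, j] > boot[, top])
    wins_top / max(wins_j, 1)
  }, numeric(1))
  res <- data.frame(
    model_id = colnames(m), auprc = au, auroc = ro, p_value = p,
    p_adjusted = p_adj, bayes_factor_vs_top = bf,
    top_performer = p_adj < fdr_cut & bf < bf_cut,
    row.names = NULL)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("leaderboard", "data.frame")
  res
}

# ---- internal helpers -----------------------------------------------------

check_scores_labels <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (length(scores) == 0L) stop("empty input")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

as_score_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("patient_id" %in% names(x))
      x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  if (ncol(x) == 0L) stop("empty score matrix")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("model_", seq_len(ncol(x)))
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions do not clobber it.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
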