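#' Rank-normalize a score matrix
#'
#' Converts each model's scores to normalized ranks in (0, 1\]: average
#' ranks under ties, divided by the number of patients.  The result is
#' invariant to any strictly increasing transform of a model's raw scores,
#' which puts models with arbitrary score scales on a common footing before
#' clustering or averaging.
#'
#' @param score_matrix patients x models scores (data frame with a
#'   `patient_id` column, or plain matrix).
#' @return numeric matrix of normalized ranks with patient ids as row names
#'   (when available) and model ids as column names.
#' @export
rank_normalize <- function(score_matrix) {
  ids <- if (is.data.frame(score_matrix) &&
             "patient_id" %in% names(score_matrix))
    score_matrix$patient_id else NULL
  m <- as_score_matrix(score_matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty score matrix")
  out <- apply(m, 2, function(col) {
    if (anyNA(col)) stop("missing scores in a model column")
    rank(col, ties.method = "average") / length(col)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = list(ids, colnames(m)))
  out
}

#' Cluster patients on rank-normalized risk profiles
#'
#' Agglomerative hierarchical clustering of patient rows with Manhattan
#' (L1) pairwise distances and Ward's minimum-variance linkage
#' (Lance-Williams update on the supplied dissimilarities), cut at `k`
#' clusters.  Deterministic given the input order.
#'
#' @param rank_matrix patients x models matrix, typically from
#'   [rank_normalize()].
#' @param k number of clusters (1 <= k <= n).
#' @return integer vector of cluster labels (1..k), named by patient when
#'   row names are present.
#' @export
hierarchical_cluster <- function(rank_matrix, k) {
  n <- nrow(rank_matrix)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  hc <- stats::hclust(stats::dist(rank_matrix, method = "manhattan"),
                      method = "ward.D")
  stats::cutree(hc, k = k)
}

#' Choose the number of clusters by the elbow of the dispersion curve
#'
#' Computes the within-cluster dispersion (sum of L1 distances of each
#' patient to its cluster's componentwise median) for k = 1..`k_max` and
#' returns the k in 2..k_max-1 maximizing the second difference of the
#' curve — a formalization of the visual "where the variation begins to
#' flatten" rule.  When no pronounced elbow exists (maximum curvature below
#' `min_curvature` of the k = 1 dispersion) the smallest admissible k (2)
#' is returned with a low-confidence flag.
#'
#' @inheritParams hierarchical_cluster
#' @param k_max largest k examined (default 10; must be >= 3 and < n).
#' @param min_curvature relative curvature (maximum second difference of
#'   the dispersion curve over the k = 1 dispersion) below which the elbow
#'   is deemed absent (default 0.15; structureless matrices stay below
#'   ~0.07, well-separated planted blocks exceed ~0.3).
#' @return list with `k`, `dispersion` (length `k_max`), `curvature`
#'   (second differences, named by k), `low_confidence`.
#' @export
elbow_k <- function(rank_matrix, k_max = 10L, min_curvature = 0.15) {
  n <- nrow(rank_matrix)
  if (k_max < 3) stop("k_max must be at least 3")
  if (n < k_max) stop("fewer patients than k_max")
  hc <- stats::hclust(stats::dist(rank_matrix, method = "manhattan"),
                      method = "ward.D")
  disp <- vapply(seq_len(k_max), function(k) {
    lab <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(n), lab), function(idx) {
      block <- rank_matrix[idx, , drop = FALSE]
      med <- apply(block, 2, stats::median)
      sum(abs(sweep(block, 2, med)))
    }, numeric(1)))
  }, numeric(1))
  curv <- diff(disp, differences = 2)          # at k = 2..k_max-1
  names(curv) <- as.character(2:(k_max - 1))
  k_best <- as.integer(names(curv)[which.max(curv)])
  low <- max(curv) < min_curvature * disp[1]
  list(k = if (low) 2L else k_best, dispersion = disp, curvature = curv,
       low_confidence = low)
}

#' Label clusters as concordant-high, concordant-low, or discordant risk
#'
#' With a k = 3 clustering of rank-normalized risk profiles, the cluster
#' with the highest mean normalized rank is the concordant high-risk group,
#' the lowest the concordant low-risk group, and the remaining cluster the
#' discordant group.  The per-cluster cross-model rank dispersion (mean
#' over patients of the standard deviation of their row) is reported so the
#' discordant cluster's disagreement can be verified rather than assumed.
#'
#' @inheritParams hierarchical_cluster
#' @param labels integer cluster labels from a k = 3 clustering.
#' @return list with `group` (per-patient factor `high`/`low`/`discordant`),
#'   `cluster_summary` (data frame: cluster, n, mean_rank, dispersion,
#'   group).
#' @export
label_risk_groups <- function(rank_matrix, labels) {
  k <- length(unique(labels))
  if (k != 3L)
    stop("risk-group labelling expects a k = 3 clustering (got k = ", k, ")")
  mean_rank <- tapply(rowMeans(rank_matrix), labels, mean)
  if (max(mean_rank) - min(mean_rank) < 1e-8)
    stop("clusters are not separated; risk-group labelling refused")
  disp <- tapply(apply(rank_matrix, 1, stats::sd), labels, mean)
  cl <- as.integer(names(mean_rank))
  group_of <- rep("discordant", k)
  group_of[which.max(mean_rank)] <- "high"
  group_of[which.min(mean_rank)] <- "low"
  summary <- data.frame(cluster = cl, n = as.integer(table(labels)[as.character(cl)]),
                        mean_rank = as.numeric(mean_rank),
                        dispersion = as.numeric(disp), group = group_of)
  group <- factor(group_of[match(labels, cl)],
                  levels = c("high", "low", "discordant"))
  list(group = group, cluster_summary = summary)
}

#' Consensus risk grouping in one call
#'
#' Rank-normalizes a score matrix, clusters patients (Manhattan + Ward) at
#' k chosen by the elbow rule (or a forced `k`), and labels the three
#' groups.
#'
#' @inheritParams rank_normalize
#' @param k number of clusters; `NULL` (default) chooses by [elbow_k()].
#' @param k_max passed to [elbow_k()].
#' @return list with `group`, `cluster_summary`, `labels`, `elbow`,
#'   `rank_matrix`.
#' @export
consensus_groups <- function(score_matrix, k = NULL, k_max = 10L) {
  rm <- rank_normalize(score_matrix)
  elbow <- elbow_k(rm, k_max = k_max)
  if (is.null(k)) k <- elbow$k
  labels <- hierarchical_cluster(rm, k)
  grouping <- if (k == 3L) label_risk_groups(rm, labels)
    else list(group = NULL, cluster_summary = NULL)
  c(grouping, list(labels = labels, elbow = elbow, rank_matrix = rm))
}

#' Cumulative incidence under competing risks
#'
#' Aalen-Johansen nonparametric cumulative incidence of each competing
#' event type (early discontinuation due to adverse events, and death),
#' optionally stratified by patient group.  Naive per-cause 1 - Kaplan-Meier
#' estimates, which ignore the competing event and overstate incidence,
#' are returned alongside for comparison.
#'
#' @param times nonnegative event/censoring times in days.
#' @param event_types character vector: `discontinuation_AE`, `death`, or
#'   `censored`.
#' @param groups optional per-patient stratum (factor or character).
#' @return data frame with columns `group`, `event_type`, `time`, `cif`
#'   (Aalen-Johansen), `naive_1mkm` (1 - KM treating the competing event as
#'   censoring).
#' @export
cumulative_incidence <- function(times, event_types, groups = NULL) {
  if (any(times < 0)) stop("negative event times")
  valid <- c("censored", "discontinuation_AE", "death")
  if (!all(event_types %in% valid))
    stop("event_types must be one of: ", paste(valid, collapse = ", "))
  if (length(times) != length(event_types)) stop("length mismatch")
  if (is.null(groups)) groups <- rep("all", length(times))
  ev <- factor(event_types, levels = valid)
  present <- setdiff(levels(droplevels(ev)), "censored")
  out <- lapply(unique(groups), function(g) {
    sel <- groups == g
    fit <- survival::survfit(survival::Surv(times[sel], ev[sel]) ~ 1)
    states <- fit$states
    rows <- lapply(present, function(type) {
      j <- match(type, states)
      cif <- fit$pstate[, j]
      # naive 1 - KM: other event types treated as censoring
      status1 <- as.integer(event_types[sel] == type)
      km <- survival::survfit(survival::Surv(times[sel], status1) ~ 1)
      naive <- 1 - stats::stepfun(km$time, c(1, km$surv))(fit$time)
      data.frame(group = g, event_type = type, time = fit$time,
                 cif = cif, naive_1mkm = naive)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Evaluate a cumulative incidence estimate at given times
#'
#' Right-continuous step interpolation of a [cumulative_incidence()] table.
#'
#' @param cif_table output of [cumulative_incidence()].
#' @param event_type,group row selectors.
#' @param at times at which to evaluate.
#' @return numeric vector of cumulative incidence values.
#' @export
cif_at <- function(cif_table, event_type, at, group = "all") {
  sel <- cif_table$event_type == event_type & cif_table$group == group
  if (!any(sel)) return(rep(0, length(at)))
  tab <- cif_table[sel, , drop = FALSE]
  stats::stepfun(tab$time, c(0, tab$cif))(at)
}

#' Compare baseline variables across risk groups
#'
#' Continuous variables are compared across groups with the Kruskal-Wallis
#' rank-sum test, binary variables with a chi-squared test of the
#' contingency table; p-values are Benjamini-Hochberg adjusted across
#' variables and flagged at an adjusted 0.05.  Constant variables are
#' excluded and reported with a reason rather than tested.
#'
#' @param cohort data frame holding the variables.
#' @param groups per-patient group assignment (>= 2 levels present).
#' @param variables character vector of column names to test; by default
#'   every `x*`/`b*` baseline covariate column found.
#' @param alpha adjusted-p flag level (default 0.05).
#' @return data frame: `variable`, `type`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `note`.
#' @export
compare_baseline <- function(cohort, groups, variables = NULL,
                             alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("baseline comparison requires at least two groups")
  if (is.null(variables))
    variables <- grep("^(x|b)[0-9]+$", names(cohort), value = TRUE)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (length(unique(x)) < 2L)
      return(data.frame(variable = v, type = "constant",
                        statistic = NA_real_, p_value = NA_real_,
                        note = "constant variable excluded"))
    binary <- all(x %in% c(0, 1))
    if (binary) {
      tt <- suppressWarnings(stats::chisq.test(table(x, droplevels(groups))))
      data.frame(variable = v, type = "binary",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 note = "")
    } else {
      tt <- stats::kruskal.test(x, droplevels(groups))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 note = "")
    }
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_value)
  out$p_adjusted <- NA_real_
  out$p_adjusted[tested] <- bh_adjust(out$p_value[tested])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out[c("variable", "type", "statistic", "p_value", "p_adjusted",
        "significant", "note")]
}
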