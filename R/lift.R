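#' Cumulative lift ratio at a top fraction
#'
#' The lift ratio at fraction `t` is the share of all positives captured
#' among the top `t` fraction of patients ranked by predicted risk, divided
#' by `t` — equivalently, precision among the top `t` divided by
#' prevalence.  A random model has expected lift 1 at every fraction; a
#' perfect model attains `min(1/t, 1/prevalence)`.  Patients tied with the
#' boundary score are included pro rata (expected-value convention), so the
#' statistic is deterministic, invariant to input permutation, and exactly
#' conserves `lift(1) = 1`.
#'
#' @inheritParams pr_curve
#' @param fraction top fraction in (0, 1].
#' @return lift ratio (positive real).
#' @examples
#' lift_at(10:1, c(1, 1, rep(0, 8)), 0.2)  # both positives in the top 2: 5
#' @export
lift_at <- function(scores, labels, fraction) {
  labels <- check_scores_labels(scores, labels)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  npos <- sum(labels)
  if (npos == 0L) stop("lift undefined: no positive labels")
  n <- length(labels)
  k <- fraction * n                      # real-valued cut
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  grp_len <- rle(s)$lengths
  grp_end <- cumsum(grp_len)
  grp_pos <- cumsum(y)[grp_end] - c(0, cumsum(y)[grp_end])[seq_along(grp_end)]
  captured <- 0
  taken <- 0
  for (g in seq_along(grp_len)) {
    if (taken + grp_len[g] <= k) {
      captured <- captured + grp_pos[g]
      taken <- taken + grp_len[g]
    } else {
      captured <- captured + grp_pos[g] * (k - taken) / grp_len[g]
      break
    }
  }
  (captured / npos) / fraction
}

#' Cumulative lift-ratio curve with summary areas
#'
#' Evaluates the lift ratio on a grid of top fractions and computes
#' normalized areas under the lift-ratio curve: full range and restricted
#' to the top 20%.  Areas are trapezoid integrals divided by the upper
#' integration limit, so a flat random-model lift of 1 yields an area of 1
#' over any range.  Below the first grid point the curve is extended
#' flat at its first attainable value.
#'
#' @inheritParams lift_at
#' @param grid increasing fractions in (0, 1] (default 0.01 to 1 by 0.01).
#' @return list of class `"lift_curve"` with `fractions`, `lift`,
#'   `aulc_full`, `aulc_at_20`, `n`, `prevalence`.
#' @export
lift_curve <- function(scores, labels, grid = seq(0.01, 1, by = 0.01)) {
  labels <- check_scores_labels(scores, labels)
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid > 1))
    stop("grid must be increasing fractions in (0, 1]")
  lift <- vapply(grid, function(t) lift_at(scores, labels, t), numeric(1))
  curve <- structure(
    list(fractions = grid, lift = lift, n = length(labels),
         prevalence = mean(labels)),
    class = "lift_curve")
  curve$aulc_full <- aulc_at(curve, max(grid))
  curve$aulc_at_20 <- if (max(grid) >= 0.2) aulc_at(curve, 0.2) else NA_real_
  curve
}

#' Normalized area under a lift-ratio curve up to a fraction
#'
#' `(1/upto) * integral_0^upto lift(t) dt` by the trapezoid rule on the
#' curve's grid; the segment below the first grid point uses the first
#' attainable lift value (flat extension).
#'
#' @param curve a `"lift_curve"`.
#' @param upto upper fraction in (0, 1]; the grid must cover it.
#' @return normalized area (1 for a flat lift of 1).
#' @export
aulc_at <- function(curve, upto) {
  stopifnot(inherits(curve, "lift_curve"))
  if (upto <= 0 || upto > 1) stop("upto must lie in (0, 1]")
  f <- curve$fractions
  l <- curve$lift
  if (max(f) < upto) stop("lift grid does not cover upto = ", upto)
  keep <- f <= upto + 1e-12
  f2 <- f[keep]
  l2 <- l[keep]
  if (length(f2) == 0L) {
    # upto sits below the first grid point: flat extension throughout
    return(l[1])
  }
  if (abs(max(f2) - upto) > 1e-12) {     # interpolate the endpoint
    j <- which(f > upto)[1]
    l_end <- l2[length(l2)] +
      (l[j] - l2[length(l2)]) * (upto - f2[length(f2)]) / (f[j] - f2[length(f2)])
    f2 <- c(f2, upto)
    l2 <- c(l2, l_end)
  }
  area <- l2[1] * f2[1]                  # flat extension on [0, f_1]
  if (length(f2) > 1)
    area <- area + sum(diff(f2) * (utils::head(l2, -1) + utils::tail(l2, -1)) / 2)
  area / upto
}

#' Summarise lift for every model in a score matrix
#'
#' Point lifts at the top 5%, 10% and 20% plus normalized areas under the
#' lift-ratio curve (full and at 20%), one row per model.
#'
#' @param score_matrix patients x models scores (data frame with
#'   `patient_id` or plain matrix).
#' @param labels binary outcome vector.
#' @param grid fraction grid passed to [lift_curve()].
#' @return data frame with columns `model_id`, `lift_5`, `lift_10`,
#'   `lift_20`, `aulc_full`, `aulc_at_20`.
#' @export
lift_summary <- function(score_matrix, labels,
                         grid = seq(0.01, 1, by = 0.01)) {
  m <- as_score_matrix(score_matrix)
  rows <- lapply(colnames(m), function(id) {
    cv <- lift_curve(m[, id], labels, grid)
    data.frame(model_id = id,
               lift_5 = lift_at(m[, id], labels, 0.05),
               lift_10 = lift_at(m[, id], labels, 0.10),
               lift_20 = lift_at(m[, id], labels, 0.20),
               aulc_full = cv$aulc_full, aulc_at_20 = cv$aulc_at_20)
  })
  do.call(rbind, rows)
}
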