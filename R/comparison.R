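#' Non-inferiority conclusion from a CI lower limit
#'
#' Non-inferiority is shown when the lower confidence limit of the risk
#' difference lies strictly above the negated margin.  Missing margins give
#' `"not-evaluable"`.  The strict-inequality convention lives only here.
#'
#' @param lower CI lower limit(s) on the proportion scale.
#' @param margin_pct non-inferiority margin(s) in percentage points.
#' @return Character vector: `"shown"`, `"inconclusive"` or `"not-evaluable"`.
#' @export
ni_conclude <- function(lower, margin_pct) {
  stopifnot(all(is.na(margin_pct) | margin_pct > 0))
  out <- ifelse(is.na(margin_pct), "not-evaluable",
                ifelse(lower > -margin_pct / 100, "shown", "inconclusive"))
  out
}

#' Evaluate all comparisons of a trial dataset with the five CI methods
#'
#' Computes, for every comparison, the two-sided CI by the Wald,
#' Agresti-Caffo, Newcombe, Miettinen-Nurminen and SCAS methods, widths in
#' percentage points, width differences relative to Wald, non-inferiority
#' conclusions against the study margin and the most-conservative (widest)
#' method set.
#'
#' @param trials a `trial_data` data frame ([read_trials()], [as_trial_data()]
#'   or [generate_trials()]).
#' @param level two-sided confidence level, default 0.95.
#' @return An `rd_results` data frame, one row per comparison and method,
#'   carrying `lower`, `upper`, `width_pct`, `width_diff_vs_wald_pct`,
#'   `ni_shown`, `most_conservative` (logical, full arg-max set) and the
#'   stratification covariates `smallest_arm_n` and `avg_success_rate`.
#' @export
evaluate_trials <- function(trials, level = 0.95) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  .check_level(level)
  .check_table(trials$x1, trials$n1, trials$x2, trials$n2)
  ncmp <- nrow(trials)
  per_method <- lapply(RD_METHODS, function(m) {
    lim <- .limits_for(m, trials$x1, trials$n1, trials$x2, trials$n2, level)
    data.frame(
      comparison_id = trials$comparison_id,
      study_id = trials$study_id,
      method = m,
      estimate = trials$x1 / trials$n1 - trials$x2 / trials$n2,
      lower = lim[, 1], upper = lim[, 2],
      width = lim[, 2] - lim[, 1],
      level = level,
      margin_pct = trials$margin_pct,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_method)
  res$width_pct <- 100 * res$width
  wald_w <- res$width[res$method == "wald"]
  res$width_diff_vs_wald_pct <- 100 * (res$width - rep(wald_w, length(RD_METHODS)))
  res$ni_shown <- ni_conclude(res$lower, res$margin_pct)
  # widest-method set per comparison (ties kept)
  wmat <- matrix(res$width, nrow = ncmp,
                 dimnames = list(NULL, RD_METHODS))
  wmax <- apply(wmat, 1, max)
  res$most_conservative <- as.vector(wmat >= rep(wmax, length(RD_METHODS)) - 1e-15)
  res$smallest_arm_n <- rep(pmin(trials$n1, trials$n2), length(RD_METHODS))
  res$avg_success_rate <- rep((trials$x1 + trials$x2) / (trials$n1 + trials$n2),
                              length(RD_METHODS))
  res$randomization_label <- rep(trials$randomization_label, length(RD_METHODS))
  res <- res[order(match(res$comparison_id, trials$comparison_id),
                   match(res$method, RD_METHODS)), ]
  rownames(res) <- NULL
  class(res) <- c("rd_results", "data.frame")
  res
}

# interpolation-based quantiles (type 7); isolated so the summary's quantile
# convention is stated in one place
.q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))

#' Per-method summary of widths, conservatism and conclusions
#'
#' Reproduces the structure of a per-method comparison table: median and IQR
#' of CI widths (percentage points) over all comparisons, median and IQR of
#' the width difference versus Wald, counts of non-inferiority shown over
#' margin-evaluable comparisons, and counts of being the single most
#' conservative method (exact width ties broken by the fixed order
#' MN > SCAS > Newcombe > AC > Wald, a reporting convention).
#'
#' @param results an `rd_results` data frame from [evaluate_trials()].
#' @return Data frame, one row per method.
#' @export
summarize_methods <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  ids <- unique(results$comparison_id)
  # single most-conservative winner per comparison
  widest <- vapply(ids, function(id) {
    rows <- results[results$comparison_id == id, ]
    cand <- rows$method[rows$most_conservative]
    RD_CONSERVATISM_ORDER[min(match(cand, RD_CONSERVATISM_ORDER))]
  }, character(1))
  out <- do.call(rbind, lapply(RD_METHODS, function(m) {
    r <- results[results$method == m, ]
    ev <- r[r$ni_shown != "not-evaluable", ]
    data.frame(
      method = m,
      n_comparisons = nrow(r),
      width_median = .q(r$width_pct, 0.5),
      width_q25 = .q(r$width_pct, 0.25),
      width_q75 = .q(r$width_pct, 0.75),
      diff_vs_wald_median = .q(r$width_diff_vs_wald_pct, 0.5),
      diff_vs_wald_q25 = .q(r$width_diff_vs_wald_pct, 0.25),
      diff_vs_wald_q75 = .q(r$width_diff_vs_wald_pct, 0.75),
      ni_shown_n = sum(ev$ni_shown == "shown"),
      ni_evaluable = nrow(ev),
      ni_shown_pct = 100 * sum(ev$ni_shown == "shown") / max(nrow(ev), 1),
      most_conservative_n = sum(widest == m),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Five-method concordance on the non-inferiority conclusion
#'
#' A margin-evaluable comparison is concordant when all five methods reach
#' the same conclusion (all shown, or all inconclusive).
#'
#' @param results an `rd_results` data frame.
#' @param margin_pct optional fixed margin (percentage points) applied to all
#'   comparisons instead of each study's own margin.
#' @return List with `evaluable`, `concordant`, `agreement` (proportion) and
#'   `discordant`, a data frame of per-method conclusions for the discordant
#'   comparisons.
#' @export
concordance <- function(results, margin_pct = NULL) {
  stopifnot(is.data.frame(results))
  res <- results
  if (!is.null(margin_pct)) {
    stopifnot(length(margin_pct) == 1, margin_pct >= 0)
    res$ni_shown <- if (margin_pct == 0)
      ifelse(res$lower > 0, "shown", "inconclusive")
    else ni_conclude(res$lower, margin_pct)
  }
  res <- res[res$ni_shown != "not-evaluable", ]
  ids <- unique(res$comparison_id)
  per <- vapply(ids, function(id) {
    concl <- res$ni_shown[res$comparison_id == id]
    length(unique(concl)) == 1
  }, logical(1))
  disc_ids <- ids[!per]
  disc <- res[res$comparison_id %in% disc_ids,
              c("comparison_id", "method", "lower", "margin_pct", "ni_shown")]
  rownames(disc) <- NULL
  list(evaluable = length(ids),
       concordant = sum(per),
       agreement = if (length(ids)) sum(per) / length(ids) else NA_real_,
       discordant = disc)
}

#' Sweep the non-inferiority margin over a grid
#'
#' For each margin on the grid (applied to every comparison), computes the
#' proportion of comparisons where each method shows non-inferiority and the
#' proportion where all five methods agree on the conclusion.
#'
#' @param results an `rd_results` data frame.
#' @param margins_pct margin grid in percentage points, default `0:20`.
#' @return An `rd_sweep` data frame: one row per margin with per-method
#'   `ni_<method>` proportions and `agreement`.
#' @export
margin_sweep <- function(results, margins_pct = 0:20) {
  stopifnot(is.data.frame(results), all(margins_pct >= 0))
  ids <- unique(results$comparison_id)
  ncmp <- length(ids)
  lower <- matrix(results$lower[order(match(results$comparison_id, ids),
                                      match(results$method, RD_METHODS))],
                  nrow = ncmp, byrow = TRUE, dimnames = list(ids, RD_METHODS))
  rows <- lapply(margins_pct, function(m) {
    shown <- lower > -m / 100          # margin 0: shown iff lower > 0
    agree <- rowSums(shown) %in% c(0L, length(RD_METHODS))
    row <- data.frame(margin_pct = m, stringsAsFactors = FALSE)
    for (meth in RD_METHODS) row[[paste0("ni_", meth)]] <- mean(shown[, meth])
    row$agreement <- mean(agree)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rd_sweep", "data.frame")
  out
}
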