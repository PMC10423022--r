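# Two-alternative forced-choice harness: score how often a metric prefers
# the same prediction as human observers.

trial_masks <- function(trial) {
  stopifnot(is.list(trial), !is.null(trial$gt))
  trial[c("gt", "pred_a", "pred_b")]
}

#' Which prediction does a metric prefer?
#'
#' Computes the metric for (gt, pred_a) and (gt, pred_b) and prefers the
#' better side according to the metric's direction tag (`rvd` compares by
#' absolute value). Exact equality is a tie.
#'
#' @param trial one element of a `preference_trials` list (fields `gt`,
#'   `pred_a`, `pred_b` as [binary_mask()]s).
#' @param metric metric id (see [metric_direction()]).
#' @param tau tolerance for `metric = "phd"`.
#' @param skeletonize use the "-SK" variant of a plain metric.
#' @return `"A"`, `"B"` or `"tie"`.
#' @export
metric_preference <- function(trial, metric, tau = 3, skeletonize = FALSE) {
  masks <- trial_masks(trial)
  vals <- tryCatch(
    c(a = evaluate_masks(masks$pred_a, masks$gt, metric, tau = tau,
                         skeletonize = skeletonize),
      b = evaluate_masks(masks$pred_b, masks$gt, metric, tau = tau,
                         skeletonize = skeletonize)),
    error = function(e) {
      stop("metric '", metric, "' failed on trial ", trial$trial_id, ": ",
           conditionMessage(e))
    })
  if (metric == "rvd") vals <- abs(vals)
  if (vals["a"] == vals["b"]) return("tie")
  better_low <- metric_direction(metric) == "lower" || metric == "rvd"
  a_better <- if (better_low) vals["a"] < vals["b"] else vals["a"] > vals["b"]
  if (a_better) "A" else "B"
}

#' Consistency of a metric with human preference
#'
#' Default scoring is per-response: the fraction of all recorded human
#' responses that chose the side the metric prefers, with ties contributing
#' half their votes (`tie = "drop"` excludes tied trials instead).
#' `per_trial_majority = TRUE` scores agreement with each trial's majority
#' vote instead, one unit per trial.
#'
#' @param trials a `preference_trials` list ([make_trials()] or
#'   [read_trials()]).
#' @param metric metric id.
#' @param tau tolerance for `metric = "phd"`.
#' @param skeletonize use the "-SK" variant.
#' @param tie `"half"` (default) or `"drop"`.
#' @param per_trial_majority score against per-trial majorities instead of
#'   individual responses.
#' @return Scalar in \[0, 1\].
#' @export
consistency_score <- function(trials, metric, tau = 3, skeletonize = FALSE,
                              tie = c("half", "drop"),
                              per_trial_majority = FALSE) {
  tie <- match.arg(tie)
  if (length(trials) < 1L) stop("need at least one trial")
  prefs <- vapply(trials, metric_preference, character(1),
                  metric = metric, tau = tau, skeletonize = skeletonize)
  va <- vapply(trials, function(t) as.numeric(t$votes_a), numeric(1))
  vb <- vapply(trials, function(t) as.numeric(t$votes_b), numeric(1))
  if (any(va + vb < 1)) stop("every trial needs at least one recorded vote")
  if (per_trial_majority) {
    maj <- ifelse(va > vb, "A", ifelse(vb > va, "B", "tie"))
    unit <- ifelse(prefs == "tie" | maj == "tie", 0.5, (prefs == maj) * 1)
    keep <- if (tie == "drop") prefs != "tie" & maj != "tie" else TRUE
    return(mean(unit[keep]))
  }
  agree <- ifelse(prefs == "A", va, ifelse(prefs == "B", vb, (va + vb) / 2))
  if (tie == "drop") {
    keep <- prefs != "tie"
    if (!any(keep)) stop("all trials tied; no responses left to score")
    return(sum(agree[keep]) / sum((va + vb)[keep]))
  }
  sum(agree) / sum(va + vb)
}
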