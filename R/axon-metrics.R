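#' Fraction of the distal axon remaining at a session
#'
#' remaining / total for the disconnected distal segment; 0 means complete
#' Wallerian degeneration.
#'
#' @param record An `axon_lesion_record`.
#' @param session Session time in days post-lesion.
#' @return A fraction in `[0, 1]`.
#' @export
degeneration_fraction <- function(record, session) {
  stopifnot(inherits(record, "axon_lesion_record"))
  if (record$distal_length_um <= 0) stop("distal length must be > 0", call. = FALSE)
  k <- match_session(session, record$session_times_days)
  rem <- record$distal_remaining_um[k]
  if (rem > record$distal_length_um + 1e-9)
    stop("remaining distal length exceeds total: data error", call. = FALSE)
  rem / record$distal_length_um
}

#' Cohort fraction with complete distal degeneration by a given day
#'
#' @param cohort A `lesion_cohort`.
#' @param by_day Day post-lesion (default 1).
#' @return Fraction of axons whose distal segment is fully degenerated at
#'   the last session at or before `by_day`.
#' @export
complete_degeneration_fraction <- function(cohort, by_day = 1) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  done <- vapply(cohort, function(r) {
    k <- which(r$session_times_days <= by_day + 1e-9)
    length(k) > 0 && min(r$distal_remaining_um[k]) <= 0
  }, logical(1))
  mean(done)
}

#' Proximal-stump retraction distance and phase deltas
#'
#' Distance from the proximal tip to the lesion site at `session`, plus
#' the biphasic decomposition: acute = tip distance at the day-1 session,
#' chronic = final-session distance minus the day-1 distance.
#'
#' @inheritParams degeneration_fraction
#' @return List with `distance_um`, `acute_um`, `chronic_um`.
#' @export
retraction_distance <- function(record, session) {
  stopifnot(inherits(record, "axon_lesion_record"))
  k <- match_session(session, record$session_times_days)
  t1 <- which(record$session_times_days >= 1)[1]
  acute <- if (is.na(t1)) NA_real_ else record$tip_distance_um[t1]
  final <- record$tip_distance_um[length(record$tip_distance_um)]
  list(distance_um = record$tip_distance_um[k],
       acute_um = acute,
       chronic_um = final - acute)
}

#' Call attempted regeneration of the proximal stump
#'
#' Regrowth is called when any between-session elongation of the proximal
#' stump strictly exceeds the regrowth threshold -- twice the maximum
#' session-to-session measurement noise (`2 x 3 um = 6 um`).  Elongation
#' is a decrease in tip-to-lesion distance between consecutive sessions.
#' Branch growth events are reported alongside but never set the flag:
#' only the proximal stump counts as regeneration.
#'
#' @inheritParams degeneration_fraction
#' @param threshold_um Strict elongation threshold (default
#'   [regrowth_threshold_um()]).
#' @return List with `regenerated` (logical), `max_elongation_um`, and
#'   `branch_growth_events` (data.frame or NULL).
#' @export
call_regeneration <- function(record, threshold_um = regrowth_threshold_um()) {
  stopifnot(inherits(record, "axon_lesion_record"))
  tip <- record$tip_distance_um
  if (length(tip) < 2L) stop("need >= 2 sessions", call. = FALSE)
  elong <- -diff(tip)  # positive = tip moved back toward the lesion
  list(regenerated = any(elong > threshold_um),
       max_elongation_um = max(elong),
       branch_growth_events = record$branch_growth_events)
}

#' Regrowth-calling threshold
#'
#' Twice the maximum measurement noise between fiducial points over
#' repeated imaging sessions (noise 3 um, threshold 6 um, strict).
#' @return Threshold in micrometres.
#' @export
regrowth_threshold_um <- function() 2 * 3

#' Binomial test for an observed regeneration deficit or excess
#'
#' Probability of observing a result at least as extreme as `n_regen`
#' regenerating axons out of `n_total` under an expected per-axon
#' regeneration probability `p_expected`.  The default (`"auto"`) is
#' one-sided in the direction of the observed deviation: the lower tail
#' `P(X <= n_regen)` for a deficit (so `n_regen = 0` gives `(1 - p)^n`),
#' the upper tail for an excess.  `"less"`, `"greater"` and
#' `"two.sided"` force a tail.
#'
#' @param n_regen Observed number of regenerating axons.
#' @param n_total Cohort size.
#' @param p_expected Expected regeneration probability.
#' @param alternative `"auto"` (default), `"less"`, `"greater"` or
#'   `"two.sided"`.
#' @return The p value.
#' @export
regeneration_binomial_test <- function(n_regen, n_total, p_expected,
                                       alternative = c("auto", "less",
                                                       "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (n_regen < 0 || n_regen > n_total)
    stop("n_regen must lie in [0, n_total]", call. = FALSE)
  if (p_expected < 0 || p_expected > 1)
    stop("p_expected must lie in [0, 1]", call. = FALSE)
  if (alternative == "auto")
    alternative <- if (n_regen <= n_total * p_expected) "less" else "greater"
  switch(alternative,
    less = stats::pbinom(n_regen, n_total, p_expected),
    greater = stats::pbinom(n_regen - 1, n_total, p_expected,
                            lower.tail = FALSE),
    two.sided = stats::binom.test(n_regen, n_total, p_expected,
                                  alternative = "two.sided")$p.value)
}
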