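#' Generate a cohort of lesioned axons with degeneration and retraction
#'
#' Emulates the post-axotomy time courses the axon-level metrics consume:
#' Wallerian degeneration of the disconnected distal segment and biphasic
#' retraction of the proximal stump (an acute jump by day 1, then a slow
#' chronic drift).  A configured fraction of the cohort reaches complete
#' distal degeneration by the day-1 session (assignment is deterministic
#' under the seed: the first `round(frac * n)` axons); the remainder
#' complete by the following session.  All axons show at least 50%
#' degeneration at the first post-lesion session.
#'
#' @param params A [synth_params()] object (supplies the seed and the
#'   distal-length distribution via `axon_length_um` scaled to the
#'   disconnected segment).
#' @param n_axons Number of axons in the cohort.
#' @param frac_fully_degenerated_day1 Fraction reaching complete distal
#'   degeneration by the day-1 session.
#' @param retraction_profile Numeric length 4:
#'   `(acute_mean, acute_sd, chronic_mean, chronic_sd)` in micrometres;
#'   acute = tip distance at day 1, chronic = additional retraction
#'   between day 1 and the final session.
#' @param session_times_days Measurement times (days post-lesion).
#' @param distal_length_um Mean and sd of the disconnected distal length.
#' @param branch_growth Optional data.frame of branch (not proximal-stump)
#'   growth events with columns `axon_id`, `t_start`, `t_end`,
#'   `growth_um`; attached to the matching records.
#' @return A `lesion_cohort`: list of `axon_lesion_record` objects. Each
#'   record has `axon_id`, `distal_length_um`, `session_times_days`,
#'   `distal_remaining_um`, `tip_distance_um`, `branch_growth_events`,
#'   `fully_degenerated_by` (session index or `NA`).
#' @export
generate_lesion_cohort <- function(params,
                                   n_axons,
                                   frac_fully_degenerated_day1 = 12 / 14,
                                   retraction_profile = c(36, 25, 17, 11),
                                   session_times_days = c(0, 0.25, 1, 2, 4, 11, 32, 90),
                                   distal_length_um = c(314, 111),
                                   branch_growth = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (frac_fully_degenerated_day1 < 0 || frac_fully_degenerated_day1 > 1)
    stop("frac_fully_degenerated_day1 must lie in [0, 1]", call. = FALSE)
  n_axons <- as.integer(n_axons)
  if (n_axons == 0L) {
    out <- list()
    class(out) <- "lesion_cohort"
    return(out)
  }
  set.seed(params$seed + 1L)
  times <- session_times_days
  day1 <- which(times >= 1)[1]
  if (is.na(day1)) stop("session_times_days must include a time >= 1 day", call. = FALSE)
  n_fast <- round(frac_fully_degenerated_day1 * n_axons)

  records <- vector("list", n_axons)
  for (a in seq_len(n_axons)) {
    axon_id <- sprintf("lesioned%02d", a)
    dlen <- max(10, stats::rnorm(1, distal_length_um[1], distal_length_um[2]))
    complete_by <- if (a <= n_fast) day1 else min(day1 + 1L, length(times))

    # remaining distal length: >=50% gone at the first post-lesion session,
    # zero from `complete_by` onward, monotone in between
    frac_6h <- stats::runif(1, 0.05, 0.5)
    remaining <- numeric(length(times))
    for (k in seq_along(times)) {
      remaining[k] <- if (k == 1L) dlen
      else if (k >= complete_by) 0
      else dlen * frac_6h * (complete_by - k) / (complete_by - 1)
    }

    acute <- max(0, stats::rnorm(1, retraction_profile[1], retraction_profile[2]))
    chronic <- max(0, stats::rnorm(1, retraction_profile[3], retraction_profile[4]))
    tip <- numeric(length(times))
    t_final <- times[length(times)]
    for (k in seq_along(times)) {
      tk <- times[k]
      tip[k] <- if (tk < 1) acute * tk  # partial acute retraction pre-day-1
      else if (t_final > 1) acute + chronic * log1p(tk - 1) / log1p(t_final - 1)
      else acute
    }

    events <- NULL
    if (!is.null(branch_growth)) {
      events <- branch_growth[branch_growth$axon_id == axon_id, , drop = FALSE]
      if (nrow(events) == 0L) events <- NULL
    }
    rec <- list(
      axon_id = axon_id,
      distal_length_um = dlen,
      session_times_days = times,
      distal_remaining_um = remaining,
      tip_distance_um = tip,
      branch_growth_events = events,
      fully_degenerated_by = complete_by
    )
    class(rec) <- "axon_lesion_record"
    records[[a]] <- rec
  }
  class(records) <- "lesion_cohort"
  records
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("Lesioned-axon cohort: %d axons\n", length(x)))
  if (length(x)) {
    done1 <- vapply(x, function(r) {
      t1 <- which(r$session_times_days >= 1)[1]
      !is.na(r$fully_degenerated_by) && r$fully_degenerated_by <= t1
    }, logical(1))
    cat(sprintf("  complete distal degeneration by day 1: %d/%d (%.0f%%)\n",
                sum(done1), length(x), 100 * mean(done1)))
  }
  invisible(x)
}

#' @export
print.axon_lesion_record <- function(x, ...) {
  cat(sprintf("Lesioned axon %s: distal %.0f um, tip at final session %.1f um\n",
              x$axon_id, x$distal_length_um,
              x$tip_distance_um[length(x$tip_distance_um)]))
  invisible(x)
}

#' Tabulate a lesion cohort / rebuild one from its table
#'
#' One row per axon x session; used for the cohort CSV round trip.
#' @param cohort A `lesion_cohort`.
#' @param path CSV path.
#' @return A data.frame (`lesion_cohort_table`), or the path invisibly.
#' @export
lesion_cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(axon_id = r$axon_id,
               session_time_days = r$session_times_days,
               distal_length_um = r$distal_length_um,
               distal_remaining_um = r$distal_remaining_um,
               tip_distance_um = r$tip_distance_um)
  }))
}

#' @rdname lesion_cohort_table
#' @export
write_lesion_csv <- function(cohort, path) {
  utils::write.csv(lesion_cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname lesion_cohort_table
#' @export
read_lesion_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  records <- lapply(split(tab, tab$axon_id), function(d) {
    d <- d[order(d$session_time_days), ]
    complete <- which(d$distal_remaining_um <= 0)
    rec <- list(
      axon_id = d$axon_id[1],
      distal_length_um = d$distal_length_um[1],
      session_times_days = d$session_time_days,
      distal_remaining_um = d$distal_remaining_um,
      tip_distance_um = d$tip_distance_um,
      branch_growth_events = NULL,
      fully_degenerated_by = if (length(complete)) complete[1] else NA_integer_
    )
    class(rec) <- "axon_lesion_record"
    rec
  })
  names(records) <- NULL
  class(records) <- "lesion_cohort"
  records
}
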