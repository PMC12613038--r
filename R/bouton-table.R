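#' Per-axon metric table across sessions and intervals
#'
#' Computes, for each axon of a dataset, the standard longitudinal bouton
#' metrics: per-session density and stable fraction, per-interval TOR,
#' gains/losses fractions and mean size ratio, and the pre-lesion
#' aggregates used for figure-style summaries (density and stability over
#' the pre-lesion sessions; daily TOR over the pre-lesion one-day
#' intervals; gains/losses over all pre-lesion intervals).  Optionally
#' restricted to the close or far group at `close_threshold_um`.
#'
#' @param dataset A `bouton_dataset`.
#' @param group `"all"`, `"close"` or `"far"`.
#' @param close_threshold_um Distance cut for the close/far split.
#' @return A list of tidy data.frames: `sessions` (axon_id,
#'   session_time_days, density, stable_fraction, persistent_fraction,
#'   mean_intensity), `intervals` (axon_id, t_a, t_b, tor, gains, losses,
#'   mean_size_ratio), `prelesion` (axon_id, density, daily_tor, gains,
#'   losses).
#' @export
bouton_metric_table <- function(dataset, group = c("all", "close", "far"),
                                close_threshold_um = 250) {
  group <- match.arg(group)
  axon_ids <- dataset$axons$axon_id
  sess_rows <- list(); int_rows <- list(); pre_rows <- list()
  for (ax in axon_ids) {
    m <- axon_matrices(dataset, ax)
    ids <- if (group == "all") NULL
           else split_by_distance(dataset, ax, close_threshold_um)[[group]]
    keep <- if (is.null(ids)) rep(TRUE, nrow(m$presence))
            else rownames(m$presence) %in% ids
    pres <- m$presence[keep, , drop = FALSE]
    times <- m$times
    n_sess <- length(times)

    stable_at <- function(k) {
      prev <- if (k > 1L) pres[, k - 1L] else FALSE
      nxt <- if (k < n_sess) pres[, k + 1L] else FALSE
      pres[, k] & (prev | nxt)
    }
    persistent <- rowSums(pres) == n_sess
    sess_rows[[length(sess_rows) + 1L]] <- data.frame(
      axon_id = ax,
      session_time_days = times,
      density = colSums(pres) / m$length_um,
      stable_fraction = vapply(seq_len(n_sess), function(k) {
        n <- sum(pres[, k]); if (n == 0) NA_real_ else sum(stable_at(k)) / n
      }, numeric(1)),
      persistent_fraction = vapply(seq_len(n_sess), function(k) {
        n <- sum(pres[, k]); if (n == 0) NA_real_ else sum(persistent & pres[, k]) / n
      }, numeric(1)),
      mean_intensity = vapply(seq_len(n_sess), function(k) {
        v <- m$intensity[keep, k][pres[, k]]
        if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1))
    )

    for (k in seq_len(n_sess - 1L)) {
      pair <- c(times[k], times[k + 1L])
      tor <- suppressWarnings(turnover_rate(dataset, ax, pair, boutons = ids))
      gl <- suppressWarnings(gains_losses_fractions(dataset, ax, pair, boutons = ids))
      sr <- size_ratio(dataset, ax, pair, boutons = ids)
      int_rows[[length(int_rows) + 1L]] <- data.frame(
        axon_id = ax, t_a = pair[1], t_b = pair[2],
        tor = tor, gains = gl[["gains"]], losses = gl[["losses"]],
        mean_size_ratio = if (all(is.na(sr))) NA_real_ else mean(sr, na.rm = TRUE)
      )
    }
  }
  sessions <- do.call(rbind, sess_rows)
  intervals <- do.call(rbind, int_rows)

  # figure-legend aggregates: density over pre-lesion sessions; daily TOR
  # over the pre-lesion one-day intervals; gains/losses over all
  # pre-lesion intervals
  pre_rows <- lapply(axon_ids, function(ax) {
    s <- sessions[sessions$axon_id == ax & sessions$session_time_days <= 0, ]
    i <- intervals[intervals$axon_id == ax & intervals$t_b <= 0, ]
    daily <- i[abs((i$t_b - i$t_a) - 1) < 1e-9, ]
    data.frame(axon_id = ax,
               density = mean(s$density),
               daily_tor = mean(daily$tor, na.rm = TRUE),
               gains = mean(i$gains, na.rm = TRUE),
               losses = mean(i$losses, na.rm = TRUE))
  })
  list(sessions = sessions, intervals = intervals,
       prelesion = do.call(rbind, pre_rows))
}

#' Nonparametric test battery with Bonferroni adjustment
#'
#' Runs the named two-tailed test on each entry of `comparisons` and
#' reports the statistic, raw p value and the Bonferroni-adjusted p
#' (p x n, capped at 1), with n the number of comparisons in the battery.
#' Exact small-sample distributions are used where the underlying test
#' supports them (Wilcoxon/Mann-Whitney without ties, n per group <= 25);
#' the normal approximation is used otherwise.
#'
#' @param comparisons A named list; each element is a list with fields
#'   `test` (one of `"wilcoxon-signed-rank"`, `"mann-whitney-u"`,
#'   `"friedman"`, `"kruskal-wallis"`, `"pearson"`), `x`, and `y` (or, for
#'   friedman/kruskal, `groups`: a list of numeric vectors; friedman
#'   treats them as repeated measures on the same subjects).
#' @return A data.frame: `comparison`, `test`, `statistic`, `p`,
#'   `p_bonferroni`.
#' @export
stats_battery <- function(comparisons) {
  stopifnot(is.list(comparisons), length(comparisons) > 0)
  n <- length(comparisons)
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    res <- run_one_test(cmp)
    data.frame(comparison = nm, test = cmp$test,
               statistic = res$statistic, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * n)
  out
}

run_one_test <- function(cmp) {
  test <- match.arg(cmp$test, c("wilcoxon-signed-rank", "mann-whitney-u",
                                "friedman", "kruskal-wallis", "pearson"))
  exact_ok <- function(...) all(vapply(list(...), length, 1L) <= 25)
  switch(test,
    "wilcoxon-signed-rank" = {
      if (length(cmp$x) != length(cmp$y))
        stop("paired design requires equal lengths", call. = FALSE)
      if (all(cmp$x == cmp$y)) {
        warning("all paired differences are zero; p reported as 1")
        return(list(statistic = 0, p = 1))
      }
      ht <- stats::wilcox.test(cmp$x, cmp$y, paired = TRUE,
                               exact = exact_ok(cmp$x))
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    "mann-whitney-u" = {
      if (length(cmp$x) == 0 || length(cmp$y) == 0)
        stop("empty group", call. = FALSE)
      ht <- stats::wilcox.test(cmp$x, cmp$y,
                               exact = exact_ok(cmp$x, cmp$y))
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    "friedman" = {
      mat <- do.call(cbind, cmp$groups)
      ht <- stats::friedman.test(mat)
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    "kruskal-wallis" = {
      ht <- stats::kruskal.test(cmp$groups)
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    "pearson" = {
      ht <- stats::cor.test(cmp$x, cmp$y, method = "pearson")
      list(statistic = unname(ht$estimate), p = ht$p.value)
    })
}
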