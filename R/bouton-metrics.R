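#' Per-axon presence and intensity matrices
#'
#' Internal workhorse: reshapes the long bouton table of one axon into a
#' boutons x sessions presence (logical) and intensity (numeric) matrix,
#' ordered by session time.
#' @noRd
axon_matrices <- function(dataset, axon_id) {
  d <- dataset$boutons[dataset$boutons$axon_id == axon_id, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown axon_id: ", axon_id, call. = FALSE)
  times <- sort(unique(d$session_time_days))
  ids <- unique(d$bouton_id)
  pres <- matrix(FALSE, length(ids), length(times),
                 dimnames = list(ids, as.character(times)))
  inten <- matrix(NA_real_, length(ids), length(times),
                  dimnames = list(ids, as.character(times)))
  bi <- match(d$bouton_id, ids)
  si <- match(d$session_time_days, times)
  pres[cbind(bi, si)] <- d$present > 0
  inten[cbind(bi, si)] <- d$intensity
  dist <- d$distance_um[!duplicated(d$bouton_id)]
  names(dist) <- d$bouton_id[!duplicated(d$bouton_id)]
  list(presence = pres, intensity = inten, times = times,
       distance_um = dist[ids],
       length_um = dataset$axons$length_um[dataset$axons$axon_id == axon_id])
}

#' Bouton density of one axon at one session
#'
#' Density(a) = n_a / length_a, the number of boutons present in session
#' `a` per micrometre of mapped axon.
#'
#' @param dataset A `bouton_dataset`.
#' @param axon_id Axon identifier.
#' @param session Session time in days (must match a session in the data).
#' @return Density in boutons per micrometre.
#' @export
bouton_density <- function(dataset, axon_id, session) {
  m <- axon_matrices(dataset, axon_id)
  if (m$length_um <= 0) stop("axon length must be > 0", call. = FALSE)
  k <- match_session(session, m$times)
  sum(m$presence[, k]) / m$length_um
}

match_session <- function(session, times) {
  k <- which(abs(times - session) < 1e-9)
  if (length(k) != 1L)
    stop("session ", session, " not found in dataset", call. = FALSE)
  k
}

#' Bouton turnover rate between two sessions
#'
#' TOR(a, b) = (nG + nL) / (2 N), where nG and nL count boutons gained and
#' lost between sessions `a` and `b`, and N is the number of boutons
#' present at session `a`.  Undefined (NA, with a warning) when N = 0.
#'
#' @inheritParams bouton_density
#' @param pair Numeric length 2, session times `(a, b)` with `a < b`.
#' @param boutons Optional character vector restricting the computation to
#'   a subset of bouton ids (e.g. a close/far group).
#' @return The turnover rate, a fraction in `[0, 1]` for contiguous
#'   lifetimes.
#' @export
turnover_rate <- function(dataset, axon_id, pair, boutons = NULL) {
  gl <- gains_losses_counts(dataset, axon_id, pair, boutons)
  if (gl[["N"]] == 0L) {
    warning("no boutons present at session a; TOR undefined")
    return(NA_real_)
  }
  (gl[["nG"]] + gl[["nL"]]) / (2 * gl[["N"]])
}

gains_losses_counts <- function(dataset, axon_id, pair, boutons = NULL) {
  stopifnot(length(pair) == 2L, pair[1] < pair[2])
  m <- axon_matrices(dataset, axon_id)
  a <- match_session(pair[1], m$times)
  b <- match_session(pair[2], m$times)
  keep <- if (is.null(boutons)) rep(TRUE, nrow(m$presence))
          else rownames(m$presence) %in% boutons
  pa <- m$presence[keep, a]
  pb <- m$presence[keep, b]
  c(nG = sum(!pa & pb), nL = sum(pa & !pb), N = sum(pa))
}

#' Gains and losses fractions between two sessions
#'
#' Gains(a, b) = nG / N and Losses(a, b) = nL / N with N the bouton count
#' at session `a`.
#'
#' @inheritParams turnover_rate
#' @return Named numeric `(gains, losses)`.
#' @export
gains_losses_fractions <- function(dataset, axon_id, pair, boutons = NULL) {
  gl <- gains_losses_counts(dataset, axon_id, pair, boutons)
  if (gl[["N"]] == 0L) {
    warning("no boutons present at session a; fractions undefined")
    return(c(gains = NA_real_, losses = NA_real_))
  }
  c(gains = gl[["nG"]] / gl[["N"]], losses = gl[["nL"]] / gl[["N"]])
}

#' Size ratio of boutons between two sessions
#'
#' DeltaS = S_b / S_a per bouton, for boutons present (with positive
#' intensity) at both sessions; boutons absent at either session get NA.
#' When `normalize = TRUE` (default) intensities are first divided by the
#' axon's median intensity at each session, which removes session-wide
#' imaging-gain differences; the ratio of a single bouton is unaffected
#' only when the per-session medians differ, so the switch is exposed.
#'
#' @inheritParams turnover_rate
#' @param normalize Divide by the axon's per-session median intensity
#'   before forming ratios.
#' @return Named numeric vector of per-bouton size ratios (NA when
#'   undefined for the pair).
#' @export
size_ratio <- function(dataset, axon_id, pair, boutons = NULL, normalize = FALSE) {
  stopifnot(length(pair) == 2L, pair[1] < pair[2])
  m <- axon_matrices(dataset, axon_id)
  a <- match_session(pair[1], m$times)
  b <- match_session(pair[2], m$times)
  Sa <- m$intensity[, a]
  Sb <- m$intensity[, b]
  if (normalize) {
    Sa <- Sa / stats::median(Sa[m$presence[, a]], na.rm = TRUE)
    Sb <- Sb / stats::median(Sb[m$presence[, b]], na.rm = TRUE)
  }
  ok <- m$presence[, a] & m$presence[, b] & !is.na(Sa) & !is.na(Sb) & Sa > 0
  out <- ifelse(ok, Sb / Sa, NA_real_)
  names(out) <- rownames(m$presence)
  if (!is.null(boutons)) out <- out[names(out) %in% boutons]
  out
}

#' Classify boutons by their longitudinal presence pattern
#'
#' Assigns the standard stability classes from a presence pattern over the
#' imaging sessions (lesion at time 0):
#' \describe{
#'   \item{stable}{present for at least two consecutive sessions at some
#'     point of its lifetime (per-session stability is also returned).}
#'   \item{new}{first appears at a session strictly after time 0.}
#'   \item{new_stable}{new, and present for >= 2 consecutive sessions.}
#'   \item{persistent}{present in every session.}
#'   \item{destabilized}{present for >= 2 consecutive sessions within the
#'     first three sessions, and absent from the last two sessions.}
#' }
#'
#' @inheritParams bouton_density
#' @return A data.frame, one row per bouton: `bouton_id`, logical columns
#'   `stable`, `new`, `new_stable`, `persistent`, `destabilized`.
#' @export
classify_boutons <- function(dataset, axon_id) {
  m <- axon_matrices(dataset, axon_id)
  if (ncol(m$presence) < 2L) stop("need >= 2 sessions", call. = FALSE)
  cls <- t(apply(m$presence, 1L, classify_pattern, times = m$times))
  data.frame(bouton_id = rownames(m$presence),
             stable = as.logical(cls[, 1]),
             new = as.logical(cls[, 2]),
             new_stable = as.logical(cls[, 3]),
             persistent = as.logical(cls[, 4]),
             destabilized = as.logical(cls[, 5]),
             row.names = NULL)
}

# classification of a single 0/1 presence pattern; exported for reuse in
# property tests via classify_boutons()
classify_pattern <- function(p, times) {
  p <- as.logical(p)
  n <- length(p)
  runs <- rle(p)
  has2 <- any(runs$lengths >= 2 & runs$values)
  first <- if (any(p)) which(p)[1] else NA_integer_
  is_new <- !is.na(first) && times[first] > 0
  early <- p[seq_len(min(3L, n))]
  runs_e <- rle(early)
  early2 <- any(runs_e$lengths >= 2 & runs_e$values)
  last2_absent <- n >= 2 && !any(p[(n - 1L):n])
  c(stable = has2,
    new = is_new,
    new_stable = is_new && has2,
    persistent = all(p),
    destabilized = early2 && last2_absent)
}

#' Split an axon's boutons by distance from the lesion
#'
#' Partition at `threshold_um` from the lesion site; boutons at exactly
#' the threshold are assigned to the close group (`boundary = "close"`,
#' the default) so no bouton is dropped, or to the far group
#' (`boundary = "far"`).
#'
#' @inheritParams bouton_density
#' @param threshold_um Distance cut in micrometres (default 250).
#' @param boundary Which group receives boutons at exactly the threshold.
#' @return List with character vectors `close` and `far` of bouton ids.
#' @export
split_by_distance <- function(dataset, axon_id, threshold_um = 250,
                              boundary = c("close", "far")) {
  boundary <- match.arg(boundary)
  m <- axon_matrices(dataset, axon_id)
  d <- m$distance_um
  close <- if (boundary == "close") d <= threshold_um else d < threshold_um
  list(close = names(d)[close], far = names(d)[!close])
}
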