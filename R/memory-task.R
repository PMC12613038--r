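#' Construct the three memory patterns
#'
#' Draws three disjoint random subsets of `N_pattern` neurons from the
#' network and, within each, a fixed stimulated subset
#' (`N_pattern - N_test` neurons, ~60% of the pattern) and a withheld test
#' subset (`N_test` neurons).  Subsets are fixed once per simulation.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return A `pattern_set`: list of 3 lists, each with `neurons`,
#'   `stimulated`, `test` (integer indices).
#' @export
make_patterns <- function(cfg, seed) {
  stopifnot(inherits(cfg, "network_config"))
  pr <- cfg$protocol
  if (3L * pr$N_pattern > cfg$N)
    stop("N too small for 3 disjoint patterns", call. = FALSE)
  set.seed(seed)
  pool <- sample.int(cfg$N, 3L * pr$N_pattern)
  pats <- lapply(0:2, function(k) {
    neurons <- sort(pool[k * pr$N_pattern + seq_len(pr$N_pattern)])
    stim <- sort(sample(neurons, pr$N_pattern - pr$N_test))
    list(neurons = neurons, stimulated = stim,
         test = sort(setdiff(neurons, stim)))
  })
  structure(pats, class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: 3 patterns of %d neurons (%d stimulated / %d test each)\n",
              length(x[[1]]$neurons), length(x[[1]]$stimulated),
              length(x[[1]]$test)))
  invisible(x)
}

new_stim_protocol <- function(stimuli, targets, total_ms, noise_rate_hz,
                              noise_amp_pa, kind) {
  structure(list(stimuli = stimuli, targets = targets, total_ms = total_ms,
                 noise_rate_hz = noise_rate_hz, noise_amp_pa = noise_amp_pa,
                 kind = kind),
            class = "stim_protocol")
}

#' Build training and testing stimulation protocols
#'
#' Training presents each pattern `reps_train` times in randomized order
#' (stimulating the full pattern at the training rate/amplitude for
#' `sim_train` ms, separated by `g_train` ms), with background noise
#' throughout.  Testing presents each pattern `reps_test` times in fixed
#' order, stimulating only the ~60% stimulated subset for `sim_test` ms
#' with `g_test` ms gaps; plasticity is off during testing by convention
#' of the caller.  Noise is present in testing as in training when the
#' config's `noise_in_test` is TRUE (default).
#'
#' @param cfg A [network_config()].
#' @param patterns A [make_patterns()] result.
#' @param seed Seed for the randomized training order.
#' @param reps Optional override of the number of presentations per
#'   pattern (e.g. 1 for the single post-injury training repetition).
#' @return A `stim_protocol`: `stimuli` data.frame (`pattern`, `onset_ms`,
#'   `dur_ms`, `rate_hz`, `amp_pa`), `targets` (list of integer vectors),
#'   `total_ms`, `noise_rate_hz`, `noise_amp_pa`.
#' @export
build_training_protocol <- function(cfg, patterns, seed = 1L, reps = NULL) {
  stopifnot(inherits(cfg, "network_config"), inherits(patterns, "pattern_set"))
  pr <- cfg$protocol
  reps <- if (is.null(reps)) pr$reps_train else as.integer(reps)
  order <- if (reps > 0) {
    set.seed(seed)
    sample(rep(1:3, reps))
  } else integer(0)
  n_stim <- length(order)
  onsets <- (seq_len(n_stim) - 1L) * (pr$sim_train + pr$g_train)
  total <- if (reps == pr$reps_train) pr$Sim_train
           else if (n_stim > 0) onsets[n_stim] + pr$sim_train else 0
  if (n_stim > 0 && onsets[n_stim] + pr$sim_train > total + 1e-9)
    stop("training schedule overflows Sim_train", call. = FALSE)
  stimuli <- data.frame(pattern = order, onset_ms = onsets,
                        dur_ms = rep(pr$sim_train, n_stim),
                        rate_hz = rep(pr$r_ext_r, n_stim),
                        amp_pa = rep(pr$I_ext_r, n_stim))
  targets <- lapply(order, function(p) patterns[[p]]$neurons)
  new_stim_protocol(stimuli, targets, total, pr$r_noise, pr$I_noise, "training")
}

#' @rdname build_training_protocol
#' @export
build_testing_protocol <- function(cfg, patterns, reps = NULL) {
  stopifnot(inherits(cfg, "network_config"), inherits(patterns, "pattern_set"))
  pr <- cfg$protocol
  reps <- if (is.null(reps)) pr$reps_test else as.integer(reps)
  order <- rep(1:3, reps)
  n_stim <- length(order)
  onsets <- (seq_len(n_stim) - 1L) * (pr$sim_test + pr$g_test)
  total <- if (reps == pr$reps_test) pr$Sim_test
           else if (n_stim > 0) onsets[n_stim] + pr$sim_test else 0
  if (n_stim > 0 && onsets[n_stim] + pr$sim_test > total + 1e-9)
    stop("testing schedule overflows Sim_test", call. = FALSE)
  stimuli <- data.frame(pattern = order, onset_ms = onsets,
                        dur_ms = rep(pr$sim_test, n_stim),
                        rate_hz = rep(pr$r_ext_e, n_stim),
                        amp_pa = rep(pr$I_ext_e, n_stim))
  targets <- lapply(order, function(p) patterns[[p]]$stimulated)
  noise_rate <- if (isTRUE(pr$noise_in_test)) pr$r_noise else 0
  new_stim_protocol(stimuli, targets, total, noise_rate, pr$I_noise, "testing")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("%s protocol: %d stimuli over %.0f ms, noise %g Hz\n",
              x$kind, nrow(x$stimuli), x$total_ms, x$noise_rate_hz))
  invisible(x)
}

#' Associative-memory recall error
#'
#' For each pattern and each test presentation, the true-positive fraction
#' is the share of that pattern's withheld test neurons that fire at least
#' once inside the stimulation window.  With TP the per-pattern sum of
#' those fractions over presentations,
#' `E = 1 - TP / reps_test`, averaged over patterns; `E` lies in `[0, 1]`
#' (0 = perfect recall, 1 = no test neuron ever recalled).
#'
#' @param sim A `sim_result` from a testing run (or a data.frame of spikes
#'   with columns `neuron`, `time_ms`).
#' @param patterns The [make_patterns()] used to build the protocol.
#' @param protocol The testing `stim_protocol`.
#' @return The error E.
#' @export
compute_error <- function(sim, patterns, protocol) {
  spikes <- if (inherits(sim, "sim_result")) sim$spikes else sim
  stopifnot(inherits(protocol, "stim_protocol"))
  st <- protocol$stimuli
  if (nrow(st) == 0L) stop("protocol has no test stimuli", call. = FALSE)
  reps <- sum(st$pattern == st$pattern[1])
  tp_frac <- vapply(seq_len(nrow(st)), function(k) {
    test_n <- patterns[[st$pattern[k]]]$test
    inwin <- spikes$time_ms > st$onset_ms[k] &
      spikes$time_ms <= st$onset_ms[k] + st$dur_ms[k]
    length(intersect(unique(spikes$neuron[inwin]), test_n)) / length(test_n)
  }, numeric(1))
  per_pattern <- tapply(tp_frac, st$pattern, sum) / reps
  1 - mean(per_pattern)
}

#' Model-side synaptic turnover between two weight snapshots
#'
#' Mirrors the experimental turnover formula on the weight matrix: a gain
#' is a connection whose weight crosses the synaptic threshold upward
#' between the snapshots, a loss a downward crossing, and N the number of
#' supra-threshold connections in the first snapshot;
#' TOR = (nG + nL) / (2 N).
#'
#' @param W_before,W_after `weight_matrix` objects (or plain matrices) of
#'   the same dimension.
#' @param theta_synaptic Weight threshold in mV (default 0.4).
#' @return The turnover rate (NA with a warning when N = 0).
#' @export
model_turnover <- function(W_before, W_after, theta_synaptic = 0.4) {
  wb <- if (inherits(W_before, "weight_matrix")) W_before$w else W_before
  wa <- if (inherits(W_after, "weight_matrix")) W_after$w else W_after
  stopifnot(all(dim(wb) == dim(wa)))
  above_b <- wb >= theta_synaptic
  above_a <- wa >= theta_synaptic
  nG <- sum(!above_b & above_a)
  nL <- sum(above_b & !above_a)
  N <- sum(above_b)
  if (N == 0L) {
    warning("no supra-threshold connections in W_before; TOR undefined")
    return(NA_real_)
  }
  (nG + nL) / (2 * N)
}

#' Network connectivity of a weight matrix
#'
#' The fraction of existing connections whose weight is at or above the
#' synaptic threshold (`measure = "threshold"`, the default used
#' throughout), or the mean weight of existing connections
#' (`measure = "mean_weight"`).
#'
#' @param wm A `weight_matrix`.
#' @param theta_synaptic Threshold in mV.
#' @param measure `"threshold"` or `"mean_weight"`.
#' @return A scalar.
#' @export
connectivity <- function(wm, theta_synaptic = 0.4,
                         measure = c("threshold", "mean_weight")) {
  measure <- match.arg(measure)
  stopifnot(inherits(wm, "weight_matrix"))
  if (sum(wm$mask) == 0L) return(0)
  if (measure == "threshold") mean(wm$w[wm$mask] >= theta_synaptic)
  else mean(wm$w[wm$mask])
}
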