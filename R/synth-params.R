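#' Parameters for the synthetic bouton-tracking generator
#'
#' Bundles every knob of the longitudinal bouton-track generator into a
#' validated list. Defaults emulate the imaging study the package models:
#' 8 EPB-rich axons (~277 boutons in total) followed over 8 sessions at
#' -4, -2, -1, 0 days pre-lesion and +6 h, +1, +2, +4 days post-lesion,
#' with a lesion placed along each axon and bouton gains/losses governed
#' by per-day hazards that are transiently boosted after the lesion.
#'
#' Hazards are per-bouton, per-day probabilities; over an interval of
#' `dt` days the loss probability compounds as `1 - (1 - h)^dt`, and the
#' expected number of gains per axon is `N * (1 - (1 - g)^dt)` where `N`
#' is the bouton count entering the interval.  In the two post-lesion
#' windows (`[0, 6 h]` and `[6 h, 1 d]`) the daily hazards are multiplied
#' by the corresponding boost factors before compounding; boosts can be
#' distance-dependent via the `close`/`far` pairs, split at
#' `close_threshold_um` from the lesion site.
#'
#' @param n_axons Number of axons to generate.
#' @param axon_length_um Mean and sd (length-2 numeric) of axon length in
#'   micrometres; lengths are drawn from a normal truncated at
#'   `2 * lesion_offset_um` so the lesion always lies on the axon.
#' @param epb_density_per_um Expected boutons per micrometre of axon.
#' @param session_times Strictly increasing imaging times in days
#'   relative to the lesion (0 = lesion session).
#' @param lesion_offset_um Position of the lesion along each axon,
#'   measured from the distal end of the mapped proximal stretch.
#' @param close_threshold_um Distance cut separating boutons "close to"
#'   and "far from" the lesion (default 250).
#' @param baseline_gain_hazard,baseline_loss_hazard Per-day per-bouton
#'   gain/loss probabilities before the lesion (and after the boosted
#'   windows have elapsed).
#' @param post_lesion_gain_boost,post_lesion_loss_boost Length-2 numeric
#'   `(close, far)` multiplicative modifiers applied to the daily hazards
#'   in the `[0, 6 h]` and `[6 h, 1 d]` windows.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of
#'   bouton intensity (arbitrary units).
#' @param new_bouton_growth_factor Per-interval multiplicative intensity
#'   trajectory applied to post-lesion boutons that stabilize, so their
#'   size climbs toward the population mean.
#' @param seed Integer RNG seed; the whole dataset is reproducible from it.
#'
#' @return An object of class `synth_params` (a validated list).
#' @seealso [generate_bouton_dataset()], [generate_lesion_cohort()]
#' @export
synth_params <- function(n_axons = 8L,
                         axon_length_um = c(738, 317),
                         epb_density_per_um = 0.043,
                         session_times = c(-4, -2, -1, 0, 0.25, 1, 2, 4),
                         lesion_offset_um = 150,
                         close_threshold_um = 250,
                         baseline_gain_hazard = 0.16,
                         baseline_loss_hazard = 0.16,
                         post_lesion_gain_boost = c(close = 1.5, far = 2.2),
                         post_lesion_loss_boost = c(close = 2.2, far = 0.6),
                         intensity_meanlog = 1.1,
                         intensity_sdlog = 0.45,
                         new_bouton_growth_factor = 1.5,
                         seed = 1L) {
  p <- list(
    n_axons = as.integer(n_axons),
    axon_length_um = as.numeric(axon_length_um),
    epb_density_per_um = as.numeric(epb_density_per_um),
    session_times = as.numeric(session_times),
    lesion_offset_um = as.numeric(lesion_offset_um),
    close_threshold_um = as.numeric(close_threshold_um),
    baseline_gain_hazard = as.numeric(baseline_gain_hazard),
    baseline_loss_hazard = as.numeric(baseline_loss_hazard),
    post_lesion_gain_boost = rep_len(as.numeric(post_lesion_gain_boost), 2L),
    post_lesion_loss_boost = rep_len(as.numeric(post_lesion_loss_boost), 2L),
    intensity_meanlog = as.numeric(intensity_meanlog),
    intensity_sdlog = as.numeric(intensity_sdlog),
    new_bouton_growth_factor = as.numeric(new_bouton_growth_factor),
    seed = as.integer(seed)
  )
  validate_synth_params(p)
  class(p) <- "synth_params"
  p
}

validate_synth_params <- function(p) {
  stop_cfg <- function(msg) stop("invalid synth_params: ", msg, call. = FALSE)
  if (p$n_axons < 0L) stop_cfg("n_axons must be >= 0")
  if (length(p$axon_length_um) != 2L || p$axon_length_um[1] <= 0)
    stop_cfg("axon_length_um must be (mean > 0, sd)")
  if (p$epb_density_per_um <= 0) stop_cfg("density must be > 0")
  if (length(p$session_times) < 1L || is.unsorted(p$session_times, strictly = TRUE))
    stop_cfg("session_times must be non-empty and strictly increasing")
  hz <- c(p$baseline_gain_hazard, p$baseline_loss_hazard)
  if (any(hz < 0 | hz > 1)) stop_cfg("hazards must lie in [0, 1]")
  if (any(c(p$post_lesion_gain_boost, p$post_lesion_loss_boost) < 0))
    stop_cfg("boosts must be >= 0")
  if (p$lesion_offset_um < 0 || p$lesion_offset_um > p$axon_length_um[1])
    stop_cfg("lesion_offset_um must lie within the mean axon length")
  invisible(p)
}

#' @export
print.synth_params <- function(x, ...) {
  cat("Synthetic bouton-track generator parameters\n")
  cat(sprintf("  axons: %d, density: %.3f /um, mean length: %.0f um\n",
              x$n_axons, x$epb_density_per_um, x$axon_length_um[1]))
  cat(sprintf("  sessions (d): %s\n", paste(x$session_times, collapse = ", ")))
  cat(sprintf("  baseline hazards (gain/loss, per day): %.3f / %.3f\n",
              x$baseline_gain_hazard, x$baseline_loss_hazard))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
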