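#' Initialise a random weight matrix
#'
#' Every ordered pair (i, j), i != j, is connected with probability
#' `P_con`; connected weights are drawn Uniform(0, w_init).  Rows are
#' presynaptic, columns postsynaptic; the diagonal is empty.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return A `weight_matrix`: list with `w` (N x N numeric, mV) and
#'   `mask` (N x N logical connection mask).
#' @export
init_weights <- function(cfg, seed) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  N <- cfg$N
  mask <- matrix(stats::runif(N * N) < cfg$P_con, N, N)
  diag(mask) <- FALSE
  w <- matrix(0, N, N)
  w[mask] <- stats::runif(sum(mask), 0, cfg$plasticity$w_init)
  weight_matrix(w, mask)
}

#' @rdname init_weights
#' @param w,mask Components of an existing matrix.
#' @export
weight_matrix <- function(w, mask) {
  stopifnot(is.matrix(w), is.matrix(mask), all(dim(w) == dim(mask)))
  if (any(diag(mask))) stop("self-connections are not allowed", call. = FALSE)
  if (any(w[!mask] != 0)) stop("weights must be 0 off the mask", call. = FALSE)
  structure(list(w = w, mask = mask), class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Weight matrix: %d neurons, %d connections (%.1f%% of pairs)\n",
              nrow(x$w), sum(x$mask),
              100 * sum(x$mask) / (nrow(x$w) * (nrow(x$w) - 1))))
  if (sum(x$mask))
    cat(sprintf("  weights: mean %.3f mV, max %.3f mV\n",
                mean(x$w[x$mask]), max(x$w[x$mask])))
  invisible(x)
}

#' Run the LIF network over a stimulation protocol
#'
#' Forward-Euler integration at `dt_ms` with delta synapses (the spike
#' time constant is far below the step, so recurrent spikes and stimulus
#' events act as instantaneous voltage jumps), Poisson stimulus/noise
#' event trains, threshold/reset spiking, a low-pass rate filter per
#' neuron, a trailing-average rate threshold, and (optionally) the gated
#' Hebbian covariance rule on existing connections.
#'
#' @param wm A `weight_matrix`.
#' @param cfg A [network_config()].
#' @param protocol A `stim_protocol` from [build_training_protocol()] /
#'   [build_testing_protocol()].
#' @param plasticity_on Apply the Hebbian update each step.
#' @param seed Integer seed (drives stimulus and noise event trains).
#' @param checkpoint_ms Optional time at which to snapshot the weight
#'   matrix (used for turnover measurement).
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation; identical trajectories under the same seed).
#' @return A `sim_result`: list with `spikes` (data.frame `neuron`,
#'   `time_ms`), `W` (final `weight_matrix`), `W_checkpoint` (or NULL),
#'   `pop_rate_hz`, `rate_hz` (per neuron), `duration_ms`, `config`,
#'   `protocol`.
#' @export
run_simulation <- function(wm, cfg, protocol, plasticity_on = TRUE, seed = 1L,
                           checkpoint_ms = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(wm, "weight_matrix"), inherits(cfg, "network_config"),
            inherits(protocol, "stim_protocol"))
  engine <- match.arg(engine)
  dt <- cfg$dt_ms
  n_steps <- as.integer(round(protocol$total_ms / dt))
  if (nrow(protocol$stimuli) > 0 &&
      max(protocol$stimuli$onset_ms + protocol$stimuli$dur_ms) > protocol$total_ms + 1e-9)
    stop("protocol longer than simulated duration", call. = FALSE)

  stim_id_per_step <- integer(n_steps)
  if (nrow(protocol$stimuli) > 0) {
    for (k in seq_len(nrow(protocol$stimuli))) {
      from <- as.integer(round(protocol$stimuli$onset_ms[k] / dt)) + 1L
      to <- as.integer(round((protocol$stimuli$onset_ms[k] +
                              protocol$stimuli$dur_ms[k]) / dt))
      stim_id_per_step[from:to] <- k
    }
  }
  checkpoint_step <- if (is.null(checkpoint_ms)) 0L
                     else as.integer(round(checkpoint_ms / dt))
  jumps <- protocol$stimuli$amp_pa * cfg$mv_per_pa
  noise_jump <- protocol$noise_amp_pa * cfg$mv_per_pa

  set.seed(seed)
  core <- if (engine == "cpp") lif_run_cpp else lif_run_r
  res <- core(wm$w, wm$mask, cfg$neuron, cfg$plasticity,
              stim_id_per_step, protocol$targets,
              protocol$stimuli$rate_hz, jumps,
              protocol$noise_rate_hz, noise_jump,
              dt, plasticity_on, checkpoint_step, 0)

  spikes <- data.frame(neuron = res$spike_neuron,
                       time_ms = res$spike_step * dt)
  rate_hz <- tabulate(res$spike_neuron, nbins = cfg$N) /
    (n_steps * dt) * 1000
  out <- list(
    spikes = spikes,
    W = weight_matrix(res$W, wm$mask),
    W_checkpoint = if (!is.null(res$W_checkpoint))
      weight_matrix(res$W_checkpoint, wm$mask) else NULL,
    pop_rate_hz = mean(rate_hz),
    rate_hz = rate_hz,
    duration_ms = n_steps * dt,
    config = cfg,
    protocol = protocol
  )
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation: %.0f ms, %d spikes, population rate %.1f Hz\n",
              x$duration_ms, nrow(x$spikes), x$pop_rate_hz))
  invisible(x)
}

#' Hebbian update kernel
#'
#' The per-step weight change of the gated rate-covariance rule:
#' `delta = eta * d_i * d_j * (1 - H(-d_i) H(-d_j))` where
#' `d = nu - <nu>` is the deviation of the filtered rate from its trailing
#' average and `H` is the Heaviside step (`H(0) = 1`).  The gate silences
#' the quadrant where both neurons sit below their rate thresholds; the
#' other three quadrants potentiate (both above) or depress (one above,
#' one below).  `eta = beta * dt / 0.04 ms` is the step gain actually
#' applied by the simulation engines.
#'
#' @param d_i,d_j Pre-/post-synaptic rate deviations (vectorized).
#' @param beta Learning rate.
#' @param dt Integration step in ms.
#' @return The (unclipped) weight increment in mV.
#' @export
hebbian_delta <- function(d_i, d_j, beta, dt = 0.1) {
  gate <- !(d_i < 0 & d_j < 0)
  beta * (dt / 0.04) * d_i * d_j * gate
}

# Pure-R reference engine: mirrors lif_run_cpp draw-for-draw.
lif_run_r <- function(W0, mask, neuron, plast,
                      stim_id_per_step, stim_targets,
                      stim_rate_hz, stim_jump_mv,
                      noise_rate_hz, noise_jump_mv,
                      dt, plasticity_on, checkpoint_step, const_drive_mv) {
  N <- nrow(W0)
  W <- W0
  n_steps <- length(stim_id_per_step)
  p_noise <- noise_rate_hz * dt * 1e-3
  leak <- dt / neuron$tau_m
  rho <- 1 - dt / plast$tau_nu
  wsteps <- max(1L, as.integer(round(plast$t_w / dt)))
  con <- which(mask & !diag(TRUE, N), arr.ind = TRUE)

  u <- rep(neuron$u_rest, N)
  nu <- numeric(N)
  buf <- matrix(0, wsteps, N)
  bufsum <- numeric(N)
  buf_count <- 0L; buf_head <- 1L
  spiked_prev <- integer(0)
  out_step <- integer(0); out_neuron <- integer(0)
  W_checkpoint <- NULL

  for (s in seq_len(n_steps)) {
    input <- numeric(N)
    if (length(spiked_prev))
      input <- colSums(W[spiked_prev, , drop = FALSE])
    input <- input + (stats::runif(N) < p_noise) * noise_jump_mv
    sid <- stim_id_per_step[s]
    if (sid > 0) {
      tg <- stim_targets[[sid]]
      hit <- stats::runif(length(tg)) < stim_rate_hz[sid] * dt * 1e-3
      input[tg] <- input[tg] + hit * stim_jump_mv[sid]
    }

    u <- u + leak * (neuron$u_rest - u + const_drive_mv) + input
    if (any(!is.finite(u))) stop("non-finite membrane potential")
    spiked <- which(u >= neuron$theta)
    u[spiked] <- neuron$u_rest
    out_step <- c(out_step, rep(s, length(spiked)))
    out_neuron <- c(out_neuron, spiked)

    nu <- nu * rho
    nu[spiked] <- nu[spiked] + 1
    denom <- min(buf_count, wsteps)
    nubar <- if (denom > 0) bufsum / denom else numeric(N)
    d <- nu - nubar

    if (plasticity_on && nrow(con)) {
      di <- d[con[, 1]]; dj <- d[con[, 2]]
      W[con] <- pmin(plast$w_max,
                     pmax(plast$w_min,
                          W[con] + hebbian_delta(di, dj, plast$beta, dt)))
    }

    old <- buf[buf_head, ]
    buf[buf_head, ] <- nu
    bufsum <- bufsum + nu - if (buf_count >= wsteps) old else 0
    buf_head <- buf_head %% wsteps + 1L
    if (buf_count < wsteps) buf_count <- buf_count + 1L
    spiked_prev <- spiked

    if (checkpoint_step > 0 && s == checkpoint_step) W_checkpoint <- W
  }
  list(W = W, spike_step = out_step, spike_neuron = out_neuron,
       u_final = u, nu_final = nu, W_checkpoint = W_checkpoint)
}
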