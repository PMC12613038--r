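# Shared fixtures and independent reference implementations used as
# oracles across the suite.

# Build a bouton_dataset by hand from a presence matrix (boutons x
# sessions) and optional intensity matrix; positions/distances explicit.
make_dataset <- function(presence, times, positions = NULL, intensities = NULL,
                         length_um = 300, lesion_position_um = 0,
                         axon_id = "axA") {
  nb <- nrow(presence); ns <- ncol(presence)
  stopifnot(ns == length(times))
  if (is.null(positions)) positions <- seq_len(nb) * 10
  if (is.null(intensities)) {
    intensities <- matrix(1, nb, ns)
  }
  intensities[presence == 0] <- NA_real_
  boutons <- data.frame(
    axon_id = axon_id,
    bouton_id = sprintf("%s_b%03d", axon_id, rep(seq_len(nb), each = ns)),
    position_um = rep(positions, each = ns),
    distance_um = rep(abs(positions - lesion_position_um), each = ns),
    session_time_days = rep(times, nb),
    present = as.integer(t(presence)),
    intensity = as.vector(t(intensities))
  )
  axons <- data.frame(axon_id = axon_id, length_um = length_um,
                      lesion_position_um = lesion_position_um)
  structure(list(boutons = boutons, axons = axons, params = NULL),
            class = "bouton_dataset")
}

default_times <- c(-4, -2, -1, 0, 0.25, 1, 2, 4)

# Naive direct-definition classifier used as the oracle for
# classify_boutons(): works from the raw presence vector.
naive_classify <- function(p, times) {
  p <- as.logical(p)
  n <- length(p)
  two_consec <- function(v) {
    if (length(v) < 2) return(FALSE)
    any(v[-1] & v[-length(v)])
  }
  first <- if (any(p)) which(p)[1] else NA
  list(
    stable = two_consec(p),
    new = !is.na(first) && times[first] > 0,
    new_stable = !is.na(first) && times[first] > 0 && two_consec(p),
    persistent = all(p),
    destabilized = two_consec(p[1:min(3, n)]) && !p[n] && !p[n - 1]
  )
}

# Naive per-row metric reference for small datasets: counts straight from
# the long table, no matrix reshaping.
naive_metrics <- function(dataset, axon_id, pair) {
  d <- dataset$boutons[dataset$boutons$axon_id == axon_id, ]
  at <- function(t) d[abs(d$session_time_days - t) < 1e-9, ]
  a <- at(pair[1]); b <- at(pair[2])
  pa <- a$bouton_id[a$present == 1]
  pb <- b$bouton_id[b$present == 1]
  N <- length(pa)
  nG <- length(setdiff(pb, pa))
  nL <- length(setdiff(pa, pb))
  list(N = N, nG = nG, nL = nL,
       tor = (nG + nL) / (2 * N),
       gains = nG / N, losses = nL / N,
       density_a = N / dataset$axons$length_um[dataset$axons$axon_id == axon_id])
}

# Exact Mann-Whitney p value by enumerating all assignments of ranks
# (two-sided, via the null distribution of the U statistic).
exact_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  u_all <- apply(idx, 2, function(i) {
    sum(rank(pooled)[i]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small, fast network configuration for engine-level tests.
tiny_config <- function(condition = "young_epb", beta = 0.03, N = 12L, ...) {
  network_config(condition, beta = beta, N = N,
                 protocol = list(N_pattern = 4L, N_test = 2L,
                                 Sim_train = 400, sim_train = 30, g_train = 20,
                                 reps_train = 2L,
                                 Sim_test = 300, sim_test = 80, g_test = 20,
                                 reps_test = 1L),
                 ...)
}
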