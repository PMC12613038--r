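empty_protocol <- function(cfg, total_ms = 50) {
  boutonnet:::new_stim_protocol(
    data.frame(pattern = integer(0), onset_ms = numeric(0),
               dur_ms = numeric(0), rate_hz = numeric(0),
               amp_pa = numeric(0)),
    list(), total_ms, 0, 0, "testing")
}

# run the compiled core directly with a constant suprathreshold drive
run_const_drive <- function(cfg, drive_mv, n_steps, engine = "cpp") {
  core <- if (engine == "cpp") boutonnet:::lif_run_cpp else boutonnet:::lif_run_r
  N <- 1L
  set.seed(1)
  core(matrix(0, N, N), matrix(FALSE, N, N), cfg$neuron, cfg$plasticity,
       integer(n_steps), list(), numeric(0), numeric(0),
       0, 0, cfg$dt_ms, FALSE, 0L, drive_mv)
}

test_that("connection sampling matches the Bernoulli graph model", {
  cfg0 <- network_config("young_epb", P_con = 0)
  expect_equal(sum(init_weights(cfg0, 1)$mask), 0)

  cfg <- network_config("young_epb", P_con = 1)
  wm <- init_weights(cfg, 2)
  expect_equal(sum(wm$mask), 100 * 99)
  expect_true(all(wm$w[wm$mask] > 0 & wm$w[wm$mask] < cfg$plasticity$w_init))
  expect_false(any(diag(wm$mask)))

  cfg23 <- network_config("young_epb")
  counts <- vapply(1:60, function(s) sum(init_weights(cfg23, s)$mask),
                   numeric(1))
  expected <- 0.23 * 9900
  se <- sqrt(9900 * 0.23 * 0.77 / 60)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("a resting neuron without input stays at rest forever", {
  cfg <- network_config("young_epb")
  res <- run_const_drive(cfg, 0, 2000)
  expect_length(res$spike_step, 0)
  expect_equal(res$u_final, cfg$neuron$u_rest)
})

test_that("the membrane leak follows the closed-form exponential", {
  # u0 = -50 mV, no input: u(t) = -72 + 22 exp(-t / 28 ms)
  cfg <- network_config("young_epb")
  n_steps <- 280L  # 28 ms
  # inject a one-step drive that lifts u from rest to -50 mV, then leak
  N <- 1L
  stim_steps <- integer(n_steps + 1L)
  stim_steps[1] <- 1L
  set.seed(1)
  res <- boutonnet:::lif_run_r(matrix(0, 1, 1), matrix(FALSE, 1, 1),
                               cfg$neuron, cfg$plasticity,
                               stim_steps, list(1L), 1e7, 22,
                               0, 0, cfg$dt_ms, FALSE, 0L, 0)
  # Euler map: u_k = u_rest + 22 (1 - dt/tau)^k; compare with exp at t = 28
  u_exact <- -72 + 22 * exp(-28 / 28)
  expect_lt(abs(res$u_final - u_exact), 0.05)
  expect_length(res$spike_step, 0)
})

test_that("constant-drive interspike intervals match the LIF closed form", {
  cfg <- network_config("young_epb")
  for (drive in c(40, 60, 90)) {
    res <- run_const_drive(cfg, drive, 20000)  # 2 s
    isi <- diff(res$spike_step) * cfg$dt_ms
    expect_gt(length(isi), 5)
    expect_lt(max(isi) - min(isi), 1e-9)  # deterministic
    T_exact <- cfg$neuron$tau_m *
      log(drive / (drive - (cfg$neuron$theta - cfg$neuron$u_rest)))
    expect_lt(abs(isi[1] - T_exact), cfg$dt_ms + 0.05 * T_exact)
  }
})

test_that("compiled and pure-R engines produce identical trajectories", {
  cfg <- tiny_config()
  pat <- make_patterns(cfg, 5)
  wm <- init_weights(cfg, 6)
  trp <- build_training_protocol(cfg, pat, seed = 7)
  a <- run_simulation(wm, cfg, trp, TRUE, seed = 11, checkpoint_ms = 100,
                      engine = "cpp")
  b <- run_simulation(wm, cfg, trp, TRUE, seed = 11, checkpoint_ms = 100,
                      engine = "r")
  expect_identical(a$spikes, b$spikes)
  expect_equal(a$W$w, b$W$w, tolerance = 1e-12)
  expect_equal(a$W_checkpoint$w, b$W_checkpoint$w, tolerance = 1e-12)
  expect_gt(nrow(a$spikes), 0)
})

test_that("rate filter relaxes exponentially after a single spike", {
  cfg <- network_config("young_epb")
  # one guaranteed stimulus event at the first step, then silence
  n_steps <- 200L
  stim_steps <- integer(n_steps)
  stim_steps[1] <- 1L
  set.seed(1)
  res <- boutonnet:::lif_run_cpp(matrix(0, 1, 1), matrix(FALSE, 1, 1),
                                 cfg$neuron, cfg$plasticity,
                                 stim_steps, list(1L), 1e7, 60,
                                 0, 0, cfg$dt_ms, FALSE, 0L, 0)
  expect_equal(res$spike_step, 1L)
  rho <- 1 - cfg$dt_ms / cfg$plasticity$tau_nu
  expect_equal(res$nu_final, rho^(n_steps - 1L), tolerance = 1e-9)

  # no spikes ever -> nu stays 0
  res0 <- run_const_drive(cfg, 0, 100)
  expect_equal(res0$nu_final, 0)
})

test_that("the Hebbian kernel reproduces the sign table on all quadrants", {
  cases <- expand.grid(d_i = c(-0.7, 0.9), d_j = c(-0.4, 1.1))
  delta <- hebbian_delta(cases$d_i, cases$d_j, beta = 0.03)
  # both below threshold -> nothing
  expect_equal(delta[cases$d_i < 0 & cases$d_j < 0], 0)
  # mixed -> depression
  expect_true(all(delta[xor(cases$d_i < 0, cases$d_j < 0)] < 0))
  # both above -> potentiation
  expect_true(all(delta[cases$d_i > 0 & cases$d_j > 0] > 0))

  # sign structure holds across random magnitudes
  set.seed(3)
  di <- runif(500, -2, 2); dj <- runif(500, -2, 2)
  dl <- hebbian_delta(di, dj, 0.02)
  expect_true(all(dl[di < 0 & dj < 0] == 0))
  expect_true(all(dl[di > 0 & dj > 0] >= 0))
  expect_true(all(dl[xor(di < 0, dj < 0)] <= 0))
  # boundary: zero deviation contributes nothing
  expect_equal(hebbian_delta(0, -1, 0.05), 0)
})

test_that("learning respects weight bounds and never alters topology", {
  for (cond in c("young_epb", "young_tb")) {
    cfg <- tiny_config(cond, beta = 0.05)
    wm <- init_weights(cfg, 21)
    pat <- make_patterns(cfg, 22)
    trp <- build_training_protocol(cfg, pat, seed = 23)
    tr <- run_simulation(wm, cfg, trp, TRUE, seed = 24)
    expect_identical(tr$W$mask, wm$mask)
    expect_true(all(tr$W$w[tr$W$mask] >= cfg$plasticity$w_min - 1e-12))
    expect_true(all(tr$W$w[tr$W$mask] <= cfg$plasticity$w_max + 1e-12))
    expect_true(all(tr$W$w[!tr$W$mask] == 0))
    expect_true(all(diag(tr$W$w) == 0))
  }
})

test_that("an empty protocol with plasticity off changes nothing", {
  cfg <- network_config("young_epb")
  wm <- init_weights(cfg, 31)
  prot <- empty_protocol(cfg)
  res <- run_simulation(wm, cfg, prot, plasticity_on = FALSE, seed = 32)
  expect_equal(nrow(res$spikes), 0)
  expect_equal(res$W$w, wm$w)
})

test_that("halving the integration step leaves the memory error stable", {
  err_at_dt <- function(dt) {
    cfg <- network_config("young_epb", beta = 0.03, dt_ms = dt)
    es <- vapply(1:4, function(s) {
      pat <- make_patterns(cfg, s * 3)
      wm <- init_weights(cfg, s * 5)
      trp <- build_training_protocol(cfg, pat, seed = s * 7)
      tr <- run_simulation(wm, cfg, trp, TRUE, seed = s * 11)
      tep <- build_testing_protocol(cfg, pat)
      te <- run_simulation(tr$W, cfg, tep, FALSE, seed = s * 13)
      compute_error(te, pat, tep)
    }, numeric(1))
    mean(es)
  }
  expect_lt(abs(err_at_dt(0.1) - err_at_dt(0.05)), 0.1)
})
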