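#' Recompute the headline modeling results end to end
#'
#' Runs the full network analysis from scratch: calibrates learning rates
#' for the aged-vs-young EPB pair and the TB-vs-EPB pair against their
#' experimental turnover anchors, runs baseline recall experiments for
#' each calibrated condition, the staged injury experiments, the
#' learning-rate sweep with its three correlations, and the
#' EPB-training firing-rate measurement.  All randomness descends from
#' `seed` through the package's counter-based seed fan-out.
#'
#' @param seed Master integer seed.
#' @param n_sims,repeats Baseline/injury experiment size per condition
#'   (`n_sims x repeats` runs).
#' @param beta_grid Calibration grid over the admissible learning-rate
#'   range.
#' @param n_per_beta Calibration simulations per grid point.
#' @param sweep_n Number of simulations in the correlation sweep.
#' @param rate_seeds Number of seeds for the firing-rate measurement.
#' @param verbose Log per-stage wall times to stderr.
#' @return A `reproduce_report`: list with `values` (named list of the
#'   headline numbers), `n` (problem size per value), `calibrations`,
#'   and the per-stage result tables.
#' @export
reproduce_report <- function(seed = 1L, n_sims = 50L, repeats = 3L,
                             beta_grid = seq(0.01, 0.05, length.out = 41),
                             n_per_beta = 10L, sweep_n = 50L,
                             rate_seeds = 12L, verbose = TRUE) {
  t_all <- Sys.time()
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[reproduce] ", fmt), ...))
  }
  log_stage("seed %d, package boutonnet %s", seed,
            as.character(utils::packageVersion("boutonnet")))

  tic <- function() Sys.time()
  toc <- function(t0, what) {
    log_stage("%s: %.1f s", what, as.numeric(Sys.time() - t0, units = "secs"))
  }

  aged <- network_config("aged_epb")
  young <- network_config("young_epb")
  tb <- network_config("young_tb")

  # learning-rate calibration against experimental turnover ratios
  t0 <- tic()
  cal_age <- calibrate_beta(aged, young, betas = beta_grid,
                            n_per_beta = n_per_beta,
                            seed = child_seed(seed, 101))
  toc(t0, "aged/young EPB calibration")
  t0 <- tic()
  cal_tb <- calibrate_beta(tb, young, betas = beta_grid,
                           n_per_beta = n_per_beta,
                           seed = child_seed(seed, 102))
  toc(t0, "TB/EPB calibration")

  cfg_aged <- network_config("aged_epb", beta = cal_age$beta_a)
  cfg_young <- network_config("young_epb", beta = cal_age$beta_b)
  cfg_tb <- network_config("young_tb", beta = cal_tb$beta_a)
  cfg_young2 <- network_config("young_epb", beta = cal_tb$beta_b)

  base <- list()
  base_specs <- list(
    young_vs_tb = cfg_young2,   # young EPB member of the EPB/TB pairing
    tb = cfg_tb,
    young_vs_aged = cfg_young,  # young EPB member of the aged pairing
    aged = cfg_aged
  )
  for (nm in names(base_specs)) {
    t0 <- tic()
    base[[nm]] <- run_baseline_experiment(base_specs[[nm]], n_sims = n_sims,
                                          repeats = repeats,
                                          seed = child_seed(seed, 200 + match(nm, names(base_specs))))
    toc(t0, paste("baseline", nm))
  }

  inj <- list()
  inj_specs <- list(aged = cfg_aged, young = cfg_young, tb = cfg_tb)
  for (nm in names(inj_specs)) {
    t0 <- tic()
    inj[[nm]] <- run_injury_experiment(inj_specs[[nm]], n_sims = n_sims,
                                       repeats = repeats,
                                       seed = child_seed(seed, 300 + match(nm, names(inj_specs))))
    toc(t0, paste("injury", nm))
  }

  t0 <- tic()
  sweep <- run_correlation_experiment(
    network_config("young_epb"),
    betas = seq(0.01, 0.05, length.out = sweep_n),
    seed = child_seed(seed, 400))
  toc(t0, "correlation sweep")

  t0 <- tic()
  rates <- vapply(seq_len(rate_seeds), function(k) {
    u <- baseline_unit(cfg_young, child_seed(seed, 500 + k))
    u$train_rate_hz
  }, numeric(1))
  toc(t0, "firing-rate measurement")

  cors <- stats::setNames(sweep$correlations$r, sweep$correlations$pair)
  values <- list(
    baseline_error_young_epb_vs_tb = mean(base$young_vs_tb$error),
    baseline_error_young_tb = mean(base$tb$error),
    baseline_error_young_epb_vs_aged = mean(base$young_vs_aged$error),
    baseline_error_aged_epb = mean(base$aged$error),
    postinjury_error_aged_epb = mean(inj$aged$error_stage2),
    postinjury_error_young_epb = mean(inj$young$error_stage2),
    postinjury_error_young_tb = mean(inj$tb$error_stage2),
    r_beta_tor = unname(cors["beta_tor"]),
    r_tor_error = unname(cors["tor_error"]),
    r_tor_connectivity_mag = abs(unname(cors["tor_connectivity"])),
    train_rate_epb_hz = mean(rates)
  )
  n_runs <- n_sims * repeats
  n <- list(
    baseline_error_young_epb_vs_tb = n_runs,
    baseline_error_young_tb = n_runs,
    baseline_error_young_epb_vs_aged = n_runs,
    baseline_error_aged_epb = n_runs,
    postinjury_error_aged_epb = n_runs,
    postinjury_error_young_epb = n_runs,
    postinjury_error_young_tb = n_runs,
    r_beta_tor = sweep_n,
    r_tor_error = sweep_n,
    r_tor_connectivity_mag = sweep_n,
    train_rate_epb_hz = rate_seeds
  )
  log_stage("total: %.1f s", as.numeric(Sys.time() - t_all, units = "secs"))

  out <- list(values = values, n = n,
              calibrations = list(aged_young = cal_age, tb_young = cal_tb),
              baseline = base, injury = inj, sweep = sweep,
              train_rates_hz = rates, seed = seed)
  class(out) <- "reproduce_report"
  out
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat("End-to-end reproduction report (seed", x$seed, ")\n")
  cat(sprintf("  calibrated betas: aged %.3f / young %.3f (ratio %.2f); ",
              x$calibrations$aged_young$beta_a,
              x$calibrations$aged_young$beta_b,
              x$calibrations$aged_young$ratio))
  cat(sprintf("TB %.3f / young %.3f (ratio %.2f)\n",
              x$calibrations$tb_young$beta_a,
              x$calibrations$tb_young$beta_b,
              x$calibrations$tb_young$ratio))
  for (nm in names(x$values))
    cat(sprintf("  %-34s %8.4f  (n = %d)\n", nm, x$values[[nm]],
                x$n[[nm]]))
  invisible(x)
}
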