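test_that("generator is reproducible from its seed and validates inputs", {
  p <- synth_params(n_axons = 3L, seed = 11L)
  d1 <- generate_bouton_dataset(p)
  d2 <- generate_bouton_dataset(p)
  expect_identical(d1$boutons, d2$boutons)
  expect_identical(d1$axons, d2$axons)

  d3 <- generate_bouton_dataset(synth_params(n_axons = 3L, seed = 12L))
  expect_false(identical(d1$boutons, d3$boutons))

  expect_error(synth_params(baseline_gain_hazard = 1.2), "hazard")
  expect_error(synth_params(session_times = c(1, 1, 2)), "increasing")
  expect_error(synth_params(session_times = numeric(0)), "non-empty")
  expect_error(synth_params(epb_density_per_um = 0), "density")
})

test_that("zero hazards give fully static boutons and zero turnover", {
  p <- synth_params(n_axons = 4L, baseline_gain_hazard = 0,
                    baseline_loss_hazard = 0, seed = 2L)
  d <- generate_bouton_dataset(p)
  expect_true(all(d$boutons$present == 1L))
  times <- p$session_times
  for (k in seq_len(length(times) - 1L)) {
    tor <- turnover_rate(d, d$axons$axon_id[1], c(times[k], times[k + 1]))
    expect_identical(tor, 0)
  }
})

test_that("bouton count and density match the configured rate", {
  p <- synth_params(n_axons = 8L, axon_length_um = c(738, 0),
                    epb_density_per_um = 0.043,
                    baseline_gain_hazard = 0, baseline_loss_hazard = 0,
                    seed = 5L)
  d <- generate_bouton_dataset(p)
  n_tot <- length(unique(d$boutons$bouton_id))
  expected <- 0.043 * 738 * 8  # ~254
  expect_lt(abs(n_tot - expected), 3 * sqrt(expected))  # Poisson error

  # pooled density recovery at large n (many axons, fixed length)
  p2 <- synth_params(n_axons = 60L, axon_length_um = c(738, 0),
                     epb_density_per_um = 0.043,
                     baseline_gain_hazard = 0, baseline_loss_hazard = 0,
                     seed = 6L)
  d2 <- generate_bouton_dataset(p2)
  dens <- vapply(d2$axons$axon_id, function(a) bouton_density(d2, a, -4),
                 numeric(1))
  expect_lt(abs(mean(dens) - 0.043) / 0.043, 0.05)
})

test_that("per-day hazards map to the configured interval turnover", {
  # gain = loss = 0.23/day over a one-day pre-lesion pair at large n:
  # measured TOR must sit within Monte-Carlo error of the hazard
  p <- synth_params(n_axons = 1L, axon_length_um = c(2e5, 0),
                    epb_density_per_um = 0.05,  # ~1e4 boutons
                    baseline_gain_hazard = 0.23, baseline_loss_hazard = 0.23,
                    lesion_offset_um = 100, seed = 7L)
  d <- generate_bouton_dataset(p)
  expect_gt(sum(d$boutons$present[d$boutons$session_time_days == -2]), 5000)
  tor <- turnover_rate(d, d$axons$axon_id[1], c(-2, -1))
  expect_lt(abs(tor - 0.23), 0.01)

  # and the identity TOR = (gains + losses) / 2 holds exactly
  gl <- gains_losses_fractions(d, d$axons$axon_id[1], c(-2, -1))
  expect_equal(tor, (gl[["gains"]] + gl[["losses"]]) / 2)
})

test_that("bouton positions never exceed their axon's length", {
  d <- generate_bouton_dataset(synth_params(n_axons = 6L, seed = 9L))
  len <- setNames(d$axons$length_um, d$axons$axon_id)
  expect_true(all(d$boutons$position_um >= 0))
  expect_true(all(d$boutons$position_um <= len[d$boutons$axon_id] + 1e-9))
})

test_that("new stabilized boutons follow the configured growth trajectory", {
  p <- synth_params(n_axons = 40L, new_bouton_growth_factor = 2.15,
                    post_lesion_gain_boost = c(3, 3), seed = 13L)
  d <- generate_bouton_dataset(p)
  ratios <- c()
  for (ax in d$axons$axon_id) {
    cls <- classify_boutons(d, ax)
    ids <- cls$bouton_id[cls$new_stable]
    if (length(ids)) ratios <- c(ratios, size_ratio(d, ax, c(1, 2), boutons = ids))
  }
  ratios <- ratios[!is.na(ratios)]
  expect_gt(length(ratios), 50)
  expect_lt(abs(mean(ratios) - 2.15), 0.05)
})

test_that("bouton CSV schema round-trips with its parameter sidecar", {
  p <- synth_params(n_axons = 2L, seed = 21L)
  d <- generate_bouton_dataset(p)
  path <- file.path(tempdir(), "tracks.csv")
  write_bouton_csv(d, path)
  d2 <- read_bouton_csv(path)
  expect_equal(d$boutons, d2$boutons, tolerance = 1e-12)
  expect_equal(d$axons, d2$axons, tolerance = 1e-12)
  expect_equal(unclass(d$params)[order(names(d$params))],
               unclass(d2$params)[order(names(d2$params))],
               tolerance = 1e-12)
})

test_that("lesion cohort honors the configured complete-degeneration fraction", {
  p <- synth_params(seed = 3L)
  co <- generate_lesion_cohort(p, n_axons = 14L,
                               frac_fully_degenerated_day1 = 12 / 14)
  expect_length(co, 14L)
  expect_equal(complete_degeneration_fraction(co, by_day = 1), 12 / 14)
  # remaining length is non-increasing and at least 50% gone by 6 h
  for (r in co) {
    expect_true(all(diff(r$distal_remaining_um) <= 1e-9))
    expect_lte(r$distal_remaining_um[2] / r$distal_length_um, 0.5)
  }
  expect_length(generate_lesion_cohort(p, n_axons = 0L), 0L)
})

test_that("zero retraction profile gives identically zero tip distances", {
  co <- generate_lesion_cohort(synth_params(seed = 4L), n_axons = 5L,
                               retraction_profile = c(0, 0, 0, 0))
  for (r in co) expect_true(all(r$tip_distance_um == 0))
})

test_that("cohort retraction means recover the configured profile", {
  co <- generate_lesion_cohort(synth_params(seed = 8L), n_axons = 4000L,
                               retraction_profile = c(36, 25, 17, 11))
  acute <- vapply(co, function(r) retraction_distance(r, 1)$acute_um, numeric(1))
  chronic <- vapply(co, function(r) retraction_distance(r, 90)$chronic_um, numeric(1))
  # oracle: closed-form mean of max(0, N(mu, sd))
  tmean <- function(mu, sd) mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
  n <- length(co)
  expect_lt(abs(mean(acute) - tmean(36, 25)), 3 * sd(acute) / sqrt(n))
  expect_lt(abs(mean(chronic) - tmean(17, 11)), 3 * sd(chronic) / sqrt(n))
})

test_that("lesion cohort CSV round-trips", {
  co <- generate_lesion_cohort(synth_params(seed = 5L), n_axons = 6L)
  path <- file.path(tempdir(), "cohort.csv")
  write_lesion_csv(co, path)
  co2 <- read_lesion_csv(path)
  expect_length(co2, 6L)
  o <- order(vapply(co2, `[[`, "", "axon_id"))
  for (k in seq_along(co)) {
    expect_equal(co[[k]]$distal_remaining_um, co2[[o[k]]]$distal_remaining_um,
                 tolerance = 1e-9)
    expect_equal(co[[k]]$tip_distance_um, co2[[o[k]]]$tip_distance_um,
                 tolerance = 1e-9)
  }
})
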