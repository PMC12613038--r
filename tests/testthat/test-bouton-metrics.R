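test_that("density is count over length, with degenerate cases handled", {
  pres <- matrix(1, 13, 8)
  d <- make_dataset(pres, default_times, length_um = 300)
  expect_equal(bouton_density(d, "axA", -4), 13 / 300)

  pres0 <- matrix(0, 2, 8)
  pres0[, 1] <- 1  # present only at the first session
  d0 <- make_dataset(pres0, default_times, length_um = 300)
  expect_equal(bouton_density(d0, "axA", 0), 0)

  d_bad <- make_dataset(pres, default_times, length_um = 0)
  expect_error(bouton_density(d_bad, "axA", -4), "length")
  expect_error(bouton_density(d, "axA", 99), "not found")
})

test_that("turnover rate implements (nG + nL) / 2N", {
  # 10 present at a; 2 of them lost, 2 new at b -> (2+2)/(2*10) = 0.2
  pres <- matrix(0, 12, 2)
  pres[1:10, 1] <- 1
  pres[c(1:8, 11, 12), 2] <- 1
  d <- make_dataset(pres, c(0, 1))
  expect_equal(turnover_rate(d, "axA", c(0, 1)), 0.2)
  gl <- gains_losses_fractions(d, "axA", c(0, 1))
  expect_equal(unname(gl), c(0.2, 0.2))

  # identical presence -> 0
  same <- matrix(1, 5, 2)
  ds <- make_dataset(same, c(0, 1))
  expect_equal(turnover_rate(ds, "axA", c(0, 1)), 0)

  # N = 0 -> undefined with a warning
  none <- matrix(c(0, 1), 1, 2, byrow = TRUE)
  dn <- make_dataset(none, c(0, 1))
  expect_warning(tor <- turnover_rate(dn, "axA", c(0, 1)), "undefined")
  expect_true(is.na(tor))
})

test_that("gains and losses fractions are counts over N at session a", {
  # N = 10; 3 gained, 1 lost
  pres <- matrix(0, 13, 2)
  pres[1:10, 1] <- 1
  pres[c(1:9, 11:13), 2] <- 1
  d <- make_dataset(pres, c(0, 0.25))
  expect_equal(gains_losses_fractions(d, "axA", c(0, 0.25)),
               c(gains = 0.3, losses = 0.1))
  expect_equal(gains_losses_fractions(make_dataset(matrix(1, 4, 2), c(0, 1)),
                                      "axA", c(0, 1)),
               c(gains = 0, losses = 0))
})

test_that("size ratio is S_b over S_a for boutons present at both sessions", {
  pres <- matrix(1, 3, 2)
  pres[3, 2] <- 0
  inten <- matrix(c(2, 3,
                    5, 5,
                    4, NA), 3, 2, byrow = TRUE)
  d <- make_dataset(pres, c(1, 2), intensities = inten)
  sr <- size_ratio(d, "axA", c(1, 2))
  expect_equal(unname(sr[1]), 1.5)
  expect_equal(unname(sr[2]), 1)
  expect_true(is.na(sr[3]))  # absent at b -> undefined for this pair
})

test_that("presence-pattern classes agree with a brute-force classifier", {
  # every possible 8-session pattern
  all_patterns <- as.matrix(expand.grid(rep(list(0:1), 8)))
  d <- make_dataset(all_patterns, default_times)
  got <- classify_boutons(d, "axA")
  for (i in seq_len(nrow(all_patterns))) {
    want <- naive_classify(all_patterns[i, ], default_times)
    for (cls in names(want)) {
      expect_identical(got[[cls]][i], want[[cls]],
                       label = sprintf("pattern %s class %s",
                                       paste(all_patterns[i, ], collapse = ""),
                                       cls))
    }
  }
  # definition-forced examples
  idx <- function(p) which(apply(all_patterns, 1, paste, collapse = "") == p)
  i1 <- idx("11111111")
  expect_true(got$persistent[i1] && got$stable[i1] && !got$new[i1])
  i2 <- idx("00001100")  # first appears at +6 h
  expect_true(got$new[i2] && got$new_stable[i2] && !got$persistent[i2])
  i3 <- idx("11100000")
  expect_true(got$destabilized[i3])
})

test_that("the persistence partition is consistent", {
  d <- generate_bouton_dataset(synth_params(n_axons = 5L, seed = 31L))
  for (ax in d$axons$axon_id) {
    cls <- classify_boutons(d, ax)
    expect_false(any(cls$persistent & cls$destabilized))
    expect_true(all(cls$stable[cls$persistent]))
    expect_true(all(cls$stable[cls$new_stable]))
  }
})

test_that("distance split partitions boutons at the threshold", {
  pres <- matrix(1, 3, 2)
  d <- make_dataset(pres, c(0, 1), positions = c(100, 240, 260))
  sp <- split_by_distance(d, "axA")
  expect_setequal(sp$close, c("axA_b001", "axA_b002"))
  expect_setequal(sp$far, "axA_b003")

  # all close -> far empty
  d2 <- make_dataset(pres, c(0, 1), positions = c(10, 20, 30))
  expect_length(split_by_distance(d2, "axA")$far, 0)

  # boundary bouton goes to the configured side
  d3 <- make_dataset(matrix(1, 1, 2), c(0, 1), positions = 250)
  expect_length(split_by_distance(d3, "axA", boundary = "close")$close, 1)
  expect_length(split_by_distance(d3, "axA", boundary = "far")$close, 0)
})

test_that("metric table equals the naive per-row reference on small data", {
  set.seed(42)
  for (rep in 1:5) {
    nb <- sample(5:20, 1)
    pres <- matrix(rbinom(nb * 8, 1, 0.7), nb, 8)
    pres[1, ] <- 1  # keep N > 0 everywhere
    d <- make_dataset(pres, default_times,
                      positions = runif(nb, 0, 300))
    tab <- bouton_metric_table(d)
    for (k in 1:7) {
      pair <- default_times[c(k, k + 1)]
      ref <- naive_metrics(d, "axA", pair)
      row <- tab$intervals[abs(tab$intervals$t_a - pair[1]) < 1e-9, ]
      expect_equal(row$tor, ref$tor)
      expect_equal(row$gains, ref$gains)
      expect_equal(row$losses, ref$losses)
      # TOR identity holds exactly
      expect_equal(row$tor, (row$gains + row$losses) / 2)
    }
    ref0 <- naive_metrics(d, "axA", default_times[1:2])
    expect_equal(tab$sessions$density[1], ref0$density_a)
  }
})

test_that("pre-lesion aggregates follow the figure-legend conventions", {
  pres <- matrix(1, 6, 8)
  pres[6, 5:8] <- 0   # one bouton lost right after the lesion
  d <- make_dataset(pres, default_times, length_um = 100)
  tab <- bouton_metric_table(d)
  # density averaged over the four pre-lesion sessions
  expect_equal(tab$prelesion$density, 6 / 100)
  # daily TOR over the two one-day pre-lesion intervals (here all static)
  expect_equal(tab$prelesion$daily_tor, 0)
  expect_equal(tab$prelesion$gains, 0)
})

test_that("the statistics battery matches exact references and corrects p", {
  # Mann-Whitney against full enumeration over all rank assignments
  x <- c(3.1, 5.2, 1.4, 7.8, 2.2)
  y <- c(4.0, 6.5, 8.1, 9.9, 5.5)
  res <- stats_battery(list(mwu = list(test = "mann-whitney-u", x = x, y = y)))
  expect_equal(res$p, exact_mwu_p(x, y))
  expect_equal(res$p_bonferroni, min(1, res$p))

  # degenerate paired design: all differences zero -> p = 1 with warning
  expect_warning(
    res2 <- stats_battery(list(w = list(test = "wilcoxon-signed-rank",
                                        x = 1:5, y = 1:5))),
    "zero")
  expect_equal(res2$p, 1)

  # exactly collinear data -> r = 1
  res3 <- stats_battery(list(p = list(test = "pearson",
                                      x = 1:10, y = 2 * (1:10) + 3)))
  expect_equal(res3$statistic, 1)

  # Bonferroni: adjusted p >= raw p, capped at 1, multiplied by battery size
  res4 <- stats_battery(list(
    a = list(test = "mann-whitney-u", x = x, y = y),
    b = list(test = "kruskal-wallis", groups = list(x, y)),
    c = list(test = "friedman", groups = list(1:5, c(2, 1, 4, 3, 5), 5:1))
  ))
  expect_true(all(res4$p_bonferroni >= res4$p))
  expect_true(all(res4$p_bonferroni <= 1))
  expect_equal(res4$p_bonferroni, pmin(1, res4$p * 3))

  expect_error(stats_battery(list(b = list(test = "mann-whitney-u",
                                           x = numeric(0), y = 1:3))),
               "empty")
  expect_error(stats_battery(list(w = list(test = "wilcoxon-signed-rank",
                                           x = 1:4, y = 1:5))),
               "equal lengths")
})
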