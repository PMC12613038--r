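# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Cut a fraction of connections from a trained weight matrix
#'
#' Removes `round(Bloss_injury x current connection count)` uniformly
#' random existing connections (weights set to 0, mask cleared) --
#' the acute loss of boutons at the lesion.
#'
#' @param wm A `weight_matrix`.
#' @param Bloss_injury Fraction of current connections to cut.
#' @param seed Integer seed.
#' @return The lesioned `weight_matrix`.
#' @export
apply_lesion <- function(wm, Bloss_injury = 0.34, seed = 1L) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (Bloss_injury < 0 || Bloss_injury > 1)
    stop("Bloss_injury must lie in [0, 1]", call. = FALSE)
  con <- which(wm$mask)
  n_cut <- round_half_up(Bloss_injury * length(con))
  if (n_cut == 0L) return(wm)
  set.seed(seed)
  cut <- sample(con, n_cut)
  w <- wm$w; mask <- wm$mask
  w[cut] <- 0; mask[cut] <- FALSE
  weight_matrix(w, mask)
}

#' Apply one post-injury rewiring stage to the weight matrix
#'
#' Stage 1 (the 6-hour response): adds `round(Bgain_i1 x count)` new
#' connections with weights Uniform(0, w_init), then multiplies all
#' connection weights by `Bsize_i1` (clipped to `w_max`).  Stage 2 (the
#' return toward baseline): removes `round(Bloss_i2 x count)`
#' connections, multiplies all weights by `Bsize_i2`, and additionally
#' multiplies the connections added in stage 1 by `BsizeNew_i2` (clipped)
#' -- the stabilized new boutons that keep growing.
#'
#' In `optimal` rewiring mode, additions target unconnected within-pattern
#' pairs and removals target out-of-pattern connections (stage-2 removals
#' spare the stage-1 additions when possible), falling back to uniform
#' choices when the preferred pool is exhausted (with a warning).  In
#' `random` mode both are uniform.
#'
#' All fractions refer to the connections present when the stage is
#' applied; rounding is half-away-from-zero.
#'
#' @param wm A `weight_matrix`.
#' @param stage 1 or 2.
#' @param cfg A [network_config()] (supplies the injury parameter block
#'   and `w_init`/`w_max`).
#' @param patterns A [make_patterns()] result (used by optimal mode).
#' @param seed Integer seed.
#' @param added_stage1 Integer vector of matrix indices returned by the
#'   stage-1 call (required for stage 2's `BsizeNew_i2`).
#' @param mode Override of the config's `rewiring_mode`.
#' @return The rewired `weight_matrix`, with attribute `"added"` (matrix
#'   indices of connections added by this call, stage 1 only).
#' @export
apply_rewiring_stage <- function(wm, stage, cfg, patterns, seed = 1L,
                                 added_stage1 = integer(0), mode = NULL) {
  stopifnot(inherits(wm, "weight_matrix"), stage %in% c(1L, 2L),
            inherits(cfg, "network_config"))
  inj <- cfg$injury
  mode <- if (is.null(mode)) inj$rewiring_mode else match.arg(mode, c("optimal", "random"))
  N <- nrow(wm$w)
  w <- wm$w; mask <- wm$mask
  set.seed(seed)

  same_pattern <- matrix(FALSE, N, N)
  for (p in patterns) same_pattern[p$neurons, p$neurons] <- TRUE
  diag(same_pattern) <- FALSE

  if (stage == 1L) {
    n_con <- sum(mask)
    n_add <- round_half_up(inj$Bgain_i1 * n_con)
    added <- integer(0)
    if (n_add > 0L) {
      free <- which(!mask & !diag(TRUE, N))
      pool <- if (mode == "optimal") intersect(free, which(same_pattern)) else free
      if (length(pool) < n_add) {
        warning("preferred rewiring pool exhausted; falling back to random pairs")
        pool <- unique(c(pool, free))
      }
      n_add <- min(n_add, length(pool))
      added <- if (length(pool) == 1L) pool else sample(pool, n_add)
      mask[added] <- TRUE
      w[added] <- stats::runif(n_add, 0, cfg$plasticity$w_init)
    }
    w[mask] <- pmin(cfg$plasticity$w_max, w[mask] * inj$Bsize_i1)
    out <- weight_matrix(w, mask)
    attr(out, "added") <- added
    return(out)
  }

  # stage 2
  n_con <- sum(mask)
  n_rem <- round_half_up(inj$Bloss_i2 * n_con)
  if (n_rem > 0L) {
    con <- which(mask)
    pool <- if (mode == "optimal") {
      pref <- setdiff(intersect(con, which(!same_pattern)), added_stage1)
      if (length(pref) >= n_rem) pref else {
        warning("preferred removal pool exhausted; falling back to random connections")
        con
      }
    } else con
    rem <- if (length(pool) == 1L) pool else sample(pool, min(n_rem, length(pool)))
    mask[rem] <- FALSE
    w[rem] <- 0
  }
  w[mask] <- w[mask] * inj$Bsize_i2
  surviving_new <- intersect(added_stage1, which(mask))
  w[surviving_new] <- w[surviving_new] * inj$BsizeNew_i2
  w[mask] <- pmin(cfg$plasticity$w_max, pmax(cfg$plasticity$w_min, w[mask]))
  out <- weight_matrix(w, mask)
  attr(out, "added") <- integer(0)
  out
}

# one full staged run: baseline train/test, lesion, and the two rewiring
# stages, each followed by a single training repetition and a recall
# test.  The same test event seed is reused at every stage so stage
# errors are paired (differences reflect the weight matrix, not fresh
# test noise); retraining reps get fresh seeds.
injury_unit <- function(cfg, seed, mode = NULL, plasticity_on = TRUE) {
  patterns <- make_patterns(cfg, child_seed(seed, 1))
  wm <- init_weights(cfg, child_seed(seed, 2))
  train <- build_training_protocol(cfg, patterns, seed = child_seed(seed, 3))
  tr <- run_simulation(wm, cfg, train, plasticity_on = plasticity_on,
                       seed = child_seed(seed, 4))
  test <- build_testing_protocol(cfg, patterns)

  run_test <- function(w) {
    te <- run_simulation(w, cfg, test, plasticity_on = FALSE,
                         seed = child_seed(seed, 100))
    compute_error(te, patterns, test)
  }
  one_rep <- function(w, k) {
    p1 <- build_training_protocol(cfg, patterns, seed = child_seed(seed, 200 + k),
                                  reps = 1L)
    run_simulation(w, cfg, p1, plasticity_on = plasticity_on,
                   seed = child_seed(seed, 300 + k))$W
  }

  e_baseline <- run_test(tr$W)
  W_cut <- apply_lesion(tr$W, cfg$injury$Bloss_injury, child_seed(seed, 5))
  W_cut_t <- one_rep(W_cut, 1L)
  e_injury <- run_test(W_cut_t)

  W_s1 <- apply_rewiring_stage(W_cut_t, 1L, cfg, patterns,
                               seed = child_seed(seed, 6), mode = mode)
  added <- attr(W_s1, "added")
  W_s1_t <- one_rep(W_s1, 2L)
  e_stage1 <- run_test(W_s1_t)

  W_s2 <- apply_rewiring_stage(W_s1_t, 2L, cfg, patterns,
                               seed = child_seed(seed, 7),
                               added_stage1 = added, mode = mode)
  W_s2_t <- one_rep(W_s2, 3L)
  e_stage2 <- run_test(W_s2_t)

  list(errors = c(baseline = e_baseline, injury = e_injury,
                  stage1 = e_stage1, stage2 = e_stage2),
       W = list(baseline = tr$W, injury = W_cut_t, stage1 = W_s1_t,
                stage2 = W_s2_t),
       added_stage1 = added, patterns = patterns)
}

#' Staged lesion-and-rewiring experiment
#'
#' Per run: full training, recall test (baseline error), cut 34% of
#' connections, one training repetition, test (injury error), stage-1
#' rewiring + one repetition + test, stage-2 rewiring + one repetition +
#' test.  The stage-2 error is the headline post-lesion result.
#'
#' @param cfg A [network_config()] with a calibrated beta.
#' @param n_sims,repeats Runs (`n_sims x repeats` in total).
#' @param seed Master seed.
#' @param mode Optional override of the rewiring mode
#'   (`"optimal"`/`"random"`).
#' @param plasticity_on Hebbian learning during training runs (disable to
#'   isolate the pure weight-surgery effect of the stages).
#' @return An `injury_result` data.frame: one row per run with the four
#'   stage errors; `summary()` reports mean +/- sd per stage.
#' @export
run_injury_experiment <- function(cfg, n_sims = 50L, repeats = 3L, seed = 1L,
                                  mode = NULL, plasticity_on = TRUE) {
  rows <- list()
  for (i in seq_len(n_sims)) {
    for (r in seq_len(repeats)) {
      u <- injury_unit(cfg, child_seed(seed, i * 1000 + r), mode = mode,
                       plasticity_on = plasticity_on)
      rows[[length(rows) + 1L]] <- data.frame(
        sim = i, repeat. = r,
        error_baseline = u$errors[["baseline"]],
        error_injury = u$errors[["injury"]],
        error_stage1 = u$errors[["stage1"]],
        error_stage2 = u$errors[["stage2"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "condition") <- cfg$condition
  class(out) <- c("injury_result", "data.frame")
  out
}

#' @export
summary.injury_result <- function(object, ...) {
  stages <- c("error_baseline", "error_injury", "error_stage1", "error_stage2")
  s <- data.frame(
    stage = sub("error_", "", stages),
    mean = vapply(stages, function(v) mean(object[[v]]), numeric(1)),
    sd = vapply(stages, function(v) stats::sd(object[[v]]), numeric(1))
  )
  cat(sprintf("Injury experiment (%s): %d runs\n",
              attr(object, "condition"), nrow(object)))
  print(s, row.names = FALSE, digits = 3)
  invisible(s)
}
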