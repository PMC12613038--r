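#' Generate a synthetic longitudinal bouton-tracking dataset
#'
#' Simulates per-bouton presence and intensity over the imaging sessions of
#' a focal-lesion experiment.  Each axon receives an initial complement of
#' boutons (count ~ Poisson(density x length), positions uniform along the
#' axon).  Between consecutive sessions every present bouton is lost with a
#' compounded per-day hazard, and new boutons arrive as a Poisson stream
#' proportional to the current count; in the two post-lesion windows
#' (`[0, 6 h]`, `[6 h, 1 d]`) the daily hazards are multiplied by the
#' configured boosts, separately for boutons closer/farther than
#' `close_threshold_um` from the lesion.  Lost identities are never
#' resurrected, so every bouton has one contiguous lifetime.
#'
#' Intensities are log-normal.  Boutons first appearing after the lesion
#' start small (a fixed fraction of the population median) and, while they
#' remain present, multiply their intensity by `new_bouton_growth_factor`
#' each interval until they reach the population median scale -- the
#' rewiring signature the downstream size-ratio metrics are designed to
#' detect.
#'
#' @param params A [synth_params()] object.
#' @return A `bouton_dataset`: list with `boutons` (long data.frame, one
#'   row per bouton x session: `axon_id`, `bouton_id`, `position_um`,
#'   `distance_um` (from the lesion), `session_time_days`, `present`,
#'   `intensity`), `axons` (per-axon `axon_id`, `length_um`,
#'   `lesion_position_um`), and the generating `params`.
#' @export
generate_bouton_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  validate_synth_params(params)
  set.seed(params$seed)
  times <- params$session_times
  n_sess <- length(times)

  axon_rows <- vector("list", params$n_axons)
  bouton_rows <- vector("list", params$n_axons)

  for (a in seq_len(params$n_axons)) {
    len <- max(2 * params$lesion_offset_um,
               stats::rnorm(1, params$axon_length_um[1], params$axon_length_um[2]))
    lesion_pos <- params$lesion_offset_um
    axon_id <- sprintf("axon%02d", a)
    axon_rows[[a]] <- data.frame(axon_id = axon_id, length_um = len,
                                 lesion_position_um = lesion_pos)

    n0 <- stats::rpois(1, params$epb_density_per_um * len)
    pos <- stats::runif(n0, 0, len)
    base_int <- stats::rlnorm(n0, params$intensity_meanlog, params$intensity_sdlog)
    born <- rep(1L, n0)            # session index of first presence
    died <- rep(n_sess + 1L, n0)   # first session absent (n_sess+1 = never)
    next_id <- n0 + 1L

    for (k in seq_len(n_sess - 1L)) {
      dt <- times[k + 1L] - times[k]
      close <- abs(pos - lesion_pos) < params$close_threshold_um
      gb <- boost_for_interval(times[k], times[k + 1L], params$post_lesion_gain_boost)
      lb <- boost_for_interval(times[k], times[k + 1L], params$post_lesion_loss_boost)
      p_loss <- 1 - (1 - pmin(1, params$baseline_loss_hazard * ifelse(close, lb[1], lb[2])))^dt
      p_gain_close <- 1 - (1 - min(1, params$baseline_gain_hazard * gb[1]))^dt
      p_gain_far <- 1 - (1 - min(1, params$baseline_gain_hazard * gb[2]))^dt

      alive <- born <= k & died > k
      lose <- alive & stats::runif(length(pos)) < p_loss
      died[lose] <- k + 1L

      # gains arrive in proportion to the close/far populations
      n_alive_close <- sum(alive & close)
      n_alive_far <- sum(alive & !close)
      n_new <- stats::rpois(1, n_alive_close * p_gain_close) +
        stats::rpois(1, n_alive_far * p_gain_far)
      if (n_new > 0) {
        newpos <- stats::runif(n_new, 0, len)
        pos <- c(pos, newpos)
        start_scale <- exp(params$intensity_meanlog) *
          if (times[k + 1L] > 0) 0.37 else 1
        newint <- if (times[k + 1L] > 0) {
          start_scale * exp(stats::rnorm(n_new, 0, 0.05))
        } else {
          stats::rlnorm(n_new, params$intensity_meanlog, params$intensity_sdlog)
        }
        base_int <- c(base_int, newint)
        born <- c(born, rep(k + 1L, n_new))
        died <- c(died, rep(n_sess + 1L, n_new))
        next_id <- next_id + n_new
      }
    }

    nb <- length(pos)
    if (nb == 0L) {
      bouton_rows[[a]] <- NULL
      next
    }
    # per-session intensity trajectories
    inten <- matrix(NA_real_, nb, n_sess)
    med <- exp(params$intensity_meanlog)
    for (b in seq_len(nb)) {
      cur <- base_int[b]
      is_new <- times[born[b]] > 0
      for (k in seq_len(n_sess)) {
        if (k >= born[b] && k < died[b]) {
          inten[b, k] <- cur * exp(stats::rnorm(1, 0, 0.02))
          if (is_new && cur < med) cur <- cur * params$new_bouton_growth_factor
        }
      }
    }
    present <- outer(seq_len(nb), seq_len(n_sess),
                     function(b, k) born[b] <= k & died[b] > k)
    bouton_rows[[a]] <- data.frame(
      axon_id = axon_id,
      bouton_id = sprintf("%s_b%04d", axon_id, rep(seq_len(nb), each = n_sess)),
      position_um = rep(pos, each = n_sess),
      distance_um = rep(abs(pos - lesion_pos), each = n_sess),
      session_time_days = rep(times, nb),
      present = as.integer(t(present)),
      intensity = as.vector(t(inten))
    )
  }

  out <- list(
    boutons = do.call(rbind, bouton_rows),
    axons = do.call(rbind, axon_rows),
    params = params
  )
  class(out) <- "bouton_dataset"
  out
}

# boost pair (close, far) active in the post-lesion sub-day windows, 1 otherwise
boost_for_interval <- function(t0, t1, boost) {
  if ((t0 >= 0 && t1 <= 0.25) || (t0 >= 0.25 && t1 <= 1)) boost else c(1, 1)
}

#' @export
print.bouton_dataset <- function(x, ...) {
  nb <- length(unique(x$boutons$bouton_id))
  cat(sprintf("Bouton-tracking dataset: %d axons, %d boutons, %d sessions\n",
              nrow(x$axons), nb, length(x$params$session_times)))
  invisible(x)
}

#' @export
summary.bouton_dataset <- function(object, ...) {
  pres <- stats::aggregate(present ~ session_time_days, object$boutons, sum)
  names(pres)[2] <- "n_present"
  cat("Boutons present per session:\n")
  print(pres, row.names = FALSE)
  invisible(pres)
}

#' Write / read the bouton-track CSV schema
#'
#' Long format, one row per bouton x session, UTF-8, '.' decimal.  Columns:
#' `axon_id`, `bouton_id`, `position_um`, `distance_um`,
#' `session_time_days`, `present` (0/1), `intensity` (empty when absent).
#' A JSON sidecar (`<stem>_params.json`) and an axon table
#' (`<stem>_axons.csv`) carry provenance and axon geometry.
#'
#' @param dataset A `bouton_dataset`.
#' @param path Path of the main CSV file.
#' @return `write_bouton_csv()` returns `path` invisibly;
#'   `read_bouton_csv()` returns a `bouton_dataset`.
#' @export
write_bouton_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "bouton_dataset"))
  utils::write.csv(dataset$boutons, path, row.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  utils::write.csv(dataset$axons, paste0(stem, "_axons.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$params), paste0(stem, "_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bouton_csv
#' @export
read_bouton_csv <- function(path) {
  stem <- sub("\\.csv$", "", path)
  boutons <- utils::read.csv(path, stringsAsFactors = FALSE)
  axons <- utils::read.csv(paste0(stem, "_axons.csv"), stringsAsFactors = FALSE)
  params_path <- paste0(stem, "_params.json")
  params <- NULL
  if (file.exists(params_path)) {
    raw <- jsonlite::read_json(params_path, simplifyVector = TRUE)
    params <- do.call(synth_params, raw)
  }
  out <- list(boutons = boutons, axons = axons, params = params)
  class(out) <- "bouton_dataset"
  out
}
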