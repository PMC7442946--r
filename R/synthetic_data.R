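#' Parameters of a synthetic two-role momentary-assessment study
#'
#' Full generative specification of a simulated EMA/PeerMA study with known
#' ground truth, so that every pipeline stage — and the recovery of the
#' participant-peer coupling, bias, and lag it is supposed to detect — can
#' be exercised without field data.
#'
#' The generative model, per dyad and state: the participant carries a
#' latent daily state following a mean-reverting AR(1) on the logit scale,
#' squashed into `(0, 1)`; prompt-level participant responses add small
#' within-day noise. The peer's daily view is a convex mixture
#' `coupling * latent(day - lag_days) + (1 - coupling) * independent latent
#' + bias`, plus observation noise at the prompt level. Each scheduled
#' prompt is answered independently with the role's response rate
#' (notification expiry acts only through non-response, so it is modelled
#' implicitly by this Bernoulli). Peer confidence is drawn from a
#' high-confidence or low-confidence component according to a daily contact
#' indicator. All emitted values are clipped to the raw scale.
#'
#' Defaults mirror a dense-schedule feasibility study: 20 dyads observed for
#' 28 days under the 8-prompts/day protocol, participant and peer response
#' rates of 65% and 44%.
#'
#' @param n_dyads Number of dyads.
#' @param n_days Days in study.
#' @param config A [study_config()]; defaults to [study_a_config()].
#' @param latent List: `ar_coefficient` (in `(-1, 1)`), `innovation_sd`
#'   (logit scale), `state_means` (named, on `[0, 1]`; unnamed states
#'   default to 0.4), `within_day_sd` (response scale, 0-1 units).
#' @param peer_model List: `coupling` (in `[0, 1]`), `bias`,
#'   `observation_sd` (both 0-1 units), `lag_days` (integer `>= 0`).
#' @param response List: `participant_rate`, `peer_rate` in `[0, 1]`.
#' @param confidence_model List: `contact_probability`,
#'   `high_confidence_mean`, `low_confidence_mean` (raw scale), `sd`.
#' @param start_date First calendar day of the simulated study.
#' @param seed Integer seed used by [generate_study()].
#' @return A validated `peerma_sim_params` list.
#' @export
sim_params <- function(n_dyads = 20L, n_days = 28L,
                       config = study_a_config(),
                       latent = list(), peer_model = list(),
                       response = list(), confidence_model = list(),
                       start_date = as.Date("2024-03-04"),
                       seed = 1L) {
  latent <- utils::modifyList(
    list(ar_coefficient = 0.5, innovation_sd = 0.5,
         state_means = NULL, within_day_sd = 0.05), latent)
  peer_model <- utils::modifyList(
    list(coupling = 0.7, bias = 0, observation_sd = 0.1, lag_days = 0L),
    peer_model)
  response <- utils::modifyList(
    list(participant_rate = 0.65, peer_rate = 0.44), response)
  confidence_model <- utils::modifyList(
    list(contact_probability = 0.7, high_confidence_mean = 8,
         low_confidence_mean = 2, sd = 1), confidence_model)
  means <- setNames(rep(0.4, length(config$states)), config$states)
  if (!is.null(latent$state_means)) {
    known <- intersect(names(latent$state_means), config$states)
    means[known] <- latent$state_means[known]
  }
  latent$state_means <- means
  stopifnot(
    n_dyads >= 1L, n_days >= 1L,
    abs(latent$ar_coefficient) < 1, latent$innovation_sd >= 0,
    latent$within_day_sd >= 0,
    all(means >= 0 & means <= 1),
    peer_model$coupling >= 0, peer_model$coupling <= 1,
    peer_model$observation_sd >= 0, peer_model$lag_days >= 0L,
    response$participant_rate >= 0, response$participant_rate <= 1,
    response$peer_rate >= 0, response$peer_rate <= 1,
    confidence_model$contact_probability >= 0,
    confidence_model$contact_probability <= 1,
    confidence_model$high_confidence_mean >= 0,
    confidence_model$high_confidence_mean <= config$scale_max,
    confidence_model$low_confidence_mean >= 0,
    confidence_model$low_confidence_mean <= config$scale_max
  )
  structure(
    list(n_dyads = as.integer(n_dyads), n_days = as.integer(n_days),
         config = config, latent = latent, peer_model = peer_model,
         response = response, confidence_model = confidence_model,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "peerma_sim_params"
  )
}

#' Draw one day's signal-contingent prompt schedule
#'
#' Draws `signals_per_day` prompt times uniformly inside the daily window,
#' redrawing the whole day until every adjacent gap respects
#' `min_separation` (rejection sampling, so accepted schedules follow the
#' uniform distribution conditioned on feasibility).
#'
#' @param config A [study_config()]; infeasible configurations are already
#'   rejected at construction.
#' @return Sorted numeric vector of prompt times, minutes since midnight.
#' @export
generate_schedule <- function(config) {
  k <- config$signals_per_day
  for (i in seq_len(100000L)) {
    t <- sort(stats::runif(k, config$window_start, config$window_end))
    if (k == 1L || all(diff(t) >= config$min_separation)) return(t)
  }
  stop("could not draw a feasible schedule", call. = FALSE)  # nocov
}

# mean-reverting AR(1) on the logit scale, squashed to (0,1)
latent_series <- function(n_days, mean01, phi, innovation_sd) {
  m <- stats::qlogis(pmin(pmax(mean01, 0.02), 0.98))
  z <- numeric(n_days)
  z[1] <- m + stats::rnorm(1, 0, innovation_sd)
  for (t in seq_len(n_days - 1L)) {
    z[t + 1L] <- m + phi * (z[t] - m) + stats::rnorm(1, 0, innovation_sd)
  }
  stats::plogis(z)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate one dyad's assessment records and ground truth
#'
#' Uses the current RNG state; callers wanting reproducibility seed once
#' (as [generate_study()] does) before simulating all dyads.
#'
#' @param params A [sim_params()] object.
#' @param dyad_index Positive integer identifying the dyad; person ids are
#'   `S<i>` (participant) and `S<i>P1` (peer).
#' @return List with `records` (assessment tibble on the raw scale,
#'   satisfying all record invariants) and `truth` (per day x state tibble
#'   of the participant's latent and the peer's noise-free daily view, plus
#'   the dyad's coupling, bias, and lag).
#' @export
simulate_dyad <- function(params, dyad_index = 1L) {
  cfg <- params$config
  pm <- params$peer_model
  lat <- params$latent
  states <- cfg$states
  n_days <- params$n_days
  dyad_id <- sprintf("dyad%02d", dyad_index)
  participant <- sprintf("S%d", dyad_index)
  peer <- sprintf("S%dP1", dyad_index)
  dates <- params$start_date + seq_len(n_days) - 1L

  truth <- vector("list", length(states))
  records <- vector("list", 2L * length(states))
  # daily contact drives which confidence component the peer draws from
  contact <- stats::runif(n_days) < params$confidence_model$contact_probability

  # response outcome per prompt instance (all states of a prompt share it)
  day_sched <- lapply(seq_len(n_days), function(d) {
    list(participant = generate_schedule(cfg), peer = generate_schedule(cfg))
  })
  answered_p <- lapply(day_sched, function(s)
    stats::runif(length(s$participant)) < params$response$participant_rate)
  answered_r <- lapply(day_sched, function(s)
    stats::runif(length(s$peer)) < params$response$peer_rate)
  conf_prompt <- lapply(seq_len(n_days), function(d) {
    mu <- if (contact[d]) params$confidence_model$high_confidence_mean else
      params$confidence_model$low_confidence_mean
    pmin(cfg$scale_max,
         pmax(0, stats::rnorm(length(day_sched[[d]]$peer), mu,
                              params$confidence_model$sd)))
  })

  for (si in seq_along(states)) {
    st <- states[si]
    lp <- latent_series(n_days, lat$state_means[[st]], lat$ar_coefficient,
                        lat$innovation_sd)
    li <- latent_series(n_days, lat$state_means[[st]], lat$ar_coefficient,
                        lat$innovation_sd)
    lagged <- lp[pmax(seq_len(n_days) - pm$lag_days, 1L)]
    peer_daily <- clip01(pm$coupling * lagged +
                           (1 - pm$coupling) * li + pm$bias)
    truth[[si]] <- tibble::tibble(
      dyad_id = dyad_id, state = st, day = seq_len(n_days), date = dates,
      latent_participant = lp, peer_daily = peer_daily)

    mk <- function(person, role, day, times, vals, conf) {
      tibble::tibble(
        study_id = "sim", dyad_id = dyad_id, person_id = person,
        role = role, state = st,
        value = vals, confidence = conf,
        timestamp = as.POSIXct(paste(dates[day], "00:00"), tz = "UTC") +
          60 * floor(times),
        trigger = "signal")
    }
    recs_p <- recs_r <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      keep <- answered_p[[d]]
      if (any(keep)) {
        tms <- day_sched[[d]]$participant[keep]
        v <- clip01(lp[d] + stats::rnorm(length(tms), 0, lat$within_day_sd))
        recs_p[[d]] <- mk(participant, "participant", d, tms,
                          v * cfg$scale_max, NA_real_)
      }
      keep <- answered_r[[d]]
      if (any(keep)) {
        tms <- day_sched[[d]]$peer[keep]
        v <- clip01(peer_daily[d] +
                      stats::rnorm(length(tms), 0, pm$observation_sd))
        recs_r[[d]] <- mk(peer, "peer", d, tms, v * cfg$scale_max,
                          conf_prompt[[d]][keep])
      }
    }
    records[[2L * si - 1L]] <- dplyr::bind_rows(recs_p)
    records[[2L * si]] <- dplyr::bind_rows(recs_r)
  }
  truth <- dplyr::bind_rows(truth)
  truth$coupling <- pm$coupling
  truth$bias <- pm$bias
  truth$lag_days <- pm$lag_days
  list(records = dplyr::bind_rows(records), truth = truth)
}

#' Simulate a full synthetic study in memory
#'
#' Seeds the RNG from `params$seed` and simulates all dyads; a fixed seed
#' reproduces the dataset exactly.
#'
#' @param params A [sim_params()] object.
#' @return List with `records` (all dyads) and `truth`.
#' @export
simulate_study <- function(params) {
  set.seed(params$seed)
  sims <- lapply(seq_len(params$n_dyads), function(i)
    simulate_dyad(params, i))
  list(records = dplyr::bind_rows(lapply(sims, `[[`, "records")),
       truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")))
}

#' Generate a synthetic study on disk
#'
#' Writes `assessments.csv` (long format, see [read_assessments()]),
#' `ground_truth.csv` (per dyad x state x day: latent participant state,
#' noise-free peer view, true coupling, bias, lag), and `manifest.json`
#' echoing the configuration, seed, and row counts. Identical parameters
#' and seed produce byte-identical files.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with the two tibbles and the file paths.
#' @export
generate_study <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  sim <- simulate_study(params)
  paths <- list(
    assessments = file.path(out_dir, "assessments.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_assessments(sim$records, paths$assessments)
  readr::write_csv(sim$truth, paths$ground_truth, progress = FALSE)
  cfg <- params$config
  manifest <- list(
    generator = "peerma::generate_study",
    version = as.character(utils::packageVersion("peerma")),
    seed = params$seed,
    n_dyads = params$n_dyads, n_days = params$n_days,
    config = list(
      window_start = format_tod(cfg$window_start),
      window_end = format_tod(cfg$window_end),
      signals_per_day = cfg$signals_per_day,
      min_separation = cfg$min_separation,
      expiry = cfg$expiry, scale_max = cfg$scale_max, states = cfg$states),
    latent = params$latent, peer_model = params$peer_model,
    response = params$response, confidence_model = params$confidence_model,
    rows = list(assessments = nrow(sim$records), ground_truth = nrow(sim$truth))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(sim, list(paths = paths)))
}
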