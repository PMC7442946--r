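#' Per-person min-max normalization of assessment values
#'
#' Rescales each person's assessments of each state to `[0, 1]` using that
#' person's own minimum and maximum: `v' = (v - min) / (max - min)`. This is
#' the usual conditioning step before comparing visual-analog style momentary
#' assessments across people, whose idiosyncratic scale use would otherwise
#' dominate. The transform is affine within each `(person, state)` group, so
#' it preserves value order and leaves rank-based statistics downstream
#' (Spearman correlations) unchanged.
#'
#' A degenerate group in which every value is identical carries no range
#' information; it is mapped to the scale midpoint 0.5 and a warning is
#' emitted, keeping the series usable for directional analysis (all flat)
#' without fabricating extremes.
#'
#' @param records Assessment tibble (see [read_assessments()]).
#' @return The records with `value` replaced by its normalized counterpart
#'   (confidence is left on the raw scale).
#' @export
normalize_per_person <- function(records) {
  if (nrow(records) == 0L) return(records)
  out <- records |>
    dplyr::group_by(.data$study_id, .data$person_id, .data$state) |>
    dplyr::mutate(
      .rng = max(.data$value) - min(.data$value),
      value = dplyr::if_else(
        .data$.rng > 0,
        (.data$value - min(.data$value)) / .data$.rng,
        0.5
      )
    ) |>
    dplyr::ungroup()
  degen <- out |>
    dplyr::filter(.data$.rng == 0) |>
    dplyr::distinct(.data$person_id, .data$state)
  if (nrow(degen) > 0L) {
    warning("constant value group(s) normalized to 0.5: ",
            paste(paste0(degen$person_id, "/", degen$state), collapse = ", "),
            call. = FALSE)
  }
  out$.rng <- NULL
  out
}

#' Derived well-being from stress, fatigue, and anxiety
#'
#' Computed well-being is defined as one minus the arithmetic mean of the
#' three normalized negative states: high stress, fatigue, or anxiety lowers
#' well-being; all three at zero gives well-being 1. All inputs must already
#' be on the `[0, 1]` scale.
#'
#' @param stress,fatigue,anxiety Normalized values in `[0, 1]`; vectorized.
#' @return `1 - (stress + fatigue + anxiety) / 3`, `NA` where any input is
#'   missing.
#' @examples
#' computed_wellbeing(0.2, 0.4, 0.6)  # 0.6
#' @export
computed_wellbeing <- function(stress, fatigue, anxiety) {
  vals <- cbind(stress, fatigue, anxiety)
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("inputs must be normalized to [0, 1]", call. = FALSE)
  }
  1 - (stress + fatigue + anxiety) / 3
}

#' Append instance-level computed well-being records
#'
#' A survey instance is the group of states sharing one `(person, timestamp)`.
#' For every instance in which stress, fatigue, and anxiety were all
#' answered, one derived record with state `"wellbeing_computed"` and value
#' [computed_wellbeing()] is appended; instances missing any of the three
#' contribute nothing. Daily means of the derived series are then means of
#' instance-level values, matching the assessment-level semantics of the raw
#' states.
#'
#' @param records Normalized assessment tibble.
#' @return The input records plus the derived `"wellbeing_computed"` rows.
#' @export
add_computed_wellbeing <- function(records) {
  need <- c("stress", "fatigue", "anxiety")
  wide <- records |>
    dplyr::filter(.data$state %in% need) |>
    tidyr::pivot_wider(
      id_cols = c("study_id", "dyad_id", "person_id", "role",
                  "timestamp", "trigger"),
      names_from = "state", values_from = "value"
    )
  for (s in setdiff(need, names(wide))) wide[[s]] <- NA_real_
  complete <- wide |>
    dplyr::filter(!is.na(.data$stress), !is.na(.data$fatigue),
                  !is.na(.data$anxiety)) |>
    dplyr::mutate(
      state = "wellbeing_computed",
      value = computed_wellbeing(.data$stress, .data$fatigue, .data$anxiety),
      confidence = NA_real_
    ) |>
    dplyr::select(dplyr::all_of(ASSESSMENT_COLS))
  dplyr::bind_rows(records, complete)
}

#' Paired daily series for one dyad and state
#'
#' Averages all of a person's same-day assessments of a state into one value
#' per calendar date, then aligns the participant and the peer on the dyad's
#' full date range (first to last day either member reported). Days on which
#' a person gave no assessment carry `NA`, never 0 — the distinction between
#' "absent" and "zero" is essential for every downstream statistic.
#'
#' @param records Normalized assessment tibble.
#' @param dyad_id,state Dyad and state to extract.
#' @return A `peerma_daily` tibble with columns `dyad_id`, `state`, `date`,
#'   `participant_mean`, `peer_mean`, `participant_n`, `peer_n`; dates
#'   strictly increasing and gap-free.
#' @export
daily_aggregate <- function(records, dyad_id, state) {
  sub <- records[records$dyad_id == dyad_id & records$state == state, ]
  if (nrow(sub) == 0L) {
    stop("no records for dyad '", dyad_id, "', state '", state, "'",
         call. = FALSE)
  }
  daily <- sub |>
    dplyr::mutate(date = as.Date(.data$timestamp)) |>
    dplyr::group_by(.data$role, .data$date) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  dates <- seq(min(daily$date), max(daily$date), by = "day")
  grid <- tidyr::expand_grid(role = ROLES, date = dates)
  out <- grid |>
    dplyr::left_join(daily, by = c("role", "date")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "role", values_from = c("mean", "n")) |>
    dplyr::transmute(
      dyad_id = dyad_id, state = state, date = .data$date,
      participant_mean = .data$mean_participant,
      peer_mean = .data$mean_peer,
      participant_n = .data$n_participant,
      peer_n = .data$n_peer
    )
  class(out) <- c("peerma_daily", class(out))
  out
}

#' Fill interior gaps of a daily series with a cubic interpolating spline
#'
#' Interpolates missing values of a per-date series with an order-4
#' (degree-3, cubic) spline through the observed points, for plotting only:
#' agreement statistics always use observed data. Observed points are
#' reproduced exactly; imputed values are clipped to `[0, 1]`; leading and
#' trailing gaps are never extrapolated and stay missing. With fewer
#' non-missing support points than the spline order the series is returned
#' unchanged with a warning.
#'
#' @param values Numeric vector (one entry per consecutive date), `NA` for
#'   missing.
#' @param order Spline order; 4 (cubic) by default.
#' @return `values` with interior `NA` runs replaced by spline interpolants.
#' @export
spline_impute <- function(values, order = 4L) {
  obs <- which(!is.na(values))
  if (length(obs) < order) {
    warning("fewer than ", order,
            " support points; series returned unchanged", call. = FALSE)
    return(values)
  }
  interior <- which(is.na(values))
  interior <- interior[interior > min(obs) & interior < max(obs)]
  if (length(interior) == 0L) return(values)
  # "fmm" end conditions reproduce cubic polynomials exactly
  f <- stats::splinefun(obs, values[obs], method = "fmm")
  values[interior] <- pmin(1, pmax(0, f(interior)))
  values
}

#' Drop low-confidence peer assessments
#'
#' Peers rate how confident they are in each assessment; analyses may discard
#' low-confidence peer reports (e.g. the zero-labelled ones). Participant
#' records carry no confidence and always survive. The number of removed
#' records is reported as a message.
#'
#' @param records Assessment tibble.
#' @param min_confidence Keep peer records with `confidence >=
#'   min_confidence`; 0 keeps everything. Peer records with no recorded
#'   confidence are kept.
#' @return Filtered records.
#' @export
filter_by_confidence <- function(records, min_confidence = 0) {
  drop <- records$role == "peer" & !is.na(records$confidence) &
    records$confidence < min_confidence
  if (any(drop)) {
    message("filter_by_confidence: removed ", sum(drop),
            " peer record(s) below confidence ", min_confidence)
  }
  records[!drop, ]
}

#' Participation arithmetic over an engagement table
#'
#' Totals person-days and summarizes response rates across a set of persons,
#' mirroring the engagement tables of EMA field studies: per-person days in
#' study and response rate (answered / triggered, as a percentage) go in;
#' total person-days, mean rate (rounded to integer percent) and sample
#' standard deviation of the rate (n - 1 denominator, one decimal) come out.
#'
#' @param days Integer vector, days in study per person.
#' @param response_rates Numeric vector, response rate per person in percent
#'   (a rate above 100 is possible when self-triggered reports exceed the
#'   scheduled count).
#' @return A one-row tibble: `n_persons`, `person_days`, `rate_mean`,
#'   `rate_sd` (`NA` for a single person), plus unrounded `rate_mean_raw`,
#'   `rate_sd_raw`.
#' @export
summarize_participation <- function(days, response_rates) {
  if (length(days) == 0L) stop("no persons", call. = FALSE)
  if (length(days) != length(response_rates)) {
    stop("days and response_rates must have equal length", call. = FALSE)
  }
  m <- mean(response_rates)
  s <- if (length(response_rates) > 1L) sd(response_rates) else NA_real_
  tibble::tibble(
    n_persons = length(days),
    person_days = sum(days),
    rate_mean = round(m),
    rate_sd = round(s, 1),
    rate_mean_raw = m,
    rate_sd_raw = s
  )
}

#' Per-person summary profile of one state
#'
#' Median (midpoint convention for even n), mean, and sample standard
#' deviation of all of one person's normalized assessments of one state —
#' the per-person rows of an assessment-summary table.
#'
#' @param records Normalized assessment tibble.
#' @param person_id,state Person and state to profile.
#' @return One-row tibble: `person_id`, `state`, `n`, `median`, `mean`, `sd`.
#' @export
person_state_profile <- function(records, person_id, state) {
  v <- records$value[records$person_id == person_id &
                       records$state == state]
  if (length(v) == 0L) {
    stop("no assessments for person '", person_id, "', state '", state, "'",
         call. = FALSE)
  }
  tibble::tibble(
    person_id = person_id, state = state, n = length(v),
    median = median(v), mean = mean(v),
    sd = if (length(v) > 1L) sd(v) else 0
  )
}

#' Profiles for every person-state combination present
#'
#' @param records Normalized assessment tibble.
#' @return Tibble of [person_state_profile()] rows, plus `role`.
#' @export
all_profiles <- function(records) {
  records |>
    dplyr::group_by(.data$person_id, .data$role, .data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) sd(.data$value) else 0,
      .groups = "drop"
    )
}
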