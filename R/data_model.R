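#' @importFrom rlang .data
#' @importFrom stats median sd setNames
#' @importFrom utils head tail
NULL

# canonical column order of the long assessment table
ASSESSMENT_COLS <- c(
  "study_id", "dyad_id", "person_id", "role", "state",
  "value", "confidence", "timestamp", "trigger"
)

ROLES <- c("participant", "peer")
TRIGGERS <- c("signal", "self")
CORE_STATES <- c("stress", "fatigue", "anxiety", "wellbeing")

#' Study configuration for a momentary-assessment protocol
#'
#' Describes a signal-contingent prompting protocol: the daily prompting
#' window, the number of prompts per day, the minimum separation between
#' prompts, the notification expiry, the response scale, and the states
#' assessed. Two presets, [study_a_config()] and [study_b_config()], capture
#' the two protocols most EMA/PeerMA feasibility work uses: a dense schedule
#' (8 prompts, 9 AM-9 PM, >= 45 min apart) and a sparse one (3 prompts,
#' 8 AM-8 PM, >= 2 h apart).
#'
#' @param window_start,window_end Daily prompting window bounds, `"HH:MM"`
#'   strings (local time-of-day).
#' @param signals_per_day Number of signal-contingent prompts per day.
#' @param min_separation Minimum gap between consecutive prompts, minutes.
#' @param expiry Minutes before an unanswered notification expires. Recorded
#'   for documentation; non-response is modelled directly via response rates.
#' @param scale_max Upper bound of the raw response scale (lower bound is 0).
#' @param states Character vector of assessed states.
#' @return A `peerma_config` list.
#' @examples
#' cfg <- study_config("09:00", "21:00", signals_per_day = 8,
#'                     min_separation = 45)
#' cfg$signals_per_day
#' @export
study_config <- function(window_start = "09:00", window_end = "21:00",
                         signals_per_day = 8L, min_separation = 45,
                         expiry = 40, scale_max = 10,
                         states = c("stress", "fatigue", "anxiety")) {
  ws <- parse_tod(window_start)
  we <- parse_tod(window_end)
  if (we <= ws) {
    stop("window_end must be after window_start", call. = FALSE)
  }
  signals_per_day <- as.integer(signals_per_day)
  if (signals_per_day < 1L) stop("signals_per_day must be >= 1", call. = FALSE)
  if (min_separation < 0 || expiry < 0 || scale_max <= 0) {
    stop("min_separation, expiry must be >= 0 and scale_max > 0", call. = FALSE)
  }
  # feasibility: the (k-1) mandatory gaps must fit strictly inside the window
  if ((signals_per_day - 1L) * min_separation >= we - ws) {
    stop("infeasible schedule: (signals_per_day - 1) * min_separation ",
         "must be smaller than the window length", call. = FALSE)
  }
  states <- as.character(states)
  if (length(states) == 0L) stop("at least one state required", call. = FALSE)
  structure(
    list(window_start = ws, window_end = we,
         signals_per_day = signals_per_day,
         min_separation = as.numeric(min_separation),
         expiry = as.numeric(expiry),
         scale_max = as.numeric(scale_max),
         states = states),
    class = "peerma_config"
  )
}

#' @rdname study_config
#' @export
study_a_config <- function() {
  study_config("09:00", "21:00", signals_per_day = 8L, min_separation = 45,
               expiry = 40, scale_max = 10,
               states = c("stress", "fatigue", "anxiety"))
}

#' @rdname study_config
#' @export
study_b_config <- function() {
  study_config("08:00", "20:00", signals_per_day = 3L, min_separation = 120,
               expiry = 30, scale_max = 10,
               states = c("stress", "fatigue", "anxiety", "wellbeing"))
}

#' @export
print.peerma_config <- function(x, ...) {
  cat(sprintf(
    "<peerma_config> %d signals/day in [%s, %s], >= %g min apart, scale 0-%g\n",
    x$signals_per_day, format_tod(x$window_start), format_tod(x$window_end),
    x$min_separation, x$scale_max))
  cat("states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

# "HH:MM" -> minutes since midnight
parse_tod <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop("time-of-day must be 'HH:MM': ", x, call. = FALSE)
  as.numeric(m[2]) * 60 + as.numeric(m[3])
}

format_tod <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60, round(mins %% 60))
}

#' Read a long-format assessment table
#'
#' Reads one-row-per-response CSV with columns exactly
#' `study_id,dyad_id,person_id,role,state,value,confidence,timestamp,trigger`.
#' Timestamps are ISO-8601 to minute resolution (`YYYY-MM-DDTHH:MM`),
#' timezone-naive local time; `confidence` is empty for participant rows.
#' Every row is validated against the record invariants and violations are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param config A [study_config()]; supplies `scale_max` and the admissible
#'   state set.
#' @return A tibble of validated assessment records with typed columns
#'   (`timestamp` as POSIXct, `role`/`trigger`/`state` as character).
#' @seealso [write_assessments()], [validate_study()]
#' @export
read_assessments <- function(path, config = study_b_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      dyad_id = readr::col_character(),
      person_id = readr::col_character(),
      role = readr::col_character(),
      state = readr::col_character(),
      value = readr::col_double(),
      confidence = readr::col_double(),
      timestamp = readr::col_character(),
      trigger = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(ASSESSMENT_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[ASSESSMENT_COLS]
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad_ts <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad_ts) > 0L) {
    stop("unparseable timestamp (expected YYYY-MM-DDTHH:MM) on data row(s): ",
         paste(head(bad_ts, 5L), collapse = ", "), call. = FALSE)
  }
  raw$timestamp <- ts
  validate_assessments(raw, config)
  raw
}

#' Write a long-format assessment table
#'
#' Inverse of [read_assessments()]: `read(write(read(x)))` is the identity on
#' valid record collections (modulo floating-point formatting).
#'
#' @param records Assessment tibble as returned by [read_assessments()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path) {
  out <- records[ASSESSMENT_COLS]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate assessment records against the domain invariants
#'
#' Checks, for every record: role and trigger levels; state within the
#' configured set; value (and confidence, when present) inside
#' `[0, scale_max]`; confidence present only on peer rows; and uniqueness of
#' `(person_id, state, timestamp)` within a study. Violations abort with a
#' message naming the offending row numbers. Validation never mutates the
#' records.
#'
#' @inheritParams write_assessments
#' @param config A [study_config()].
#' @param extra_states Additional admissible state labels (derived series
#'   such as `"wellbeing_computed"`).
#' @return `records`, invisibly.
#' @export
validate_assessments <- function(records, config = study_b_config(),
                                 extra_states = "wellbeing_computed") {
  fail_rows <- function(what, idx) {
    stop(what, " on row(s): ", paste(head(idx, 5L), collapse = ", "),
         if (length(idx) > 5L) sprintf(" (and %d more)", length(idx) - 5L),
         call. = FALSE)
  }
  req <- setdiff(ASSESSMENT_COLS, names(records))
  if (length(req) > 0L) {
    stop("missing required column(s): ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0L) return(invisible(records))
  idx <- which(!records$role %in% ROLES)
  if (length(idx)) fail_rows("invalid role", idx)
  idx <- which(!records$trigger %in% TRIGGERS)
  if (length(idx)) fail_rows("invalid trigger", idx)
  ok_states <- union(config$states, extra_states)
  idx <- which(!records$state %in% ok_states)
  if (length(idx)) fail_rows("unknown state", idx)
  idx <- which(is.na(records$value) |
                 records$value < 0 | records$value > config$scale_max)
  if (length(idx)) {
    fail_rows(sprintf("value outside [0, %g]", config$scale_max), idx)
  }
  has_conf <- !is.na(records$confidence)
  idx <- which(has_conf & records$role == "participant")
  if (length(idx)) fail_rows("confidence set on a participant row", idx)
  idx <- which(has_conf &
                 (records$confidence < 0 | records$confidence > config$scale_max))
  if (length(idx)) {
    fail_rows(sprintf("confidence outside [0, %g]", config$scale_max), idx)
  }
  idx <- which(is.na(records$timestamp))
  if (length(idx)) fail_rows("missing timestamp", idx)
  key <- paste(records$study_id, records$person_id, records$state,
               format(records$timestamp, "%Y-%m-%dT%H:%M"), sep = "\r")
  idx <- which(duplicated(key))
  if (length(idx)) {
    fail_rows("duplicate (person_id, state, timestamp)", idx)
  }
  invisible(records)
}

#' Summarize a record collection and flag protocol deviations
#'
#' Produces a per-person participation overview (first/last calendar day,
#' states observed, record count) plus warnings for records outside the
#' configured daily window (self-triggered reports may legitimately fall
#' anywhere, so these are warnings, not errors) and for dyads lacking one of
#' the two roles.
#'
#' @inheritParams validate_assessments
#' @return A list of class `peerma_validation` with elements `persons`
#'   (tibble), `warnings` (character vector), and `n_records`.
#' @export
validate_study <- function(records, config = study_b_config()) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  validate_assessments(records, config)
  day <- as.Date(records$timestamp)
  persons <- records |>
    dplyr::mutate(.day = as.Date(.data$timestamp)) |>
    dplyr::group_by(.data$study_id, .data$person_id, .data$role) |>
    dplyr::summarise(
      first_day = min(.data$.day),
      last_day = max(.data$.day),
      n_records = dplyr::n(),
      states = paste(sort(unique(.data$state)), collapse = ";"),
      .groups = "drop"
    )
  warnings <- character()
  tod <- as.numeric(difftime(records$timestamp,
                             as.POSIXct(paste(day, "00:00"), tz = "UTC"),
                             units = "mins"))
  outside <- which(tod < config$window_start | tod > config$window_end)
  for (i in outside) {
    warnings <- c(warnings, sprintf(
      "record %d (%s, %s) at %s lies outside the %s-%s daily window",
      i, records$person_id[i], records$state[i],
      format(records$timestamp[i], "%Y-%m-%dT%H:%M"),
      format_tod(config$window_start), format_tod(config$window_end)))
  }
  roles_by_dyad <- records |>
    dplyr::distinct(.data$study_id, .data$dyad_id, .data$role) |>
    dplyr::count(.data$study_id, .data$dyad_id)
  incomplete <- roles_by_dyad[roles_by_dyad$n < 2L, ]
  for (i in seq_len(nrow(incomplete))) {
    warnings <- c(warnings, sprintf(
      "dyad %s has records for only one role", incomplete$dyad_id[i]))
  }
  structure(
    list(persons = persons, warnings = warnings, n_records = nrow(records)),
    class = "peerma_validation"
  )
}

#' @export
print.peerma_validation <- function(x, ...) {
  cat(sprintf("<peerma_validation> %d records, %d persons, %d warning(s)\n",
              x$n_records, nrow(x$persons), length(x$warnings)))
  if (length(x$warnings)) {
    cat(paste0("  - ", head(x$warnings, 10L), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read an entry-survey trait table
#'
#' Optional companion table of per-person scalar traits from entry surveys
#' (e.g. perceived-stress, social-desirability, or emotion-recognition
#' scores), columns `person_id,trait,score`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `person_id`, `trait`, `score`.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    trait = readr::col_character(),
    score = readr::col_double()
  ), progress = FALSE)
}
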