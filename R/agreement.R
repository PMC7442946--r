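STRENGTH_LEVELS <- c(
  "highly_positive", "moderately_positive", "weakly_positive",
  "weakly_negative", "moderately_negative", "highly_negative"
)

#' Direction of change between consecutive daily means
#'
#' Converts a per-date series into the sign of its day-to-day change:
#' `"up"` if the value increased, `"down"` if it decreased, `"flat"` if it
#' stayed put (changes smaller than `eps` in magnitude count as flat, guarding
#' against floating-point noise). A transition touching a missing day is
#' undefined (`NA`). Directional agreement deliberately ignores the magnitude
#' of change — only its sign is compared between participant and peer.
#'
#' @param values Numeric per-date vector, `NA` for days without data.
#' @param eps Half-width of the flat band; defaults to `1e-9`.
#' @return Character vector of length `length(values) - 1` with entries
#'   `"up"`, `"down"`, `"flat"`, or `NA`.
#' @examples
#' directional_changes(c(0.4, 0.3, 0.7))  # "down" "up"
#' @export
directional_changes <- function(values, eps = 1e-9) {
  if (length(values) < 2L) stop("need at least 2 dates", call. = FALSE)
  d <- diff(values)
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d > eps] <- "up"
  out[!is.na(d) & d < -eps] <- "down"
  out[!is.na(d) & abs(d) <= eps] <- "flat"
  out
}

#' Mean directional accuracy of a dyad's paired daily series
#'
#' For every consecutive-date transition on which both members' directions
#' are defined, counts whether the peer's change agrees with the
#' participant's. Two matching rules are supported:
#'
#' * `same_day` — the peer's transition over the same date pair must agree;
#' * `same_or_next_day` — agreement on the same date pair *or* on the peer's
#'   following transition also counts, capturing peers who register the
#'   participant's change with a one-day delay.
#'
#' The evaluable set (transitions where the same-day comparison is defined)
#' is identical for both rules, so `mda(same_or_next_day) >= mda(same_day)`
#' always holds. Flat only matches flat: direction is a three-valued sign.
#'
#' @param series A `peerma_daily` tibble from [daily_aggregate()], or any
#'   tibble with `participant_mean` and `peer_mean` ordered by date.
#' @param lag_window `"same_day"` or `"same_or_next_day"`.
#' @param eps Flat band passed to [directional_changes()].
#' @return One-row tibble: `lag_window`, `matches`, `evaluable`, `mda`
#'   (`NA` with zero evaluable transitions).
#' @examples
#' s <- tibble::tibble(participant_mean = c(0.4, 0.3, 0.7),
#'                     peer_mean = c(0.2, 0.4, 0.6))
#' mda(s, "same_day")  # 1 match of 2: mda 0.5
#' @export
mda <- function(series, lag_window = c("same_day", "same_or_next_day"),
                eps = 1e-9) {
  lag_window <- match.arg(lag_window)
  if (nrow(series) < 2L) stop("need at least 2 dates", call. = FALSE)
  dp <- directional_changes(series$participant_mean, eps)
  dr <- directional_changes(series$peer_mean, eps)
  evaluable <- which(!is.na(dp) & !is.na(dr))
  if (length(evaluable) == 0L) {
    warning("no evaluable transitions for this series", call. = FALSE)
    return(tibble::tibble(lag_window = lag_window, matches = 0L,
                          evaluable = 0L, mda = NA_real_))
  }
  same <- dp[evaluable] == dr[evaluable]
  if (lag_window == "same_day") {
    matches <- sum(same)
  } else {
    nxt <- evaluable + 1L
    next_ok <- nxt <= length(dr) & !is.na(dr[nxt])
    next_match <- next_ok & dp[evaluable] == dr[pmin(nxt, length(dr))]
    matches <- sum(same | next_match)
  }
  n_eval <- length(evaluable)
  tibble::tibble(lag_window = lag_window, matches = as.integer(matches),
                 evaluable = n_eval, mda = matches / n_eval)
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
all_permutations <- function(n) {
  p <- matrix(1L, 1L, 1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1L) * m + 1L):(pos * m)
      left <- if (pos > 1L) p[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos < k) p[, pos:(k - 1L), drop = FALSE] else NULL
      out[rows, ] <- cbind(left, matrix(k, m, 1L), right)
    }
    p <- out
  }
  p
}

#' Spearman rank correlation with tie correction
#'
#' Rank correlation between two paired series: Pearson correlation of
#' average (midrank) ranks, which equals the classical
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` form when no ties are present. The
#' preferred statistic when paired momentary assessments are neither
#' independent nor normally distributed. Incomplete pairs are dropped first.
#'
#' Two-sided p-values: an exact permutation null (all `n!` pairings, valid
#' under ties) for `n <= 9`, and the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom otherwise.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `r_s`, `p_value`, `n`, `strength` (see
#'   [classify_strength()]), `defined`. With fewer than 3 complete pairs or a
#'   zero-variance rank vector the result is undefined (`defined = FALSE`,
#'   statistics `NA`).
#' @examples
#' spearman_rank(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r_s = 0.6
#' @export
spearman_rank <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  undefined <- tibble::tibble(r_s = NA_real_, p_value = NA_real_, n = n,
                              strength = NA_character_, defined = FALSE)
  if (n < 3L) {
    warning("fewer than 3 complete pairs; correlation undefined",
            call. = FALSE)
    return(undefined)
  }
  rx <- rank(x)
  ry <- rank(y)
  a <- rx - mean(rx)
  b <- ry - mean(ry)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) {
    warning("zero variance in a ranked vector; correlation undefined",
            call. = FALSE)
    return(undefined)
  }
  r <- sum(a * b) / denom
  if (n <= 9L) {
    perms <- all_permutations(n)
    # correlation of rx with every permutation of ry, vectorized
    s <- matrix(b[perms], nrow(perms), n) %*% a
    p <- mean(abs(s / denom) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r_s = r, p_value = min(p, 1), n = n,
                 strength = as.character(classify_strength(r)),
                 defined = TRUE)
}

#' Wilcoxon signed-rank test for paired daily series
#'
#' Tests whether two paired sets of daily means share the same distribution
#' (null hypothesis of statistical equality between a participant's and the
#' peer's assessments). Zero differences are dropped by the signed-rank
#' convention; the statistic is the sum of ranks of positive differences.
#' The p-value is two-sided: the exact signed-rank null for `n <= 25`
#' without ties among the absolute differences, otherwise a normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Paired numeric vectors (e.g. participant and peer daily
#'   means); incomplete pairs are dropped.
#' @return One-row tibble: `p_value`, `statistic` (rank sum of positive
#'   differences), `n_pairs` (complete pairs), `n_nonzero` (pairs after zero
#'   removal), `method`, `low_power` (`TRUE` when `n_nonzero < 5`), `note`.
#'   All differences zero gives `p_value = 1` with a note.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(
      p_value = 1, statistic = 0, n_pairs = n_pairs, n_nonzero = 0L,
      method = "degenerate", low_power = TRUE,
      note = "all differences zero"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  mu <- n * (n + 1) / 4
  if (n <= 25L && !ties) {
    p <- if (w > mu) {
      2 * stats::psignrank(w - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(w, n)
    }
    method <- "exact"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  tibble::tibble(
    p_value = min(p, 1), statistic = w, n_pairs = n_pairs, n_nonzero = n,
    method = method, low_power = n < 5L,
    note = if (n < 5L) "fewer than 5 nonzero differences" else NA_character_)
}

#' Classify a correlation coefficient into one of six strength bins
#'
#' Coefficients are first rounded to two decimals (the resolution at which
#' correlation tables are reported) and then binned:
#' highly positive `[0.67, 1.00]`, moderately positive `[0.34, 0.66]`,
#' weakly positive `[0.00, 0.33]`, weakly negative `[-0.33, -0.01]`,
#' moderately negative `[-0.66, -0.34]`, highly negative `[-1.00, -0.67]`.
#' The bins partition `[-1, 1]` at two-decimal resolution; an exact 0 is
#' weakly positive.
#'
#' @param r_s Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Factor with the six strength levels.
#' @examples
#' classify_strength(c(0.44, -0.34, -0.33, 1))
#' @export
classify_strength <- function(r_s) {
  if (any(abs(r_s) > 1 + 1e-9, na.rm = TRUE)) {
    stop("|r_s| must be <= 1", call. = FALSE)
  }
  r <- round(r_s, 2)
  out <- rep(NA_character_, length(r))
  out[r >= 0.67] <- "highly_positive"
  out[r >= 0.34 & r <= 0.66] <- "moderately_positive"
  out[r >= 0.00 & r <= 0.33] <- "weakly_positive"
  out[r >= -0.33 & r <= -0.01] <- "weakly_negative"
  out[r >= -0.66 & r <= -0.34] <- "moderately_negative"
  out[r <= -0.67] <- "highly_negative"
  factor(out, levels = STRENGTH_LEVELS)
}

#' Tabulate correlation strength bins per state and overall
#'
#' Counts how many dyad-level correlation coefficients fall in each strength
#' bin, per state and in total. Per-state percentages use that state's
#' number of classified coefficients as denominator; the `"total"` rows use
#' all classified coefficients. Percentages are rounded to integers as in
#' reported summary tables.
#'
#' @param coefficients Tibble with columns `state` and `r_s` (one row per
#'   dyad x state coefficient); `NA` coefficients are ignored.
#' @return Tibble with columns `state` (including `"total"`), `strength`,
#'   `n`, `pct`.
#' @export
strength_summary <- function(coefficients) {
  coefficients <- coefficients[!is.na(coefficients$r_s), ]
  if (nrow(coefficients) == 0L) {
    return(tidyr::expand_grid(state = "total", strength = STRENGTH_LEVELS) |>
             dplyr::mutate(n = 0L, pct = 0))
  }
  classified <- coefficients |>
    dplyr::mutate(strength = as.character(classify_strength(.data$r_s)))
  one_block <- function(df, label) {
    counts <- table(factor(df$strength, levels = STRENGTH_LEVELS))
    tibble::tibble(state = label, strength = STRENGTH_LEVELS,
                   n = as.integer(counts),
                   pct = round(100 * as.integer(counts) / nrow(df)))
  }
  per_state <- classified |>
    dplyr::group_by(.data$state) |>
    dplyr::group_map(~ one_block(.x, .y$state)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_state, one_block(classified, "total"))
}

#' Fraction of dyads whose assessments are statistically equal
#'
#' Given per-dyad Wilcoxon signed-rank p-values for one state, counts the
#' dyads for which the equality null is *not* rejected at `alpha` and
#' expresses them as a share of `denominator`. Thresholding is
#' rounded-inclusive: p-values are rounded to two decimals (the precision at
#' which they are reported) and a rounded p equal to `alpha` counts as
#' equal. A `denominator` larger than the number of supplied p-values treats
#' the unlisted dyads as not-equal.
#'
#' @param p_values Numeric vector of p-values (one per dyad).
#' @param alpha Significance threshold, default 0.05.
#' @param denominator Total number of dyads; defaults to
#'   `length(p_values)`.
#' @return One-row tibble: `n_equal`, `denominator`, `pct` (integer
#'   percent).
#' @export
equality_fraction <- function(p_values, alpha = 0.05,
                              denominator = length(p_values)) {
  if (denominator <= 0L) stop("denominator must be positive", call. = FALSE)
  if (denominator < length(p_values)) {
    stop("denominator smaller than the number of p-values", call. = FALSE)
  }
  n_equal <- sum(round(p_values, 2) >= alpha, na.rm = TRUE)
  tibble::tibble(n_equal = as.integer(n_equal),
                 denominator = as.integer(denominator),
                 pct = round(100 * n_equal / denominator))
}

#' Mean arctangent absolute percentage error
#'
#' Residual metric between an observed series and a reference series:
#' the mean of `atan(|(actual - predicted) / actual|)`. Unlike MAPE it stays
#' finite when the reference value is 0 — that term contributes
#' `atan(Inf) = pi/2` (or 0 when the prediction is also exact). Values lie
#' in `[0, pi/2]`.
#'
#' @param actual,predicted Paired numeric vectors; incomplete pairs dropped.
#' @return MAAPE in radians.
#' @examples
#' maape(c(1, 2), c(2, 2))  # pi/8
#' @export
maape <- function(actual, predicted) {
  ok <- !is.na(actual) & !is.na(predicted)
  a <- actual[ok]
  f <- predicted[ok]
  if (length(a) == 0L) stop("no complete pairs", call. = FALSE)
  term <- ifelse(a == f, 0,
                 ifelse(a == 0, pi / 2, atan(abs((a - f) / a))))
  mean(term)
}

#' Mean absolute percentage error
#'
#' Classical MAPE, provided for comparison with [maape()]; undefined
#' (non-finite) whenever the reference series contains a 0 with a nonzero
#' residual.
#'
#' @inheritParams maape
#' @return MAPE as a fraction (multiply by 100 for percent).
#' @export
mape <- function(actual, predicted) {
  ok <- !is.na(actual) & !is.na(predicted)
  a <- actual[ok]
  f <- predicted[ok]
  if (length(a) == 0L) stop("no complete pairs", call. = FALSE)
  mean(abs((a - f) / a))
}

#' Rank correlation between two per-unit scalar columns
#'
#' Convenience wrapper delegating to [spearman_rank()] for profile-level
#' analyses: correlating two states' per-person medians (do people treat two
#' constructs alike?), an entry-survey trait against per-dyad agreement
#' coefficients, or participant medians against peer medians for one state.
#'
#' @param table Tibble with one row per unit (person or dyad), already
#'   aligned.
#' @param col_a,col_b Names of the two numeric columns to correlate.
#' @return As [spearman_rank()].
#' @export
profile_correlation <- function(table, col_a, col_b) {
  for (cl in c(col_a, col_b)) {
    if (!cl %in% names(table)) stop("no column '", cl, "'", call. = FALSE)
  }
  spearman_rank(table[[col_a]], table[[col_b]])
}
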