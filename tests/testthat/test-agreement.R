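test_that("directional changes classify sign of day-to-day movement", {
  expect_equal(directional_changes(c(0.4, 0.3, 0.7)), c("down", "up"))
  expect_equal(directional_changes(rep(0.5, 4)), rep("flat", 3))
  expect_equal(directional_changes(c(0.2, NA, 0.5)),
               c(NA_character_, NA_character_))
  # sub-epsilon jitter counts as flat
  expect_equal(directional_changes(c(0.5, 0.5 + 1e-12)), "flat")
  expect_error(directional_changes(0.5), "at least 2")
})

test_that("mda counts matches over evaluable transitions", {
  s <- tibble::tibble(participant_mean = c(0.4, 0.3, 0.7),
                      peer_mean = c(0.2, 0.4, 0.6))
  out <- mda(s, "same_day")
  expect_equal(out$matches, 1L)
  expect_equal(out$evaluable, 2L)
  expect_equal(out$mda, 0.5)

  # identical monotone-step series agree perfectly
  v <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  same <- tibble::tibble(participant_mean = v, peer_mean = v)
  expect_equal(mda(same, "same_day")$mda, 1)

  # peer lagging by one day: same-day chance-like, next-day recovers
  lagged <- tibble::tibble(participant_mean = c(0.1, 0.5, 0.2, 0.7),
                           peer_mean = c(0.6, 0.1, 0.5, 0.2))
  expect_equal(mda(lagged, "same_day")$mda, 0)
  expect_equal(mda(lagged, "same_or_next_day")$mda, 2 / 3)

  # all-missing peer: zero evaluable, flagged
  none <- tibble::tibble(participant_mean = c(0.1, 0.2),
                         peer_mean = c(NA_real_, NA_real_))
  expect_warning(out0 <- mda(none, "same_day"), "no evaluable")
  expect_equal(out0$evaluable, 0L)
  expect_true(is.na(out0$mda))
})

test_that("same-or-next-day mda dominates same-day mda on random series", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    p <- runif(n)
    r <- runif(n)
    p[runif(n) < 0.2] <- NA
    r[runif(n) < 0.2] <- NA
    s <- tibble::tibble(participant_mean = p, peer_mean = r)
    res <- suppressWarnings(
      list(sd = mda(s, "same_day"), nd = mda(s, "same_or_next_day")))
    expect_identical(res$sd$evaluable, res$nd$evaluable)
    if (res$sd$evaluable > 0) {
      expect_gte(res$nd$mda, res$sd$mda)
    }
    # same-day mda is symmetric in the two members
    flipped <- tibble::tibble(participant_mean = r, peer_mean = p)
    expect_equal(suppressWarnings(mda(flipped, "same_day"))$mda, res$sd$mda)
  }
})

test_that("spearman_rank matches the closed form on tie-free vectors", {
  out <- spearman_rank(c(1, 2, 3), c(10, 20, 30))
  expect_equal(out$r_s, 1)
  out2 <- spearman_rank(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out2$r_s, 0.6)  # 1 - 6 * 4 / (4 * 15)
  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(1000, n)
    y <- sample(1000, n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_rank(x, y)$r_s,
                 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
})

test_that("small-n spearman p-values equal the exhaustive permutation null", {
  set.seed(303)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    x <- sample(100, n)
    y <- sample(100, n)
    ours <- spearman_rank(x, y)
    orc <- spearman_oracle(x, y)
    expect_equal(ours$r_s, orc$r, tolerance = 1e-12)
    expect_equal(ours$p_value, orc$p, tolerance = 1e-12)
    # base R's exact route agrees on tie-free data
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(ours$p_value, unname(ct$p.value), tolerance = 1e-9)
  }
})

test_that("large-n spearman uses the t approximation and stays symmetric", {
  set.seed(404)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  ours <- spearman_rank(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$r_s, unname(ct$estimate))
  r <- ours$r_s
  tt <- r * sqrt((30 - 2) / (1 - r^2))
  expect_equal(ours$p_value, 2 * pt(-abs(tt), 28))
  expect_equal(spearman_rank(y, x)$r_s, ours$r_s)
  expect_equal(spearman_rank(y, x)$p_value, ours$p_value)
})

test_that("degenerate correlation inputs are flagged undefined", {
  expect_warning(out <- spearman_rank(c(1, 2), c(3, 4)), "fewer than 3")
  expect_false(out$defined)
  expect_warning(out2 <- spearman_rank(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_false(out2$defined)
  # missing pairs dropped before the n >= 3 check
  expect_warning(spearman_rank(c(1, 2, NA, 4), c(1, NA, 3, 4)),
                 "fewer than 3")
})

test_that("signed-rank test recovers exact and approximate conventions", {
  # identical series: everything cancels
  x <- c(0.1, 0.4, 0.7)
  out <- wilcoxon_signed_rank(x, x)
  expect_equal(out$p_value, 1)
  expect_match(out$note, "all differences zero")

  # all-positive differences, n = 6: two-sided exact p = 2/64
  out2 <- wilcoxon_signed_rank(7:12, 6:11 - c(0, 1, 2, 3, 4, 5))
  expect_equal(out2$p_value, 2 / 64)
  expect_equal(out2$method, "exact")

  out3 <- wilcoxon_signed_rank(c(1, 2, 3), c(3, 2, 1))
  expect_true(out3$low_power)
})

test_that("signed-rank p equals the exhaustive sign-flip oracle", {
  set.seed(505)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    expect_equal(ours$p_value, signed_rank_oracle(x, y), tolerance = 1e-12)
    wt <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("tied differences switch to the corrected normal approximation", {
  set.seed(606)
  x <- round(runif(30, 0, 1), 1)
  y <- round(runif(30, 0, 1), 1)
  ours <- wilcoxon_signed_rank(x, y)
  expect_equal(ours$method, "normal_approximation")
  wt <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, correct = TRUE))
  expect_equal(ours$p_value, wt$p.value, tolerance = 1e-12)
  # invariance under member exchange
  expect_equal(wilcoxon_signed_rank(y, x)$p_value, ours$p_value)
})

test_that("strength bins partition [-1, 1] with two-decimal boundaries", {
  expect_equal(as.character(classify_strength(0.44)), "moderately_positive")
  expect_equal(as.character(classify_strength(-0.34)), "moderately_negative")
  expect_equal(as.character(classify_strength(-0.33)), "weakly_negative")
  expect_equal(as.character(classify_strength(1)), "highly_positive")
  expect_equal(as.character(classify_strength(0)), "weakly_positive")
  expect_error(classify_strength(1.2), "must be <= 1")
  # every two-decimal coefficient lands in exactly one bin
  grid <- seq(-1, 1, by = 0.01)
  bins <- classify_strength(grid)
  expect_false(anyNA(bins))
  # rounding first: -0.334 is weakly negative, -0.335 moderately negative
  expect_equal(as.character(classify_strength(-0.334)), "weakly_negative")
  expect_equal(as.character(classify_strength(-0.336)),
               "moderately_negative")
})

test_that("strength summary counts per state with integer percentages", {
  coefs <- tibble::tibble(
    state = rep(c("stress", "fatigue"), each = 4),
    r_s = c(0.7, 0.4, 0.1, -0.1, 0.2, 0.2, -0.4, -0.8))
  out <- strength_summary(coefs)
  stress <- out[out$state == "stress", ]
  expect_equal(stress$n[stress$strength == "highly_positive"], 1L)
  expect_equal(stress$pct[stress$strength == "highly_positive"], 25)
  total <- out[out$state == "total", ]
  expect_equal(sum(total$n), 8L)
  expect_equal(total$n[total$strength == "weakly_positive"], 3L)
  expect_equal(total$pct[total$strength == "weakly_positive"], 38)
  empty <- strength_summary(tibble::tibble(state = character(),
                                           r_s = numeric()))
  expect_true(all(empty$n == 0L))
})

test_that("equality fractions use rounded-inclusive thresholding", {
  out <- equality_fraction(c(0.05, 0.051, 0.049, 0.04, 0.3))
  # 0.05 and 0.051 and 0.049 all round to 0.05 -> equal; 0.04 not
  expect_equal(out$n_equal, 4L)
  expect_equal(out$pct, 80)
  expect_equal(equality_fraction(c(0.01, 0.02))$pct, 0)
  # unlisted dyads count against the denominator
  expect_equal(equality_fraction(c(0.5, 0.6), denominator = 4)$pct, 50)
  expect_error(equality_fraction(0.5, denominator = 0), "positive")
  expect_error(equality_fraction(c(0.5, 0.6), denominator = 1), "smaller")
})

test_that("maape is finite at zero references, unlike mape", {
  expect_equal(maape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(maape(c(1, 2), c(2, 2)), pi / 8)
  with_zero <- maape(c(0, 1), c(0.5, 1))
  expect_equal(with_zero, pi / 4)  # (pi/2 + 0) / 2
  expect_false(is.finite(mape(c(0, 1), c(0.5, 1))))
  # exact zero-residual at a zero reference contributes nothing
  expect_equal(maape(c(0, 2), c(0, 2)), 0)
  expect_true(maape(runif(10), runif(10)) <= pi / 2)
})

test_that("profile correlations delegate to the rank machinery", {
  tbl <- tibble::tibble(id = letters[1:5],
                        a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  expect_equal(profile_correlation(tbl, "a", "b")$r_s, 1)
  expect_error(profile_correlation(tbl, "a", "zz"), "no column")
})

test_that("published per-person medians recover the reported state-pair
           correlations", {
  # peers, sparse-protocol study: stress and anxiety medians correlate 0.95
  prof_b <- readr::read_csv(peerma_example("study_b_profiles.csv"),
                            show_col_types = FALSE)
  peers_b <- prof_b |>
    dplyr::filter(role == "peer") |>
    tidyr::pivot_wider(id_cols = person_id, names_from = state,
                       values_from = median)
  rb <- profile_correlation(peers_b, "stress", "anxiety")
  expect_equal(round(rb$r_s, 2), 0.95)

  # participants, dense-protocol study: recomputing from two-decimal
  # medians lands within rounding distance of the reported 0.73
  prof_a <- readr::read_csv(peerma_example("study_a_profiles.csv"),
                            show_col_types = FALSE)
  part_a <- prof_a |>
    dplyr::filter(role == "participant") |>
    tidyr::pivot_wider(id_cols = person_id, names_from = state,
                       values_from = median)
  ra <- profile_correlation(part_a, "stress", "anxiety")
  expect_lt(abs(ra$r_s - 0.73), 0.05)
})

test_that("printed p-value strings parse including censored entries", {
  expect_equal(parse_printed_p(c(".05", ".003", "<.001")),
               c(0.05, 0.003, 0.0005))
})
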