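# build one assessment record row; ts like "2024-03-04T10:30"
rec <- function(person, role, state, value, ts,
                dyad = "d1", study = "s1", conf = NA_real_,
                trigger = "signal") {
  tibble::tibble(
    study_id = study, dyad_id = dyad, person_id = person, role = role,
    state = state, value = value, confidence = conf,
    timestamp = as.POSIXct(ts, format = "%Y-%m-%dT%H:%M", tz = "UTC"),
    trigger = trigger
  )
}

# paired records for one dyad from per-day participant/peer values (0-1),
# NA meaning no assessment that day; one record per day per role
dyad_records <- function(p_vals, r_vals, state = "stress",
                         start = as.Date("2024-03-04")) {
  rows <- list()
  for (d in seq_along(p_vals)) {
    ts_p <- format(start + d - 1, "%Y-%m-%dT10:00")
    ts_r <- format(start + d - 1, "%Y-%m-%dT11:00")
    if (!is.na(p_vals[d])) {
      rows[[length(rows) + 1]] <- rec("p1", "participant", state,
                                      p_vals[d], ts_p)
    }
    if (!is.na(r_vals[d])) {
      rows[[length(rows) + 1]] <- rec("r1", "peer", state, r_vals[d], ts_r,
                                      conf = 8)
    }
  }
  dplyr::bind_rows(rows)
}

# exhaustive 2^n sign-flip oracle for the two-sided signed-rank p-value
signed_rank_oracle <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exhaustive permutation oracle for the two-sided Spearman p-value,
# with rho computed by the textbook rank formula (tie-free inputs only)
spearman_oracle <- function(x, y) {
  n <- length(x)
  rho <- function(a, b) {
    d <- rank(a) - rank(b)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  }
  r_obs <- rho(x, y)
  perms <- peerma_permutations(n)
  r_all <- apply(perms, 1, function(idx) rho(x, y[idx]))
  list(r = r_obs, p = mean(abs(r_all) >= abs(r_obs) - 1e-12))
}

# small independent permutation generator (recursive, for oracle use)
peerma_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- peerma_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}
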