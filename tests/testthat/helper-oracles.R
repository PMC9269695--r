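# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately recompute everything with naive per-element loops so
# they share no code path with the package implementation.

# Naive Cole-Kripke: recompute each epoch's weighted window sum independently,
# walking the 7 window positions one by one.
naive_cole_kripke <- function(counts, params = cole_kripke_params()) {
  a <- pmin(counts / params$scale, params$cap)
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in -4:2) {
      j <- i + k
      aj <- if (j >= 1 && j <= n) a[j] else 0
      s <- s + params$weights[k + 5] * aj
    }
    d[i] <- params$multiplier * s
  }
  list(score = d,
       state = ifelse(d < params$threshold, "Sleep", "Wake"))
}

# Brute-force onset scan: try every start position in turn.
naive_onset <- function(states, k) {
  n <- length(states)
  if (k > n) return(NA_integer_)
  for (i in seq_len(n - k + 1)) {
    if (all(states[i:(i + k - 1)] == "Sleep")) return(i)
  }
  NA_integer_
}

# Random binary minute sequence with a given sleep probability.
random_states <- function(n, p_sleep = 0.7) {
  sample(c("Sleep", "Wake"), n, replace = TRUE, prob = c(p_sleep, 1 - p_sleep))
}

# Minute-grid timestamps starting at a fixed origin.
minute_grid <- function(n, t0 = as.POSIXct("2024-03-01 23:00:00", tz = "UTC")) {
  t0 + 60 * (seq_len(n) - 1L)
}

# Build an aligned night directly from state vectors (all minutes scorable
# unless a scorable mask is given); lights-out at the first minute.
make_night <- function(psg, ag = psg, scorable = rep(TRUE, length(psg)),
                       id = "p01") {
  ts <- minute_grid(length(psg))
  align_night(
    tibble::tibble(minute_start = ts, state = psg, scorable = scorable),
    tibble::tibble(minute_start = ts, state = ag),
    lights_out = ts[1],
    participant_id = id
  )
}

# 60 s count series from a plain counts vector.
make_counts <- function(counts, id = "p01", len_s = 60) {
  t0 <- as.POSIXct("2024-03-01 23:00:00", tz = "UTC")
  new_count_epochs(id, t0 + len_s * (seq_along(counts) - 1L), counts)
}

# Long metrics table with a known device offset and optional device-by-rule
# interaction, for mixed-model recovery tests.
make_bias_table <- function(n, dev_off = 26, rule10_off = 0, seed = 1,
                            part_sd = 30, res_sd = 5, metric = "tst_min") {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  b <- rnorm(n, 400, part_sd)
  g <- expand.grid(participant_id = ids, device = c("PSG", "AG"),
                   rule = c(1L, 5L, 10L), stringsAsFactors = FALSE)
  g$metric <- metric
  g$value <- b[match(g$participant_id, ids)] +
    ifelse(g$device == "AG", dev_off, 0) +
    ifelse(g$device == "AG" & g$rule == 10L, rule10_off, 0) +
    rnorm(nrow(g), 0, res_sd)
  tibble::as_tibble(g)
}
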