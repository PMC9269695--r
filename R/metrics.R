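#' Detect sleep onset under a k-consecutive-minute rule
#'
#' Sleep onset is the first minute beginning a run of at least `k` consecutive
#' `Sleep` minutes with no intervening `Wake`. The commonly applied rules use
#' k = 1, 5 and 10 minutes; any k >= 1 is accepted.
#'
#' @param states Character vector of `Sleep`/`Wake` minute states (the
#'   included minutes within Time-in-Bed, in temporal order).
#' @param k Positive integer: required run length in minutes.
#' @return 1-based index of the onset minute, or `NA_integer_` if no run of
#'   length `k` exists.
#' @export
detect_sleep_onset <- function(states, k = 1L) {
  stopifnot(length(states) >= 1, k >= 1)
  assert_states(states)
  r <- rle(states == "Sleep")
  run_starts <- cumsum(c(1L, head(r$lengths, -1L)))
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(run_starts[hit[1]])
}

#' Night-level sleep measures for one device under one onset rule
#'
#' Computes the five sleep measures over the included minutes within
#' Time-in-Bed (TIB) of an aligned night, for either the PSG or the AG state
#' stream:
#'
#' * `tib_min` — number of included minutes in TIB;
#' * `sol_min` — Sleep Onset Latency: `Wake` minutes between lights-out and
#'   sleep onset;
#' * `tst_min` — Total Sleep Time: `Sleep` minutes from onset through the end
#'   of TIB;
#' * `waso_min` — Wake After Sleep Onset: `Wake` minutes from onset through
#'   the end of TIB;
#' * `se_pct` — Sleep Efficiency, `100 * TST / TIB`;
#' * `se_asleep_pct` — Efficiency Once Asleep, `100 * TST / (TIB - SOL)`.
#'
#' Under a multi-minute onset rule, isolated `Sleep` minutes *before* onset
#' belong to no measure; they are reported as `pre_onset_sleep_min` so that
#' the accounting identity `SOL + TST + WASO + pre_onset_sleep = TIB` holds
#' whenever onset exists. A night with no onset gets `sol_min` equal to all
#' Wake minutes in TIB, zero TST and WASO, `se_pct = 0`, and an undefined
#' (`NA`) `se_asleep_pct`.
#'
#' Runs are evaluated over included minutes only, so an unscorable gap breaks
#' a run (the conservative reading).
#'
#' @param night An [align_night()] object.
#' @param device `"PSG"` or `"AG"`.
#' @param rule Onset rule k in minutes (see [detect_sleep_onset()]).
#' @return A one-row tibble with `participant_id`, `device`, `rule`,
#'   `tib_min`, `onset_idx`, `sol_min`, `tst_min`, `waso_min`,
#'   `pre_onset_sleep_min`, `se_pct`, `se_asleep_pct`.
#' @export
compute_metrics <- function(night, device = c("PSG", "AG"), rule = 1L) {
  device <- match.arg(device)
  states <- tib_states(night, device)
  if (length(states) == 0) {
    stop("night has zero included minutes within TIB", call. = FALSE)
  }
  m <- sleep_measures(states, rule)
  tibble(
    participant_id = night$participant_id,
    device = device,
    rule = as.integer(rule),
    !!!m
  )
}

#' Sleep measures from a raw minute state sequence
#'
#' Workhorse behind [compute_metrics()]: derives the five sleep measures from
#' any minute-level binary state sequence taken as the included minutes within
#' Time-in-Bed. See [compute_metrics()] for the definitions.
#'
#' @inheritParams detect_sleep_onset
#' @param rule Onset rule k in minutes.
#' @return A named list: `tib_min`, `onset_idx`, `sol_min`, `tst_min`,
#'   `waso_min`, `pre_onset_sleep_min`, `se_pct`, `se_asleep_pct`.
#' @export
sleep_measures <- function(states, rule = 1L) {
  tib <- length(states)
  onset <- detect_sleep_onset(states, rule)
  if (is.na(onset)) {
    sol <- sum(states == "Wake")
    tst <- 0L
    waso <- 0L
    pre <- sum(states == "Sleep")
    se <- 0
    se_asleep <- NA_real_
  } else {
    before <- states[seq_len(onset - 1L)]
    after <- states[onset:tib]
    sol <- sum(before == "Wake")
    pre <- sum(before == "Sleep")
    tst <- sum(after == "Sleep")
    waso <- sum(after == "Wake")
    se <- 100 * tst / tib
    se_asleep <- 100 * tst / (tib - sol)
  }
  list(
    tib_min = as.integer(tib),
    onset_idx = onset,
    sol_min = as.integer(sol),
    tst_min = as.integer(tst),
    waso_min = as.integer(waso),
    pre_onset_sleep_min = as.integer(pre),
    se_pct = se,
    se_asleep_pct = se_asleep
  )
}

#' Long-format sleep-measure table for a set of nights
#'
#' Evaluates [compute_metrics()] for every night, both devices and every
#' onset rule, and pivots to the long shape used by the agreement and
#' mixed-model analyses: one row per
#' (participant, device, rule, metric).
#'
#' @param nights A list of [align_night()] objects (one per participant).
#' @param rules Integer vector of onset rules in minutes.
#' @return A tibble with columns `participant_id`, `device`, `rule`,
#'   `metric` (one of `tst_min`, `sol_min`, `waso_min`, `se_pct`,
#'   `se_asleep_pct`) and `value`.
#' @export
metrics_table <- function(nights, rules = c(1L, 5L, 10L)) {
  if (length(nights) == 0) stop("no nights supplied", call. = FALSE)
  rows <- list()
  for (night in nights) {
    for (device in c("PSG", "AG")) {
      for (k in rules) {
        row <- tryCatch(
          compute_metrics(night, device, k),
          error = function(e) {
            stop("participant ", night$participant_id, ": ",
                 conditionMessage(e), call. = FALSE)
          })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  wide <- dplyr::bind_rows(rows)
  tidyr::pivot_longer(
    wide,
    cols = c("tst_min", "sol_min", "waso_min", "se_pct", "se_asleep_pct"),
    names_to = "metric", values_to = "value"
  )[, c("participant_id", "device", "rule", "metric", "value")]
}

#' Median / IQR summary of a metrics table
#'
#' Cohort descriptive statistics in the shape of a device-by-rule summary
#' table: the median and interquartile range of each sleep measure, once
#' marginally by device and once marginally by onset rule.
#'
#' @param metrics A long table from [metrics_table()].
#' @return A tibble with columns `group` (`device` or `rule`), `level`,
#'   `metric`, `median`, `q25`, `q75`.
#' @export
summarize_metrics <- function(metrics) {
  summ <- function(tbl, group, level) {
    dplyr::summarise(
      dplyr::group_by(tbl, .data$metric),
      median = median(.data$value, na.rm = TRUE),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    ) |>
      dplyr::mutate(group = group, level = level, .before = 1)
  }
  by_device <- dplyr::bind_rows(lapply(
    unique(metrics$device),
    function(d) summ(metrics[metrics$device == d, ], "device", d)))
  by_rule <- dplyr::bind_rows(lapply(
    unique(metrics$rule),
    function(k) summ(metrics[metrics$rule == k, ], "rule", as.character(k))))
  dplyr::bind_rows(by_device, by_rule)
}
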