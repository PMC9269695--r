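#' Configuration for one synthetic paired night
#'
#' Describes the latent minute-level sleep architecture and the count-emission
#' process for a simulated participant night. The generator emulates the
#' structure a wrist-device validation night assumes: a lights-out period that
#' begins with a waking run (the true sleep onset latency), a consolidated
#' sleep period interrupted by a few brief awakenings (the true WASO), high
#' sleep efficiency as seen in healthy young adults, wake minutes that are
#' frequently motionless ("quiet wake", the driver of poor wake detection by
#' accelerometers), sleep minutes with occasional movement bursts, and
#' occasional unscorable PSG blocks.
#'
#' Integer quantities are described by distribution specs: a single number is
#' a point mass; `list(mean = m)` is Poisson; `list(mean = m, size = s)` is
#' negative binomial with dispersion `size`. Durations (awakening and
#' unscorable-block lengths, in minutes) are shifted-geometric with the given
#' mean, reflecting the short, memoryless bouts seen in hypnograms.
#'
#' @param tib_target_min Length of the latent lights-out-to-awake
#'   architecture, minutes.
#' @param sol_true_min True sleep onset latency spec (minutes of wake before
#'   the first sleep minute).
#' @param n_awakenings Spec for the number of wake bouts after onset.
#' @param awakening_len_min Awakening bout length spec, minutes: a scalar is
#'   a fixed length, `list(mean = L)` a shifted-geometric mean.
#' @param quiet_wake_prob Probability that a wake minute is motionless
#'   (near-zero counts); the main control on specificity.
#' @param sleep_move_prob Probability of a movement burst during a sleep
#'   minute.
#' @param active_count_level Mean x-axis counts in a restless wake minute.
#' @param burst_count_level Mean counts of a sleep movement burst.
#' @param quiet_count_level Mean counts of a motionless minute (small).
#' @param unscorable_block_prob Probability the night contains one unscorable
#'   PSG block.
#' @param unscorable_block_len Unscorable block length spec, minutes (same
#'   forms as `awakening_len_min`).
#' @param pre_lights_min Waking minutes recorded before lights-out.
#' @param post_wake_min Waking minutes recorded after the final sleep minute.
#' @param stage_probs Named numeric proportions used to relabel latent sleep
#'   minutes with AASM stages (set `NULL` to emit binary stages).
#' @param count_epoch_len_s Count epoch length emitted by the device model:
#'   60 (default) or 1 (each minute's counts split over 60 one-second epochs
#'   with multinomial noise, to exercise [collapse_epochs()]).
#' @param seed Integer seed; all of the night's randomness derives from it.
#' @return A `night_config` list.
#' @export
night_config <- function(tib_target_min = 480,
                         sol_true_min = list(mean = 19, size = 4),
                         n_awakenings = list(mean = 3),
                         awakening_len_min = list(mean = 2),
                         quiet_wake_prob = 0.8,
                         sleep_move_prob = 0.05,
                         active_count_level = 1200,
                         burst_count_level = 150,
                         quiet_count_level = 3,
                         unscorable_block_prob = 0,
                         unscorable_block_len = list(mean = 20),
                         pre_lights_min = 10,
                         post_wake_min = 10,
                         stage_probs = c(N1 = 0.05, N2 = 0.5, N3 = 0.25, REM = 0.2),
                         count_epoch_len_s = 60,
                         seed = 1L) {
  cfg <- list(
    tib_target_min = as.integer(tib_target_min),
    sol_true_min = sol_true_min,
    n_awakenings = n_awakenings,
    awakening_len_min = awakening_len_min,
    quiet_wake_prob = quiet_wake_prob,
    sleep_move_prob = sleep_move_prob,
    active_count_level = active_count_level,
    burst_count_level = burst_count_level,
    quiet_count_level = quiet_count_level,
    unscorable_block_prob = unscorable_block_prob,
    unscorable_block_len = unscorable_block_len,
    pre_lights_min = as.integer(pre_lights_min),
    post_wake_min = as.integer(post_wake_min),
    stage_probs = stage_probs,
    count_epoch_len_s = as.integer(count_epoch_len_s),
    seed = as.integer(seed)
  )
  probs <- c(cfg$quiet_wake_prob, cfg$sleep_move_prob, cfg$unscorable_block_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$tib_target_min >= spec_mean(cfg$sol_true_min) + 1,
            spec_mean(cfg$awakening_len_min) > 0,
            cfg$count_epoch_len_s %in% c(1L, 60L))
  structure(cfg, class = "night_config")
}

# Internal: mean of a distribution spec.
spec_mean <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) return(spec)
  spec$mean
}

# Internal: draw one non-negative integer from a distribution spec.
draw_spec <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) return(as.integer(spec))
  if (!is.null(spec$size)) return(rnbinom(1, mu = spec$mean, size = spec$size))
  rpois(1, spec$mean)
}

# Internal: bout duration in minutes. A numeric scalar is a fixed length; a
# list(mean = L) is shifted-geometric (minimum 1 minute) with mean L.
draw_duration <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) return(as.integer(spec))
  1L + rgeom(1, prob = 1 / max(spec$mean, 1))
}

#' Generate one synthetic paired night
#'
#' Builds the latent minute architecture (wake run of the true SOL, then a
#' sleep span with awakening bouts placed uniformly, non-adjacent, strictly
#' inside the span, ending on a sleep minute), duplicates each minute into two
#' 30 s PSG epochs (optionally relabelled with AASM stages), and emits
#' activity counts per minute: restless wake minutes draw high gamma counts,
#' quiet wake minutes draw near-zero counts, sleep minutes are zero except for
#' occasional gamma movement bursts. At most one unscorable PSG block is
#' injected. All randomness derives from `config$seed`, so a fixed
#' configuration reproduces the night exactly.
#'
#' @param config A [night_config()].
#' @param participant_id Identifier for the generated participant.
#' @return A `synthetic_night` list: `hypnogram` (a [new_hypnogram()] object),
#'   `counts` (a [new_count_epochs()] object), `lights_out`,
#'   `truth` (one-row tibble of the noiseless architecture's sleep measures
#'   under the 1-minute onset rule, from independent bookkeeping),
#'   `truth_states` (the latent minute state vector within TIB) and `config`.
#' @export
generate_night <- function(config, participant_id = "p01") {
  stopifnot(inherits(config, "night_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  tib <- config$tib_target_min
  sol <- draw_spec(config$sol_true_min)
  if (sol > tib - 1) {
    stop("infeasible config: drawn SOL (", sol, ") leaves no sleep span in TIB",
         call. = FALSE)
  }
  n_awk <- draw_spec(config$n_awakenings)
  awk_lens <- if (n_awk > 0) {
    vapply(seq_len(n_awk), function(i) draw_duration(config$awakening_len_min),
           integer(1))
  } else integer(0)
  sleep_span <- tib - sol
  waso <- sum(awk_lens)
  n_sleep <- sleep_span - waso
  if (n_sleep < n_awk + 1) {
    stop("infeasible config: awakenings (", waso,
         " min) exceed the sleep span (", sleep_span, " min)", call. = FALSE)
  }

  # Compose the sleep span: n_awk wake bouts separated by >= 1 sleep minute,
  # with sleep at both ends (stars-and-bars over the sleep minutes).
  span_states <- rep("Sleep", sleep_span)
  if (n_awk > 0) {
    cuts <- sort(sample.int(n_sleep - 1L, n_awk))
    gaps <- diff(c(0L, cuts, n_sleep))  # n_awk + 1 sleep gaps, each >= 1
    span_states <- character(0)
    for (i in seq_len(n_awk)) {
      span_states <- c(span_states, rep("Sleep", gaps[i]), rep("Wake", awk_lens[i]))
    }
    span_states <- c(span_states, rep("Sleep", gaps[n_awk + 1L]))
  }
  arch <- c(rep("Wake", sol), span_states)
  stopifnot(length(arch) == tib, arch[tib] == "Sleep")

  truth <- tibble(
    participant_id = participant_id, device = "PSG", rule = 1L,
    tib_min = tib,
    onset_idx = as.integer(sol + 1L),
    sol_min = as.integer(sol),
    tst_min = as.integer(n_sleep),
    waso_min = as.integer(waso),
    pre_onset_sleep_min = 0L,
    se_pct = 100 * n_sleep / tib,
    se_asleep_pct = 100 * n_sleep / (tib - sol)
  )

  # Full recorded night: waking lead-in, architecture, waking tail.
  states <- c(rep("Wake", config$pre_lights_min), arch,
              rep("Wake", config$post_wake_min))
  n_min <- length(states)
  t0 <- as.POSIXct("2024-03-01 22:30:00", tz = "UTC")
  minute_start <- t0 + 60 * (seq_len(n_min) - 1L)
  lights_out <- t0 + 60 * config$pre_lights_min

  # Stage relabelling: each latent sleep minute gets one AASM stage.
  stage_min <- ifelse(states == "Wake", "W", "Sleep")
  if (!is.null(config$stage_probs)) {
    is_sleep <- states == "Sleep"
    stage_min[is_sleep] <- sample(names(config$stage_probs), sum(is_sleep),
                                  replace = TRUE, prob = config$stage_probs)
  }

  # Unscorable PSG block: at most one, placed uniformly inside the
  # architecture but never covering its final (anchor) sleep minute.
  scorable_min <- rep(TRUE, n_min)
  if (config$unscorable_block_prob > 0 &&
      runif(1) < config$unscorable_block_prob) {
    len <- min(draw_duration(config$unscorable_block_len), tib - 1L)
    lo <- config$pre_lights_min + 1L
    hi <- config$pre_lights_min + tib - len  # block ends before the anchor
    start <- if (hi > lo) sample(lo:(hi - 1L), 1) else lo
    scorable_min[start:(start + len - 1L)] <- FALSE
  }

  # Count emission per minute.
  counts_min <- numeric(n_min)
  for (i in seq_len(n_min)) {
    if (states[i] == "Wake") {
      counts_min[i] <- if (runif(1) < config$quiet_wake_prob) {
        rpois(1, config$quiet_count_level)
      } else {
        rgamma(1, shape = 4, scale = config$active_count_level / 4)
      }
    } else {
      counts_min[i] <- if (runif(1) < config$sleep_move_prob) {
        rgamma(1, shape = 2, scale = config$burst_count_level / 2)
      } else 0
    }
  }
  counts_min <- as.integer(round(counts_min))

  if (config$count_epoch_len_s == 60L) {
    counts <- new_count_epochs(participant_id, minute_start, counts_min)
  } else {
    # 1 s mode: spread each minute's counts over its 60 seconds.
    per_sec <- unlist(lapply(counts_min, function(cm) {
      if (cm == 0) rep(0L, 60) else as.integer(rmultinom(1, cm, rep(1, 60)))
    }))
    sec_start <- t0 + (seq_len(60L * n_min) - 1L)
    counts <- new_count_epochs(participant_id, sec_start, per_sec)
  }

  hyp <- new_hypnogram(
    participant_id = participant_id,
    epoch_start = t0 + 30 * (seq_len(2L * n_min) - 1L),
    stage = rep(stage_min, each = 2L),
    scorable = rep(scorable_min, each = 2L),
    lights_out = lights_out
  )

  structure(
    list(hypnogram = hyp, counts = counts, lights_out = lights_out,
         truth = truth, truth_states = arch, config = config,
         participant_id = participant_id),
    class = "synthetic_night"
  )
}

#' Generate a synthetic cohort of paired nights
#'
#' Draws one night per participant from jittered copies of a template
#' configuration. Child seeds derive deterministically from the master seed as
#' `(seed + 104729 * ordinal) mod 2147483647`, so any run with the same master
#' seed reproduces the whole cohort. Per-participant random effects are
#' introduced by jittering the template: TIB gets a normal offset, and the SOL
#' mean and awakening-count mean get log-normal multipliers (the cohort-level
#' analogue of short vs. long sleepers and fragmented vs. consolidated
#' nights).
#'
#' @param n_participants Number of participants (>= 1).
#' @param template A [night_config()] used as the cohort template.
#' @param seed Master integer seed.
#' @param jitter Named list of jitter scales: `tib_sd` (minutes, normal),
#'   `sol_sdlog` and `awk_sdlog` (log-normal sdlog). Set all to 0 for an
#'   exactly homogeneous cohort.
#' @return A list of [generate_night()] objects with participant ids
#'   `p01, p02, ...`.
#' @export
generate_cohort <- function(n_participants, template = night_config(),
                            seed = 1L,
                            jitter = list(tib_sd = 25, sol_sdlog = 0.45,
                                          awk_sdlog = 0.3)) {
  stopifnot(n_participants >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  tib_off <- round(rnorm(n_participants, 0, jitter$tib_sd))
  sol_mult <- exp(rnorm(n_participants, 0, jitter$sol_sdlog))
  awk_mult <- exp(rnorm(n_participants, 0, jitter$awk_sdlog))
  lapply(seq_len(n_participants), function(i) {
    cfg <- template
    cfg$tib_target_min <- max(60L, template$tib_target_min + as.integer(tib_off[i]))
    cfg$sol_true_min <- scale_spec(template$sol_true_min, sol_mult[i])
    cfg$n_awakenings <- scale_spec(template$n_awakenings, awk_mult[i])
    cfg$seed <- as.integer((seed + 104729 * i) %% 2147483647)
    generate_night(cfg, sprintf("p%02d", i))
  })
}

# Internal: scale the mean of a distribution spec by a positive factor.
scale_spec <- function(spec, factor) {
  if (is.numeric(spec) && length(spec) == 1) return(spec * factor)
  spec$mean <- spec$mean * factor
  spec
}

#' Calibrated night configuration profiles
#'
#' Named, documented default configurations. `healthy_young_adult` emulates
#' the regime typical of wrist-device validation in healthy young adults:
#' roughly 8 h in bed, ~19 min true sleep onset latency, a handful of brief
#' awakenings (sleep efficiency well above 80%), and mostly motionless wake
#' (`quiet_wake_prob = 0.8`), under which the full pipeline yields high
#' sensitivity, low specificity, and an actigraph that overestimates TST and
#' SE while underestimating SOL and WASO.
#'
#' @param name Profile name; currently `"healthy_young_adult"`.
#' @param ... Overrides passed on to [night_config()].
#' @return A [night_config()].
#' @export
calibration_profile <- function(name = "healthy_young_adult", ...) {
  if (!identical(name, "healthy_young_adult")) {
    stop("unknown calibration profile: ", name, call. = FALSE)
  }
  base <- list(
    tib_target_min = 480,
    sol_true_min = list(mean = 19, size = 4),
    n_awakenings = list(mean = 3),
    awakening_len_min = list(mean = 2),
    quiet_wake_prob = 0.85,
    sleep_move_prob = 0.05,
    active_count_level = 600,
    burst_count_level = 150,
    unscorable_block_prob = 0.15,
    unscorable_block_len = list(mean = 20)
  )
  do.call(night_config, utils::modifyList(base, list(...)))
}

#' Write a synthetic night to the pipeline's CSV interchange formats
#'
#' Emits the counts, hypnogram and events CSVs that [read_count_epochs()] and
#' [read_hypnogram()] consume, so a simulated cohort can stand in for a real
#' device export end to end.
#'
#' @param night A [generate_night()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_night <- function(night, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- night$participant_id
  paths <- c(
    counts = file.path(dir, paste0(id, "_counts.csv")),
    hypnogram = file.path(dir, paste0(id, "_hypnogram.csv")),
    events = file.path(dir, paste0(id, "_events.csv"))
  )
  write_count_epochs(night$counts, paths[["counts"]])
  write_hypnogram(night$hypnogram, paths[["hypnogram"]],
                  events_path = paths[["events"]])
  invisible(paths)
}
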