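test_that("count CSVs parse, infer epoch length, and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,epoch_start,axis_x",
    "p01,2024-03-01T23:00:00,0",
    "p01,2024-03-01T23:01:00,5",
    "p01,2024-03-01T23:02:00,10"
  ), path)
  s <- read_count_epochs(path)
  expect_s3_class(s, "count_epochs")
  expect_equal(nrow(s), 3L)
  expect_equal(epoch_len_s(s), 60L)
  expect_equal(s$counts, c(0L, 5L, 10L))

  # 1 s epochs are inferred the same way
  s1 <- make_counts(rep(1L, 120), len_s = 1)
  expect_equal(epoch_len_s(s1), 1L)
  expect_equal(nrow(s1), 120L)

  # write/read round-trip reproduces counts and timestamps exactly
  set.seed(11)
  orig <- make_counts(rpois(50, 40))
  out <- withr::local_tempfile(fileext = ".csv")
  write_count_epochs(orig, out)
  back <- read_count_epochs(out)
  expect_equal(back$counts, orig$counts)
  expect_equal(back$epoch_start, orig$epoch_start)
  expect_equal(epoch_len_s(back), epoch_len_s(orig))
})

test_that("gaps and negative counts are rejected at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,epoch_start,axis_x",
    "p01,2024-03-01T23:00:00,0",
    "p01,2024-03-01T23:01:00,5",
    "p01,2024-03-01T23:03:00,10"  # minute 23:02 missing
  ), path)
  expect_error(read_count_epochs(path), "non-uniform epoch spacing.*after epoch 2")
  expect_error(new_count_epochs("p01", minute_grid(3), c(1, -2, 3)),
               "non-negative")
})

test_that("collapse_epochs sums windows, drops partial tails, conserves counts", {
  s <- make_counts(rep(1L, 120), len_s = 1)
  out <- collapse_epochs(s, 60)
  expect_equal(out$counts, c(60L, 60L))
  expect_equal(epoch_len_s(out), 60L)

  z <- collapse_epochs(make_counts(rep(0L, 120), len_s = 1), 60)
  expect_equal(z$counts, c(0L, 0L))

  # hand-summed: [0 x 59, 300] then [10 x 60] -> [300, 600]
  h <- collapse_epochs(make_counts(c(rep(0L, 59), 300L, rep(10L, 60)), len_s = 1), 60)
  expect_equal(h$counts, c(300L, 600L))

  expect_warning(part <- collapse_epochs(make_counts(rep(2L, 130), len_s = 1), 60),
                 "partial window")
  expect_equal(nrow(part), 2L)

  expect_error(collapse_epochs(make_counts(1:5, len_s = 60), 30), "smaller")

  # conservation over retained windows, random series
  set.seed(21)
  for (rep_i in 1:20) {
    n <- sample(60:600, 1)
    s <- make_counts(rpois(n, 20), len_s = 1)
    suppressWarnings(out <- collapse_epochs(s, 60))
    kept <- (n %/% 60) * 60
    expect_equal(sum(out$counts), sum(s$counts[seq_len(kept)]))
  }
})

test_that("stage binarization maps AASM labels and rejects unknown ones", {
  hyp <- new_hypnogram("p01", minute_grid(1) + 30 * 0:3,
                       c("W", "N1", "N2", "REM"), rep(TRUE, 4),
                       lights_out = minute_grid(1))
  expect_equal(binarize_stages(hyp)$stage, c("Wake", "Sleep", "Sleep", "Sleep"))

  allw <- new_hypnogram("p01", minute_grid(1) + 30 * 0:3, rep("W", 4),
                        rep(TRUE, 4), lights_out = minute_grid(1))
  expect_true(all(binarize_stages(allw)$stage == "Wake"))

  bin <- new_hypnogram("p01", minute_grid(1) + 30 * 0:3,
                       c("Sleep", "Wake", "Sleep", "Sleep"), rep(TRUE, 4),
                       lights_out = minute_grid(1))
  expect_identical(binarize_stages(bin)$stage, bin$stage)

  bad <- new_hypnogram("p01", minute_grid(1) + 30 * 0:3,
                       c("W", "N1", "R", "N2"), rep(TRUE, 4),
                       lights_out = minute_grid(1))
  expect_error(binarize_stages(bad), "'R' at epoch 3")
})

test_that("minute downsampling takes the first 30 s epoch of each pair", {
  mk <- function(stages, scorable = rep(TRUE, length(stages))) {
    new_hypnogram("p01", minute_grid(1) + 30 * (seq_along(stages) - 1),
                  stages, scorable, lights_out = minute_grid(1))
  }
  m <- downsample_hypnogram_to_minutes(mk(c("Wake", "Sleep", "Sleep", "Sleep",
                                            "Sleep", "Wake")))
  expect_equal(m$state, c("Wake", "Sleep", "Sleep"))
  expect_equal(as.numeric(diff(m$minute_start), units = "secs"), c(60, 60))

  expect_equal(downsample_hypnogram_to_minutes(mk(c("Sleep", "Wake")))$state,
               "Sleep")

  expect_warning(
    m5 <- downsample_hypnogram_to_minutes(
      mk(c("Wake", "Wake", "Sleep", "Sleep", "Wake"))),
    "unpaired")
  expect_equal(m5$state, c("Wake", "Sleep"))

  # a minute whose first epoch is unscorable is unscorable
  mu <- downsample_hypnogram_to_minutes(
    mk(c("Wake", "Sleep", "Sleep", "Sleep"), scorable = c(FALSE, TRUE, TRUE, TRUE)))
  expect_equal(mu$scorable, c(FALSE, TRUE))

  # duplicate-then-downsample is idempotent on the minute states
  set.seed(31)
  states <- random_states(40)
  dup <- mk(rep(states, each = 2))
  expect_equal(downsample_hypnogram_to_minutes(dup)$state, states)
})

test_that("alignment locates TIB, excludes unscorable minutes in both streams", {
  # all scorable, identical coverage
  psg <- c("Wake", "Wake", rep("Sleep", 96), "Wake", "Sleep")
  night <- make_night(psg)
  expect_equal(nrow(night$data), 100L)
  expect_true(all(night$data$included))
  expect_equal(night$tib_start_idx, 1L)
  expect_equal(night$tib_end_idx, 100L)  # ends on the last Sleep minute

  # terminal wake minutes fall outside TIB (Awake anchor)
  n2 <- make_night(c("Wake", rep("Sleep", 10), "Wake", "Wake"))
  expect_equal(n2$tib_end_idx, 11L)
  expect_equal(n2$data$psg_state[n2$tib_end_idx], "Sleep")

  # an unscorable mid-night block shrinks the comparison denominators
  scor <- rep(TRUE, 20); scor[8:10] <- FALSE
  n3 <- make_night(c("Wake", rep("Sleep", 19)), scorable = scor)
  expect_equal(sum(!n3$data$included), 3L)
  cm <- confusion(list(n3))$pooled
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 17L)

  # error cases
  expect_error(make_night(rep("Wake", 30)), "no sleep night")
  ts <- minute_grid(10)
  expect_error(align_night(
    tibble::tibble(minute_start = ts, state = rep("Sleep", 10),
                   scorable = TRUE),
    tibble::tibble(minute_start = ts + 86400, state = rep("Sleep", 10)),
    lights_out = ts[1]), "no overlapping")
})

test_that("included TIB minutes obey the metric accounting identity per rule", {
  set.seed(41)
  for (i in 1:25) {
    psg <- c(random_states(60, 0.6), "Sleep")
    scor <- runif(61) > 0.1
    night <- tryCatch(make_night(psg, scorable = scor), error = function(e) NULL)
    if (is.null(night)) next
    n_inc <- sum(night$data$included[night$tib_start_idx:night$tib_end_idx])
    for (k in c(1L, 5L, 10L)) {
      m <- compute_metrics(night, "PSG", k)
      expect_equal(m$sol_min + m$tst_min + m$waso_min + m$pre_onset_sleep_min,
                   n_inc)
      expect_equal(m$tib_min, n_inc)
    }
  }
})
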