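#' Read an activity-count epoch series
#'
#' Reads a CSV of timestamped wrist-accelerometer activity counts (one row per
#' epoch) and returns a validated `count_epochs` tibble. The epoch length is
#' inferred from the timestamp spacing, which must be perfectly uniform: a
#' wrist device records continuously, so a missing epoch indicates a corrupted
#' export and is an error, not a gap to be bridged.
#'
#' Epoch timestamps label the epoch *start*; an epoch covers the half-open
#' interval `[t, t + epoch_len_s)`. Only the x-axis (anteroposterior, parallel
#' to the forearm) count column is used; y/z columns, if present, are ignored.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the roles `participant_id`,
#'   `epoch_start` and `counts` to column names in the file. Defaults to the
#'   package's native column names (`participant_id`, `epoch_start`, `axis_x`).
#' @param tz Time zone used to parse timestamps (default `"UTC"`).
#'
#' @return A `count_epochs` tibble with columns `participant_id`,
#'   `epoch_start` (POSIXct) and `counts` (integer), and an `epoch_len_s`
#'   attribute (seconds between consecutive epochs).
#' @seealso [collapse_epochs()], [write_count_epochs()]
#' @export
read_count_epochs <- function(path,
                              schema = c(participant_id = "participant_id",
                                         epoch_start = "epoch_start",
                                         counts = "axis_x"),
                              tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- unname(schema[c("participant_id", "epoch_start", "counts")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("count CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(raw[[schema[["epoch_start"]]]], tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("unparseable epoch_start timestamp in ", path, call. = FALSE)
  counts <- raw[[schema[["counts"]]]]
  new_count_epochs(
    participant_id = as.character(raw[[schema[["participant_id"]]]]),
    epoch_start = ts,
    counts = counts
  )
}

#' Construct a count-epoch series from vectors
#'
#' Low-level constructor behind [read_count_epochs()]; validates the series
#' invariants (uniform strictly increasing timestamps, non-negative integer
#' counts) and infers the epoch length from the spacing.
#'
#' @param participant_id Character scalar or vector (recycled).
#' @param epoch_start POSIXct vector of epoch start times.
#' @param counts Non-negative numeric vector of activity counts.
#' @return A `count_epochs` tibble; see [read_count_epochs()].
#' @export
new_count_epochs <- function(participant_id, epoch_start, counts) {
  n <- length(epoch_start)
  if (n < 1) stop("count series is empty", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("activity counts must be non-negative and non-missing", call. = FALSE)
  }
  len_s <- 0L
  if (n > 1) {
    gaps <- as.numeric(diff(epoch_start), units = "secs")
    len_s <- gaps[1]
    if (len_s <= 0) stop("epoch timestamps must be strictly increasing", call. = FALSE)
    off <- which(abs(gaps - len_s) > 1e-6)
    if (length(off) > 0) {
      stop(sprintf(
        "non-uniform epoch spacing: gap of %ss after epoch %d (%s); expected %ss",
        gaps[off[1]], off[1], format(epoch_start[off[1]], usetz = TRUE), len_s),
        call. = FALSE)
    }
  }
  out <- tibble(
    participant_id = rep_len(as.character(participant_id), n),
    epoch_start = epoch_start,
    counts = as.integer(round(counts))
  )
  structure(out, epoch_len_s = as.integer(len_s),
            class = c("count_epochs", class(out)))
}

#' Epoch length of a count series, in seconds
#'
#' @param x A `count_epochs` object.
#' @return Integer number of seconds per epoch (0 for a length-1 series whose
#'   spacing cannot be inferred).
#' @export
epoch_len_s <- function(x) {
  attr(x, "epoch_len_s") %||% 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse count epochs into longer epochs by summation
#'
#' Aggregates consecutive epochs into non-overlapping windows of
#' `target_len_s` seconds, summing the activity counts within each window.
#' This is how 1 s device exports are brought to the 60 s epochs the
#' Cole-Kripke scorer requires. A trailing window that is only partially
#' covered by the input is dropped with a warning.
#'
#' @param series A `count_epochs` tibble.
#' @param target_len_s Target epoch length in seconds; must be an integer
#'   multiple of the input epoch length.
#' @return A `count_epochs` tibble at the target epoch length whose timestamps
#'   are the window starts. Total counts are conserved over retained windows.
#' @export
collapse_epochs <- function(series, target_len_s) {
  src <- epoch_len_s(series)
  if (src <= 0) stop("source epoch length unknown (series too short)", call. = FALSE)
  if (target_len_s < src) {
    stop("target epoch length (", target_len_s,
         " s) is smaller than the source epoch length (", src, " s)", call. = FALSE)
  }
  ratio <- target_len_s / src
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("target epoch length must be an integer multiple of ", src, " s",
         call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(series)
  n_full <- nrow(series) %/% ratio
  dropped <- nrow(series) - n_full * ratio
  if (n_full == 0) stop("series shorter than one target window", call. = FALSE)
  if (dropped > 0) {
    warning(sprintf("dropping trailing partial window (%d of %d source epochs)",
                    dropped, ratio), call. = FALSE)
  }
  idx <- rep(seq_len(n_full), each = ratio)
  kept <- series[seq_len(n_full * ratio), ]
  sums <- as.integer(rowsum(as.numeric(kept$counts), idx))
  new_count_epochs(
    participant_id = kept$participant_id[1],
    epoch_start = kept$epoch_start[seq(1, by = ratio, length.out = n_full)],
    counts = sums
  )
}

#' Write a count-epoch series to CSV
#'
#' Inverse of [read_count_epochs()]: writes `participant_id`, `epoch_start`
#' (ISO-8601, UTC) and `axis_x` columns so that a read round-trip reproduces
#' counts and timestamps exactly.
#'
#' @param series A `count_epochs` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_epochs <- function(series, path) {
  out <- data.frame(
    participant_id = series$participant_id,
    epoch_start = format(series$epoch_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    axis_x = series$counts
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PSG hypnogram
#'
#' Reads a CSV of 30 s polysomnography epochs (staged by a technician) together
#' with per-epoch scorable flags, and attaches the lights-out event. Stages may
#' be full AASM labels (`W`, `N1`, `N2`, `N3`, `REM`) or already-binary
#' `Wake`/`Sleep`.
#'
#' @param path Path to a hypnogram CSV with columns `participant_id`,
#'   `epoch_start` (ISO-8601), `stage` and `scorable` (0/1).
#' @param lights_out POSIXct lights-out timestamp, or `NULL` to read it from
#'   `events_path`.
#' @param events_path Optional path to an events CSV with columns
#'   `participant_id` and `lights_out`.
#' @param tz Time zone for timestamp parsing.
#' @return A `hypnogram` tibble with columns `participant_id`, `epoch_start`,
#'   `stage`, `scorable`, and a `lights_out` attribute.
#' @export
read_hypnogram <- function(path, lights_out = NULL, events_path = NULL,
                           tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "epoch_start", "stage", "scorable")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("hypnogram CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(raw$epoch_start, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (is.null(lights_out)) {
    if (is.null(events_path)) {
      stop("provide `lights_out` directly or via `events_path`", call. = FALSE)
    }
    ev <- read.csv(events_path, stringsAsFactors = FALSE)
    ev <- ev[ev$participant_id == raw$participant_id[1], , drop = FALSE]
    if (nrow(ev) != 1) {
      stop("events CSV must contain exactly one lights_out row for participant ",
           raw$participant_id[1], call. = FALSE)
    }
    lights_out <- as.POSIXct(ev$lights_out, tz = tz,
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS"))
  }
  new_hypnogram(
    participant_id = as.character(raw$participant_id),
    epoch_start = ts,
    stage = as.character(raw$stage),
    scorable = as.logical(raw$scorable),
    lights_out = lights_out
  )
}

#' Construct a hypnogram from vectors
#'
#' Validates the 30 s uniform spacing invariant and that lights-out does not
#' fall after the last epoch.
#'
#' @inheritParams read_hypnogram
#' @param participant_id,epoch_start,stage,scorable Per-epoch fields.
#' @return A `hypnogram` tibble; see [read_hypnogram()].
#' @export
new_hypnogram <- function(participant_id, epoch_start, stage, scorable,
                          lights_out) {
  n <- length(epoch_start)
  stopifnot(n >= 1, length(stage) == n, length(scorable) == n)
  if (n > 1) {
    gaps <- as.numeric(diff(epoch_start), units = "secs")
    if (any(abs(gaps - 30) > 1e-6)) {
      stop("hypnogram epochs must be uniformly spaced at 30 s", call. = FALSE)
    }
  }
  if (lights_out > epoch_start[n] + 30) {
    stop("lights_out falls after the hypnogram ends", call. = FALSE)
  }
  out <- tibble(
    participant_id = rep_len(as.character(participant_id), n),
    epoch_start = epoch_start,
    stage = stage,
    scorable = scorable
  )
  structure(out, lights_out = lights_out,
            class = c("hypnogram", class(out)))
}

#' Lights-out time of a hypnogram
#' @param x A `hypnogram` object.
#' @return POSIXct lights-out timestamp.
#' @export
lights_out <- function(x) attr(x, "lights_out")

#' Write a hypnogram (and its lights-out event) to CSV
#'
#' @param hyp A `hypnogram` tibble.
#' @param path Output hypnogram CSV path.
#' @param events_path Optional path for a one-row events CSV
#'   (`participant_id, lights_out`).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path, events_path = NULL) {
  out <- data.frame(
    participant_id = hyp$participant_id,
    epoch_start = format(hyp$epoch_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    stage = hyp$stage,
    scorable = as.integer(hyp$scorable)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path)) {
    ev <- data.frame(
      participant_id = hyp$participant_id[1],
      lights_out = format(lights_out(hyp), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    )
    write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
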