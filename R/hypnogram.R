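#' Collapse AASM sleep stages to binary Sleep/Wake
#'
#' Maps the technician-scored stages to the binary labels used for device
#' comparison: `W` becomes `Wake`; `N1`, `N2`, `N3` and `REM` all become
#' `Sleep`. A hypnogram that is already binary passes through unchanged.
#'
#' @param hyp A `hypnogram` tibble (see [read_hypnogram()]).
#' @return The hypnogram with `stage` restricted to `Wake`/`Sleep`.
#' @export
binarize_stages <- function(hyp) {
  map <- c(W = "Wake", N1 = "Sleep", N2 = "Sleep", N3 = "Sleep", REM = "Sleep",
           Wake = "Wake", Sleep = "Sleep")
  bad <- which(!(hyp$stage %in% names(map)))
  if (length(bad) > 0) {
    stop(sprintf("unknown sleep stage label '%s' at epoch %d",
                 hyp$stage[bad[1]], bad[1]), call. = FALSE)
  }
  hyp$stage <- unname(map[hyp$stage])
  hyp
}

#' Downsample a binary hypnogram to minute resolution
#'
#' PSG is staged in 30 s epochs but the scoring algorithm works on 60 s
#' epochs, so each PSG minute must be represented by a single value. The first
#' 30 s epoch of every minute is taken as the representative value for that
#' minute. Minutes are formed by pairing consecutive epochs starting from the
#' first epoch of the recording (no wall-clock snapping); a trailing unpaired
#' epoch is dropped with a warning.
#'
#' A minute counts as scorable only if its representative (first) epoch is
#' scorable: if the representative value is undefined the minute is undefined,
#' regardless of the second epoch.
#'
#' @param hyp A *binary* `hypnogram` (run [binarize_stages()] first).
#' @return A tibble of minute-level states: `minute_start` (POSIXct, 60 s
#'   spacing), `state` (`Sleep`/`Wake`) and `scorable` (logical).
#' @export
downsample_hypnogram_to_minutes <- function(hyp) {
  assert_states(hyp$stage, "stage")
  n <- nrow(hyp)
  n_min <- n %/% 2L
  if (n_min == 0) stop("hypnogram shorter than one minute", call. = FALSE)
  if (n %% 2L == 1L) {
    warning("dropping trailing unpaired 30 s epoch", call. = FALSE)
  }
  first_idx <- seq(1L, by = 2L, length.out = n_min)
  tibble(
    minute_start = hyp$epoch_start[first_idx],
    state = hyp$stage[first_idx],
    scorable = hyp$scorable[first_idx]
  )
}
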