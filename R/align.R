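#' Align PSG and actigraphy minute streams into a paired night
#'
#' Inner-joins the minute-level PSG states and device (AG) states on their
#' minute timestamps, marks minutes with unscorable PSG as excluded *in both
#' streams*, and locates the Time-in-Bed (TIB) window:
#'
#' * `tib_start_idx` is the first minute starting at or after lights-out
#'   (a lights-out event falling mid-minute therefore rounds forward to the
#'   next minute boundary);
#' * `tib_end_idx` is the "Awake" anchor: the last *included* minute whose PSG
#'   state is `Sleep`. Terminal wake minutes after it lie outside TIB.
#'
#' All downstream sleep measures and epoch-by-epoch statistics are computed
#' over included minutes within `[tib_start_idx, tib_end_idx]`.
#'
#' @param psg_minutes Tibble of PSG minutes with columns `minute_start`,
#'   `state` and `scorable` (from [downsample_hypnogram_to_minutes()]).
#' @param ag_states Tibble of device minutes with columns `minute_start` and
#'   `state` (from [cole_kripke()] / [score_night()]).
#' @param lights_out POSIXct lights-out timestamp.
#' @param participant_id Participant identifier carried through to results.
#' @return An `aligned_night` object: a list with `participant_id`, a `data`
#'   tibble (`minute_start`, `psg_state`, `ag_state`, `included`) and the
#'   integer indices `tib_start_idx`, `tib_end_idx` (1-based, inclusive).
#' @export
align_night <- function(psg_minutes, ag_states, lights_out,
                        participant_id = "unknown") {
  assert_states(psg_minutes$state, "psg state")
  assert_states(ag_states$state, "ag state")
  merged <- dplyr::inner_join(
    tibble(minute_start = psg_minutes$minute_start,
           psg_state = psg_minutes$state,
           included = psg_minutes$scorable),
    tibble(minute_start = ag_states$minute_start,
           ag_state = ag_states$state),
    by = "minute_start"
  )
  merged <- dplyr::arrange(merged, .data$minute_start)
  if (nrow(merged) == 0) {
    stop("PSG and AG minute streams have no overlapping timestamps", call. = FALSE)
  }
  tib_start <- which(merged$minute_start >= lights_out)[1]
  if (is.na(tib_start)) {
    stop("lights_out falls after the end of the overlapping record", call. = FALSE)
  }
  sleep_idx <- which(merged$included & merged$psg_state == "Sleep" &
                       seq_len(nrow(merged)) >= tib_start)
  if (length(sleep_idx) == 0) {
    stop("no sleep night: no scorable PSG Sleep minute after lights out",
         call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      data = tibble(minute_start = merged$minute_start,
                    psg_state = merged$psg_state,
                    ag_state = merged$ag_state,
                    included = merged$included),
      tib_start_idx = as.integer(tib_start),
      tib_end_idx = as.integer(max(sleep_idx))
    ),
    class = "aligned_night"
  )
}

#' @export
print.aligned_night <- function(x, ...) {
  n_tib <- sum(x$data$included[x$tib_start_idx:x$tib_end_idx])
  cat(sprintf(
    "<aligned_night> participant %s: %d aligned minutes, TIB minutes %d..%d (%d included)\n",
    x$participant_id, nrow(x$data), x$tib_start_idx, x$tib_end_idx, n_tib))
  invisible(x)
}

# Internal: device states over included minutes within TIB, in order.
tib_states <- function(night, device = c("PSG", "AG")) {
  device <- match.arg(device)
  idx <- night$tib_start_idx:night$tib_end_idx
  keep <- idx[night$data$included[idx]]
  col <- if (device == "PSG") "psg_state" else "ag_state"
  night$data[[col]][keep]
}
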