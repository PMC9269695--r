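#' Epoch-by-epoch confusion counts and agreement statistics
#'
#' Cross-tabulates the minute-level device (AG) states against the PSG
#' criterion over all supplied nights and computes, in the sleep-scoring
#' convention:
#'
#' * agreement — percentage of minutes where the devices agree;
#' * sensitivity — percentage of PSG `Sleep` minutes the AG also scored
#'   `Sleep`;
#' * specificity — percentage of PSG `Wake` minutes the AG also scored
#'   `Wake`.
#'
#' Counts are pooled over all participants' compared minutes for the headline
#' numbers; a per-participant breakdown is returned alongside for
#' diagnostics. Only included (scorable) minutes are compared. By default the
#' comparison window is Time-in-Bed, where all the sleep measures live; the
#' `full_night` scope compares every included aligned minute instead.
#'
#' @param nights A list of [align_night()] objects.
#' @param scope `"TIB"` (default) or `"full_night"`.
#' @return A list of class `epoch_agreement`: `pooled` is a one-row tibble
#'   with `tp` (both Sleep), `tn` (both Wake), `fp` (AG Sleep, PSG Wake),
#'   `fn` (AG Wake, PSG Sleep), `agreement_pct`, `sensitivity_pct`,
#'   `specificity_pct`; `per_participant` is the same per night. A statistic
#'   whose denominator is zero (e.g. specificity with no PSG Wake minutes)
#'   is `NA`.
#' @export
confusion <- function(nights, scope = c("TIB", "full_night")) {
  scope <- match.arg(scope)
  if (length(nights) == 0) stop("no nights supplied", call. = FALSE)
  one <- function(night) {
    if (scope == "TIB") {
      psg <- tib_states(night, "PSG")
      ag <- tib_states(night, "AG")
    } else {
      keep <- night$data$included
      psg <- night$data$psg_state[keep]
      ag <- night$data$ag_state[keep]
    }
    tibble(
      participant_id = night$participant_id,
      tp = sum(psg == "Sleep" & ag == "Sleep"),
      tn = sum(psg == "Wake" & ag == "Wake"),
      fp = sum(psg == "Wake" & ag == "Sleep"),
      fn = sum(psg == "Sleep" & ag == "Wake")
    )
  }
  per <- dplyr::bind_rows(lapply(nights, one))
  rates <- function(tbl) {
    dplyr::mutate(
      tbl,
      agreement_pct = 100 * (.data$tp + .data$tn) /
        (.data$tp + .data$tn + .data$fp + .data$fn),
      sensitivity_pct = ifelse(.data$tp + .data$fn > 0,
                               100 * .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity_pct = ifelse(.data$tn + .data$fp > 0,
                               100 * .data$tn / (.data$tn + .data$fp), NA_real_)
    )
  }
  pooled <- rates(dplyr::summarise(
    per, tp = sum(.data$tp), tn = sum(.data$tn),
    fp = sum(.data$fp), fn = sum(.data$fn)))
  structure(list(pooled = pooled, per_participant = rates(per), scope = scope),
            class = "epoch_agreement")
}

#' @export
print.epoch_agreement <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<epoch_agreement> (%s scope, %d nights)\n  agreement %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
    x$scope, nrow(x$per_participant),
    p$agreement_pct, p$sensitivity_pct, p$specificity_pct))
  invisible(x)
}
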