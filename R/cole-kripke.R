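#' Cole-Kripke scoring parameters
#'
#' The Cole-Kripke classifier scores each 60 s epoch from a weighted sum of
#' rescaled activity counts over a window spanning the four preceding epochs,
#' the current epoch, and the two following epochs:
#'
#' \deqn{D_i = P \sum_{k=-4}^{+2} w_k \, a_{i+k}, \qquad
#'       a_j = \min(c_j / \mathrm{scale}, \mathrm{cap})}
#'
#' and the epoch is scored Sleep when `D < threshold` (ties score Wake).
#'
#' The original publication gives coefficients for wrist devices of its era;
#' the defaults here are the 60 s-epoch coefficient set in common use for
#' ActiGraph-family wrist counts (scale 100, cap 300, multiplier P = 0.001,
#' weights 106, 54, 58, 76, 230, 74, 67, threshold 1). Because coefficient
#' dialects differ between scoring packages, every value is overridable.
#'
#' @param scale Count rescale divisor (counts are divided by this before
#'   capping).
#' @param cap Post-scale ceiling on the rescaled counts.
#' @param weights Seven window weights, ordered
#'   \eqn{w_{-4}, w_{-3}, w_{-2}, w_{-1}, w_0, w_{+1}, w_{+2}}.
#' @param multiplier Overall multiplier \eqn{P}.
#' @param threshold Epochs with weighted sum strictly below this score Sleep.
#' @return A `cole_kripke_params` list.
#' @export
cole_kripke_params <- function(scale = 100, cap = 300,
                               weights = c(106, 54, 58, 76, 230, 74, 67),
                               multiplier = 0.001, threshold = 1.0) {
  stopifnot(scale > 0, cap > 0, multiplier > 0, length(weights) == 7,
            all(is.finite(weights)))
  structure(list(scale = scale, cap = cap, weights = as.numeric(weights),
                 multiplier = multiplier, threshold = threshold),
            class = "cole_kripke_params")
}

#' Score 60 s count epochs as Sleep/Wake (Cole-Kripke)
#'
#' Applies the sliding weighted-average window of [cole_kripke_params()] to a
#' contiguous 60 s activity-count series. Windows that extend past either end
#' of the series treat the missing neighbours as zero counts, so the output
#' has the same length as the input. Scoring is fully deterministic.
#'
#' @param counts A `count_epochs` tibble with 60 s epochs (use
#'   [collapse_epochs()] on finer series first).
#' @param params A [cole_kripke_params()] object.
#' @return A tibble (`scored_series`) with columns `participant_id`,
#'   `minute_start`, `score` (the weighted sum \eqn{D}) and `state`
#'   (`Sleep` iff `score < threshold`).
#' @export
cole_kripke <- function(counts, params = cole_kripke_params()) {
  stopifnot(inherits(params, "cole_kripke_params"))
  len <- epoch_len_s(counts)
  if (len != 60L && nrow(counts) > 1) {
    stop("Cole-Kripke scoring requires 60 s epochs (got ", len,
         " s); collapse the series first with collapse_epochs()", call. = FALSE)
  }
  a <- pmin(counts$counts / params$scale, params$cap)
  n <- length(a)
  apad <- c(rep(0, 4), a, rep(0, 2))
  d <- numeric(n)
  for (j in 1:7) {
    d <- d + params$weights[j] * apad[seq_len(n) + (j - 1L)]
  }
  d <- params$multiplier * d
  out <- tibble(
    participant_id = counts$participant_id,
    minute_start = counts$epoch_start,
    score = d,
    state = ifelse(d < params$threshold, "Sleep", "Wake")
  )
  structure(out, class = c("scored_series", class(out)))
}

#' Score a night with exclusion masking
#'
#' Scoring runs on the full continuous count series *before* any exclusion
#' masking, because each window needs its contiguous neighbours; minutes that
#' are unscorable on the PSG side are flagged excluded afterwards, leaving all
#' other scores untouched. Exclusion is an analysis filter, not a signal gap.
#'
#' @param counts A 60 s `count_epochs` tibble.
#' @param params A [cole_kripke_params()] object.
#' @param exclusion_mask Logical vector, one element per minute, `TRUE` where
#'   the minute is excluded; `NULL` for no exclusions.
#' @return The [cole_kripke()] tibble with an added logical `included` column.
#'   A fully excluded night returns zero usable minutes with a warning.
#' @export
score_night <- function(counts, params = cole_kripke_params(),
                        exclusion_mask = NULL) {
  scored <- cole_kripke(counts, params)
  if (is.null(exclusion_mask)) {
    scored$included <- TRUE
    return(scored)
  }
  if (length(exclusion_mask) != nrow(scored)) {
    stop("exclusion_mask length (", length(exclusion_mask),
         ") does not match the number of minutes (", nrow(scored), ")",
         call. = FALSE)
  }
  scored$included <- !exclusion_mask
  if (!any(scored$included)) {
    warning("all minutes excluded: night has no usable epochs", call. = FALSE)
  }
  scored
}
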