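#' Run the scoring-and-alignment pipeline on one paired night
#'
#' Composes the full per-night pipeline: binarize the PSG stages, take the
#' first 30 s epoch of each minute as the minute representative, collapse the
#' count series to 60 s epochs if the device emitted finer epochs, score it
#' with Cole-Kripke, and align the two minute streams within Time-in-Bed with
#' unscorable-minute exclusion.
#'
#' @param hypnogram A `hypnogram` (stages may be AASM or binary).
#' @param counts A `count_epochs` series (1 s or 60 s epochs).
#' @param params [cole_kripke_params()] for the scorer.
#' @param lights_out Lights-out timestamp; defaults to the hypnogram's.
#' @return An [align_night()] object.
#' @export
process_night <- function(hypnogram, counts, params = cole_kripke_params(),
                          lights_out = NULL) {
  if (is.null(lights_out)) lights_out <- attr(hypnogram, "lights_out")
  psg_minutes <- downsample_hypnogram_to_minutes(binarize_stages(hypnogram))
  if (epoch_len_s(counts) != 60L) counts <- collapse_epochs(counts, 60L)
  scored <- cole_kripke(counts, params)
  align_night(psg_minutes,
              tibble(minute_start = scored$minute_start, state = scored$state),
              lights_out = lights_out,
              participant_id = hypnogram$participant_id[1])
}

#' Full validation analysis over a cohort of paired nights
#'
#' Runs every analysis stage over a set of nights: the long metrics table for
#' all onset rules, pooled and per-participant epoch-by-epoch agreement,
#' the Cohen's d grid against the PSG 1-minute criterion, and the per-metric
#' mixed-effects Device/Rule bias models.
#'
#' @param nights A list of [align_night()] objects, or of
#'   [generate_night()] objects (which are pushed through [process_night()]
#'   first).
#' @param rules Integer onset rules in minutes.
#' @param params [cole_kripke_params()] used when scoring synthetic nights.
#' @param seed Seed for the effect-size bootstrap.
#' @param es_metrics Metrics to include in the effect-size grid and bias
#'   models; defaults to all five.
#' @return A list of class `validation_report`: `nights`, `metrics`,
#'   `summary` (median/IQR table), `agreement`, `effect_sizes`,
#'   `bias_models`.
#' @export
validate_cohort <- function(nights, rules = c(1L, 5L, 10L),
                            params = cole_kripke_params(), seed = 1L,
                            es_metrics = NULL) {
  if (length(nights) > 0 && inherits(nights[[1]], "synthetic_night")) {
    nights <- lapply(nights, function(sn) {
      process_night(sn$hypnogram, sn$counts, params)
    })
  }
  metrics <- metrics_table(nights, rules)
  if (!is.null(es_metrics)) metrics_es <- metrics[metrics$metric %in% es_metrics, ]
  else metrics_es <- metrics
  structure(
    list(
      nights = nights,
      metrics = metrics,
      summary = summarize_metrics(metrics),
      agreement = confusion(nights, scope = "TIB"),
      effect_sizes = effect_size_grid(metrics_es, seed = seed),
      bias_models = fit_bias_models(metrics_es)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d nights\n", length(x$nights)))
  print(x$agreement)
  print(x$bias_models)
  invisible(x)
}
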