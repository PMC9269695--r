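#' Cohen's d with bootstrap confidence interval and magnitude label
#'
#' Standardised difference between a criterion measure and a comparison
#' measure, per participant:
#' \deqn{d = \frac{\bar x_{crit} - \bar x_{comp}}{s_{pooled}}}
#' with the pooled SD over the two samples (denominator `n1 + n2 - 2`). The
#' sign convention follows the criterion-minus-comparator framing:
#' underestimation by the comparator yields positive d.
#'
#' The independent-samples pooled-SD form is used even though the samples are
#' paired by participant, matching the criterion-vs-comparator framing of
#' classical device-validation tables; `paired = TRUE` switches to the paired
#' form (mean difference over the SD of the differences).
#'
#' The confidence interval is a bias-corrected percentile bootstrap over
#' participants (participants are resampled jointly so the pairing is
#' preserved), with 2000 resamples by default.
#'
#' Magnitude labels follow the conventional bands on |d|:
#' negligible < 0.2, small 0.2-0.49, moderate 0.5-0.79, large >= 0.8.
#'
#' @param criterion_values,comparison_values Equal-length numeric vectors in
#'   the same participant order.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @param paired Use the paired form of d instead of the pooled-SD form.
#' @return A list of class `effect_size_result` with `d`, `ci_low`,
#'   `ci_high`, `label`, `n` and `paired`.
#' @export
cohens_d <- function(criterion_values, comparison_values,
                     conf_level = 0.95, n_boot = 2000, seed = NULL,
                     paired = FALSE) {
  x <- criterion_values
  y <- comparison_values
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (anyNA(x) || anyNA(y)) stop("missing values in effect-size input", call. = FALSE)
  point <- function(xi, yi) {
    if (paired) {
      dd <- xi - yi
      s <- sd(dd)
      if (s == 0) return(if (mean(dd) == 0) 0 else NaN)
      mean(dd) / s
    } else {
      n1 <- length(xi); n2 <- length(yi)
      sp <- sqrt(((n1 - 1) * stats::var(xi) + (n2 - 1) * stats::var(yi)) /
                   (n1 + n2 - 2))
      if (sp == 0) return(if (mean(xi) == mean(yi)) 0 else NaN)
      (mean(xi) - mean(yi)) / sp
    }
  }
  d <- point(x, y)
  if (is.nan(d)) {
    stop("zero pooled SD with unequal means: d is undefined", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    point(x[idx], y[idx])
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  if (length(boots) == 0 || length(unique(boots)) == 1L) {
    ci <- c(d, d)
  } else {
    # bias-corrected percentile interval
    alpha <- 1 - conf_level
    prop <- mean(boots < d)
    prop <- min(max(prop, 1 / (length(boots) + 1)), length(boots) / (length(boots) + 1))
    z0 <- qnorm(prop)
    lo_p <- pnorm(2 * z0 + qnorm(alpha / 2))
    hi_p <- pnorm(2 * z0 + qnorm(1 - alpha / 2))
    ci <- unname(quantile(boots, c(lo_p, hi_p)))
  }
  structure(
    list(d = d, ci_low = min(ci[1], d), ci_high = max(ci[2], d),
         label = effect_size_label(d), n = n, paired = paired),
    class = "effect_size_result"
  )
}

#' Magnitude label for an effect size
#'
#' @param d Numeric effect size (sign is ignored).
#' @return `"negligible"` (|d| < 0.2), `"small"` (0.2-0.49), `"moderate"`
#'   (0.5-0.79) or `"large"` (>= 0.8).
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.2 ~ "negligible",
    a < 0.5 ~ "small",
    a < 0.8 ~ "moderate",
    TRUE ~ "large"
  )
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.2f (%.2f, %.2f), %s (n = %d%s)\n",
              x$d, x$ci_low, x$ci_high, x$label, x$n,
              if (x$paired) ", paired" else ""))
  invisible(x)
}

#' Effect-size grid against the PSG 1-minute criterion
#'
#' For each sleep measure, computes Cohen's d of the criterion
#' (PSG under the 1-minute onset rule) against the five comparators:
#' PSG under each other rule and AG under every rule.
#'
#' @param metrics A long table from [metrics_table()] containing both devices
#'   and all rules for every participant.
#' @param criterion_rule Onset rule defining the criterion (default 1).
#' @param ... Passed to [cohens_d()] (e.g. `seed`, `n_boot`).
#' @return A tibble with one row per (metric, device, rule) comparison:
#'   `metric`, `device`, `rule`, `d`, `ci_low`, `ci_high`, `label`.
#' @export
effect_size_grid <- function(metrics, criterion_rule = 1L, ...) {
  rules <- sort(unique(metrics$rule))
  cells <- expand.grid(device = c("PSG", "AG"), rule = rules,
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$device == "PSG" & cells$rule == criterion_rule), ]
  pull_cell <- function(metric, device, rule) {
    sub <- metrics[metrics$metric == metric & metrics$device == device &
                     metrics$rule == rule, ]
    sub <- sub[order(sub$participant_id), ]
    ids <- unique(metrics$participant_id)
    if (nrow(sub) != length(ids)) {
      missing_ids <- setdiff(ids, sub$participant_id)
      stop(sprintf("missing metrics cell: participant %s, device %s, rule %d, metric %s",
                   paste(missing_ids, collapse = "/"), device, rule, metric),
           call. = FALSE)
    }
    sub$value
  }
  rows <- list()
  for (metric in unique(metrics$metric)) {
    crit <- pull_cell(metric, "PSG", criterion_rule)
    for (i in seq_len(nrow(cells))) {
      comp <- pull_cell(metric, cells$device[i], cells$rule[i])
      es <- cohens_d(crit, comp, ...)
      rows[[length(rows) + 1L]] <- tibble(
        metric = metric, device = cells$device[i], rule = cells$rule[i],
        d = es$d, ci_low = es$ci_low, ci_high = es$ci_high, label = es$label
      )
    }
  }
  dplyr::bind_rows(rows)
}
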