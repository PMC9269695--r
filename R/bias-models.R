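#' Mixed-effects device and onset-rule bias models
#'
#' For each sleep measure, fits a linear mixed-effects model of the metric
#' value with fixed effects for Device and Sleep Onset Rule and a random
#' intercept per participant:
#'
#' `value ~ Device * Rule + (1 | participant)`   (full)
#' `value ~ Device + Rule + (1 | participant)`   (reduced)
#'
#' The full and reduced models are fitted by maximum likelihood and compared
#' with a likelihood-ratio test; the interaction is retained only when the
#' LRT is significant at `alpha`. Reported estimates and Wald confidence
#' intervals come from the retained model refitted by REML.
#'
#' Coding: Device uses treatment contrasts with PSG as the reference, so the
#' `device_AG` estimate is the AG-minus-PSG bias (positive = AG
#' overestimation); Rule uses treatment contrasts with the smallest rule
#' (1 min) as reference. A second likelihood-ratio test for the Rule main
#' effect (reduced model vs. Device-only model) is reported alongside.
#'
#' A fit with zero estimated between-participant variance is kept (the
#' variance sits at its boundary) and flagged with a warning.
#'
#' @param metrics A long table from [metrics_table()].
#' @param alpha Significance level for the interaction LRT (default 0.05).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A list of class `bias_models` with elements
#'   `fixed_effects` (tibble: `metric`, `term`, `estimate`, `ci_low`,
#'   `ci_high`), `tests` (tibble: `metric`, `lrt_stat`, `lrt_p`,
#'   `interaction_retained`, `rule_lrt_stat`, `rule_lrt_p`) and `alpha`.
#' @export
fit_bias_models <- function(metrics, alpha = 0.05, conf_level = 0.95) {
  stopifnot(all(c("participant_id", "device", "rule", "metric", "value")
                %in% names(metrics)))
  if (length(unique(metrics$participant_id)) < 2) {
    stop("mixed models need at least 2 participants", call. = FALSE)
  }
  fe_rows <- list()
  test_rows <- list()
  for (m in unique(metrics$metric)) {
    dat <- metrics[metrics$metric == m, ]
    if (anyNA(dat$value)) {
      warning(sprintf("dropping %d rows with undefined %s values",
                      sum(is.na(dat$value)), m), call. = FALSE)
      dat <- dat[!is.na(dat$value), ]
    }
    dat$device <- stats::relevel(factor(dat$device), ref = "PSG")
    dat$rule_f <- factor(dat$rule, levels = sort(unique(dat$rule)))
    fit_ml <- function(form) {
      suppressMessages(lme4::lmer(form, data = dat, REML = FALSE))
    }
    full <- fit_ml(value ~ device * rule_f + (1 | participant_id))
    reduced <- fit_ml(value ~ device + rule_f + (1 | participant_id))
    device_only <- fit_ml(value ~ device + (1 | participant_id))
    lrt <- anova(reduced, full)
    lrt_stat <- lrt$Chisq[2]
    lrt_p <- lrt$`Pr(>Chisq)`[2]
    rule_lrt <- anova(device_only, reduced)
    retained_form <- if (lrt_p < alpha) {
      value ~ device * rule_f + (1 | participant_id)
    } else {
      value ~ device + rule_f + (1 | participant_id)
    }
    fit <- suppressMessages(lme4::lmer(retained_form, data = dat, REML = TRUE))
    if (lme4::isSingular(fit)) {
      warning(sprintf(
        "%s: between-participant variance estimated at its boundary (zero); fixed effects remain valid",
        m), call. = FALSE)
    }
    est <- lme4::fixef(fit)
    ci <- suppressMessages(stats::confint(fit, parm = "beta_", method = "Wald",
                                          level = conf_level))
    terms <- names(est)
    pretty <- gsub("^device", "device_", gsub("rule_f", "rule_", terms))
    fe_rows[[m]] <- tibble(
      metric = m, term = pretty,
      estimate = unname(est),
      ci_low = unname(ci[terms, 1]),
      ci_high = unname(ci[terms, 2])
    )
    test_rows[[m]] <- tibble(
      metric = m,
      lrt_stat = lrt_stat, lrt_p = lrt_p,
      interaction_retained = lrt_p < alpha,
      rule_lrt_stat = rule_lrt$Chisq[2],
      rule_lrt_p = rule_lrt$`Pr(>Chisq)`[2]
    )
  }
  structure(
    list(fixed_effects = dplyr::bind_rows(fe_rows),
         tests = dplyr::bind_rows(test_rows),
         alpha = alpha),
    class = "bias_models"
  )
}

#' @export
print.bias_models <- function(x, ...) {
  cat("<bias_models> per-metric mixed-effects Device/Rule fits\n")
  dev <- x$fixed_effects[grepl("^device_", x$fixed_effects$term), ]
  for (i in seq_len(nrow(dev))) {
    cat(sprintf("  %-14s %s bias %+7.2f (%.2f, %.2f)\n",
                dev$metric[i], sub("device_", "", dev$term[i]),
                dev$estimate[i], dev$ci_low[i], dev$ci_high[i]))
  }
  invisible(x)
}

#' Device bias estimates from fitted bias models
#'
#' Convenience accessor: the AG-minus-PSG fixed-effect estimate (and CI) per
#' metric.
#'
#' @param models A [fit_bias_models()] result.
#' @return A tibble with `metric`, `estimate`, `ci_low`, `ci_high`.
#' @export
device_bias <- function(models) {
  fe <- models$fixed_effects
  out <- fe[fe$term == "device_AG", c("metric", "estimate", "ci_low", "ci_high")]
  tibble::as_tibble(out)
}
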