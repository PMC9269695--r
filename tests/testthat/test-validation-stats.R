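test_that("confusion counts and rates match the hand-built 2x2 table", {
  # PSG = S,S,W,W vs AG = S,S,S,W inside a TIB covering all four minutes:
  # wrap with anchor minutes so TIB spans the block exactly
  psg <- c("Sleep", "Sleep", "Wake", "Wake", "Sleep")
  ag <- c("Sleep", "Sleep", "Sleep", "Wake", "Sleep")
  night <- make_night(psg, ag)
  cm <- confusion(list(night))$pooled
  expect_equal(cm$tp, 3L)  # includes the anchor minute
  expect_equal(cm$tn, 1L)
  expect_equal(cm$fp, 1L)
  expect_equal(cm$fn, 0L)

  # the bare 4-minute example via sequence-level counting
  sub_psg <- psg[1:4]; sub_ag <- ag[1:4]
  tp <- sum(sub_psg == "Sleep" & sub_ag == "Sleep")
  tn <- sum(sub_psg == "Wake" & sub_ag == "Wake")
  expect_equal(100 * (tp + tn) / 4, 75)
  expect_equal(100 * tp / sum(sub_psg == "Sleep"), 100)
  expect_equal(100 * tn / sum(sub_psg == "Wake"), 50)

  # identical sequences agree perfectly
  set.seed(91)
  s <- c(random_states(50), "Sleep")
  perfect <- confusion(list(make_night(s)))$pooled
  expect_equal(perfect$agreement_pct, 100)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)

  # an AG that always sleeps: sensitivity 100, specificity 0
  deg <- confusion(list(make_night(s, rep("Sleep", length(s)))))$pooled
  expect_equal(deg$sensitivity_pct, 100)
  expect_equal(deg$specificity_pct, 0)

  # all-Sleep PSG: specificity undefined
  allsleep <- confusion(list(make_night(rep("Sleep", 30))))$pooled
  expect_true(is.na(allsleep$specificity_pct))
})

test_that("agreement equals the prevalence-weighted sensitivity/specificity mix", {
  set.seed(101)
  for (i in 1:50) {
    psg <- c(random_states(80, runif(1, 0.3, 0.9)), "Sleep")
    ag <- random_states(81, runif(1, 0.3, 0.9))
    cm <- confusion(list(make_night(psg, ag)))$pooled
    n <- cm$tp + cm$tn + cm$fp + cm$fn
    p <- (cm$tp + cm$fn) / n
    if (is.na(cm$specificity_pct) || is.na(cm$sensitivity_pct)) next
    expect_equal(cm$agreement_pct,
                 cm$sensitivity_pct * p + cm$specificity_pct * (1 - p),
                 tolerance = 1e-9)
  }
})

test_that("Cohen's d matches closed forms, labels, and symmetry properties", {
  same <- cohens_d(c(1, 2, 3), c(1, 2, 3), n_boot = 200, seed = 1)
  expect_equal(same$d, 0)
  expect_equal(same$label, "negligible")

  # pooled SD 1, mean difference -1
  es <- cohens_d(c(1, 2, 3), c(2, 3, 4), n_boot = 500, seed = 1)
  expect_equal(es$d, -1)
  expect_equal(es$label, "large")
  expect_true(es$ci_low <= es$d && es$d <= es$ci_high)

  expect_equal(effect_size_label(c(0.1, 0.3, 0.6, 0.9, -0.9)),
               c("negligible", "small", "moderate", "large", "large"))

  set.seed(111)
  x <- rnorm(20, 10, 2); y <- rnorm(20, 12, 2)
  a <- cohens_d(x, y, n_boot = 50, seed = 2)
  b <- cohens_d(y, x, n_boot = 50, seed = 2)
  expect_equal(a$d, -b$d)                     # antisymmetry
  c3 <- cohens_d(3 * x, 3 * y, n_boot = 50, seed = 2)
  expect_equal(c3$d, a$d)                     # scale invariance

  expect_error(cohens_d(c(1, 1, 1), c(2, 2, 2)), "zero pooled SD")
  expect_equal(cohens_d(c(1, 1, 1), c(1, 1, 1), n_boot = 50)$d, 0)

  # paired form: constant offset has infinite-ish standardized paired effect
  pr <- cohens_d(x, x - 2 + rnorm(20, 0, 0.5), paired = TRUE,
                 n_boot = 50, seed = 3)
  expect_true(pr$paired)
  expect_gt(pr$d, 1)
})

test_that("bootstrap CI covers the point estimate and narrows with n", {
  set.seed(121)
  x10 <- rnorm(10, 5, 1); y10 <- rnorm(10, 6, 1)
  x100 <- rnorm(100, 5, 1); y100 <- rnorm(100, 6, 1)
  e10 <- cohens_d(x10, y10, n_boot = 1000, seed = 4)
  e100 <- cohens_d(x100, y100, n_boot = 1000, seed = 4)
  expect_true(e10$ci_low <= e10$d && e10$d <= e10$ci_high)
  expect_lt(e100$ci_high - e100$ci_low, e10$ci_high - e10$ci_low)
})

test_that("the effect-size grid is PSG@1-criterion shaped and exact on constructed cohorts", {
  # identical devices, rule-invariant metrics: every d is 0
  base <- make_bias_table(6, dev_off = 0, seed = 5, res_sd = 0)
  grid0 <- effect_size_grid(base, n_boot = 50, seed = 6)
  expect_equal(nrow(grid0), 5L)  # one metric, five comparators
  expect_true(all(grid0$d == 0))
  expect_false(any(grid0$device == "PSG" & grid0$rule == 1))

  # AG SOL = PSG SOL - 20 with sample SD exactly 10 -> d = +2 in AG columns
  ids <- sprintf("p%02d", 1:3)
  psg_sol <- c(10, 20, 30)  # sd exactly 10
  rows <- expand.grid(participant_id = ids, device = c("PSG", "AG"),
                      rule = c(1L, 5L, 10L), stringsAsFactors = FALSE)
  rows$metric <- "sol_min"
  rows$value <- ifelse(rows$device == "PSG",
                       psg_sol[match(rows$participant_id, ids)],
                       psg_sol[match(rows$participant_id, ids)] - 20)
  grid <- effect_size_grid(tibble::as_tibble(rows), n_boot = 50, seed = 7)
  ag_rows <- grid[grid$device == "AG", ]
  expect_equal(ag_rows$d, rep(2, 3))
  expect_equal(unique(grid$d[grid$device == "PSG"]), 0)

  # a missing cell is reported with its coordinates
  broken <- rows[!(rows$participant_id == "p02" & rows$device == "AG" &
                     rows$rule == 5L), ]
  expect_error(effect_size_grid(tibble::as_tibble(broken), n_boot = 50),
               "p02, device AG, rule 5")
})

test_that("mixed models recover injected device bias and stay null on null data", {
  rec <- fit_bias_models(make_bias_table(50, dev_off = 26, seed = 8))
  dev <- device_bias(rec)
  expect_lt(abs(dev$estimate - 26), 2)
  expect_true(dev$ci_low <= 26 && 26 <= dev$ci_high)
  expect_false(rec$tests$interaction_retained)

  # null cohort: near-zero fixed effects, interaction not retained
  null_fit <- fit_bias_models(make_bias_table(30, dev_off = 0, seed = 9))
  fe <- null_fit$fixed_effects
  nonint <- fe[fe$term != "(Intercept)", ]
  expect_true(all(abs(nonint$estimate) < 5))
  expect_false(null_fit$tests$interaction_retained)

  # a generated Device x Rule interaction is detected
  int_fit <- fit_bias_models(make_bias_table(30, dev_off = 0, rule10_off = 10,
                                             seed = 10))
  expect_true(int_fit$tests$interaction_retained)

  expect_error(fit_bias_models(make_bias_table(1, seed = 11)),
               "at least 2 participants")
})
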