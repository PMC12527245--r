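test_that("generator config validation names the offending field", {
  expect_error(generator_config(p_sin_test = 1.5), "p_sin_test")
  expect_error(generator_config(n_participants = -1), "n_participants")
  expect_error(generator_config(event_rate_baseline = -0.1),
               "event_rate_baseline")
  expect_error(generator_config(hl_dating_error_years = -2),
               "hl_dating_error_years")
  expect_error(generator_config(baseline_end = "2005-01-01"), "baseline_end")
})

test_that("zero participants give empty, schema-valid tables end to end", {
  tabs <- generate_cohort(generator_config(n_participants = 0))
  expect_s3_class(tabs, "cohort_tables")
  for (nm in c("participants", "visits", "ehr_events", "healthcare_counts",
               "truth")) {
    expect_true(is.data.frame(tabs[[nm]]))
    expect_identical(nrow(tabs[[nm]]), 0L)
  }
  em <- emulate_trial(tabs)
  expect_identical(nrow(em$trial) + nrow(em$ledger), 0L)
})

test_that("identical config and seed reproduce identical tables", {
  a <- generate_cohort(generator_config(n_participants = 600, seed = 42))
  b <- generate_cohort(generator_config(n_participants = 600, seed = 42))
  for (nm in c("participants", "visits", "ehr_events", "healthcare_counts",
               "truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c3 <- generate_cohort(generator_config(n_participants = 600, seed = 43))
  expect_false(identical(a$ehr_events, c3$ehr_events))
})

test_that("generated tables obey the schema invariants", {
  tabs <- generate_cohort(generator_config(n_participants = 3000, seed = 9))
  p <- tabs$participants; e <- tabs$ehr_events; v <- tabs$visits
  expect_true(all(e$event_date >= as.Date("1940-01-01")))
  expect_true(all(e$event_date <= tabs$config$followup_end))
  expect_true(all(is.na(p$death_date) | p$death_date >= p$birth_ym))
  linked_ids <- p$id[p$linked]
  expect_true(all(e$id[e$source == "primary"] %in% linked_ids))
  expect_true(all(v$sr_hearing_difficulty %in% c("yes", "no", "")))
  expect_true(all(v$sr_background_noise %in% c("yes", "no", "")))
  hc <- tabs$healthcare_counts
  expect_true(all(is.na(hc$gp_events[!hc$id %in% linked_ids])))
  expect_true(all(hc$hospital_spells >= 0))
})

test_that("the scenario library covers the candidate bias explanations", {
  presets <- scenario_library()
  expect_true(all(c("null", "protective", "healthcare_confounded",
                    "dating_error", "combined") %in% names(presets)))
  expect_gte(length(presets), 5L)
  for (nm in names(presets)) expect_true(nzchar(presets[[nm]]$pattern))

  nul <- scenario_library("null")
  expect_identical(nul$true_log_rr_treatment, 0)
  expect_identical(nul$detection_bias_strength, 0)
  expect_true(all(unlist(nul$covariate_effect_vector) == 0))

  comb <- scenario_library("combined")
  expect_gt(comb$detection_bias_strength, 0)
  expect_gt(comb$hl_dating_error_years, 0)

  expect_error(scenario_library("not_a_preset"), "unknown scenario")
})

test_that("dating error forward-shifts recordable onsets for non-linked only", {
  tabs <- generate_cohort(scenario_library("dating_error",
                                           n_participants = 4000, seed = 5))
  tru <- merge(tabs$truth, tabs$participants[c("id", "linked")], by = "id")
  nl <- !tru$linked & tru$true_hl
  li <- tru$linked & tru$true_hl
  shift_nl <- hatrial:::years_between(tru$true_onset[nl],
                                      tru$recordable_onset[nl])
  expect_gt(mean(shift_nl), 3)        # exponential, mean 5 y
  expect_true(all(shift_nl >= 0))
  expect_true(all(hatrial:::years_between(tru$true_onset[li],
                                          tru$recordable_onset[li]) == 0))
})

test_that("stronger detection bias never lowers the crude risk ratio", {
  crude <- function(strength, seed) {
    cfg <- generator_config(n_participants = 15000, seed = seed,
                            conf_healthcare_on_exposure = 0.6,
                            detection_bias_strength = strength)
    tr <- emulate_trial(generate_cohort(cfg))$trial
    a <- tr$arm == "HA"
    log(mean(tr$event_itt[a]) / mean(tr$event_itt[!a]))
  }
  avg <- sapply(c(0, 0.4, 0.8), function(s) {
    mean(sapply(1:3, function(k) crude(s, k)))  # common random numbers per seed
  })
  expect_true(all(diff(avg) > -0.02))
})

test_that("the null scenario yields a crude risk ratio near one", {
  tabs <- generate_cohort(scenario_library("null", n_participants = 50000,
                                           seed = 3))
  tr <- emulate_trial(tabs)$trial
  a <- tr$arm == "HA"
  x1 <- sum(tr$event_itt[a]); n1 <- sum(a)
  x0 <- sum(tr$event_itt[!a]); n0 <- sum(!a)
  lrr <- log((x1 / n1) / (x0 / n0))
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
  expect_lt(abs(lrr), 3 * se)
})

test_that("healthcare confounding plus detection bias flips the crude sign", {
  cfg <- generator_config(n_participants = 50000, seed = 5,
                          true_log_rr_treatment = log(0.9),
                          conf_healthcare_on_exposure = 0.5,
                          detection_bias_strength = 0.4)
  tabs <- generate_cohort(cfg)
  tr <- emulate_trial(tabs)$trial
  a <- tr$arm == "HA"
  crude <- mean(tr$event_itt[a]) / mean(tr$event_itt[!a])
  expect_gt(crude, 1)
  tru <- tabs$truth[match(tr$id, tabs$truth$id), ]
  end <- hatrial:::pmin_date(tr$death_date,
                             rep(tabs$config$followup_end, nrow(tr)))
  inwin <- function(d, sel) {
    mean(!is.na(d[sel]) & d[sel] > tr$time_zero[sel] & d[sel] <= end[sel])
  }
  truth_rr <- inwin(tru$dementia_date_treated, a) /
    inwin(tru$dementia_date_control, a)
  expect_lt(truth_rr, 1)
})

test_that("perfect linkage and dating let ascertainment recover true onsets", {
  cfg <- generator_config(n_participants = 3000, seed = 11,
                          p_primary_care_linkage = 1, p_hl_ehr_primary = 1,
                          hl_ehr_delay_mean_years = 0,
                          hl_dating_error_years = 0,
                          sin_mean_nohl = -20, sin_sd = 1, sin_meas_sd = 0.2)
  tabs <- generate_cohort(cfg)
  hl <- ascertain_hearing_loss(tabs)
  tru <- tabs$truth
  has <- tru$true_hl
  expect_true(all(!is.na(hl$hl_date[has])))
  expect_true(all(hl$hl_date[has] == tru$true_onset[has]))
})

test_that("cohort tables survive a text round trip", {
  tabs <- generate_cohort(generator_config(n_participants = 500, seed = 21))
  dir <- tempfile()
  write_cohort(tabs, dir, include_truth = TRUE)
  back <- read_cohort(dir)
  em1 <- emulate_trial(tabs)
  em2 <- emulate_trial(back)
  expect_equal(nrow(em1$trial), nrow(em2$trial))
  expect_equal(em1$trial$arm, em2$trial$arm)
  expect_equal(em1$trial$event_itt, em2$trial$event_itt)
  expect_equal(ledger_counts(em1$ledger), ledger_counts(em2$ledger))
  expect_equal(back$config$followup_end, tabs$config$followup_end)
  expect_error(read_cohort(tempfile()), "missing cohort table")
})
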