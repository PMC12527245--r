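test_that("E-values match the closed form and its algebra", {
  expect_equal(round(evalue(1.43, 1.00)$evalue, 2), 2.21)
  expect_equal(round(evalue(1.43, 0.86)$evalue, 2), 2.71)
  expect_equal(evalue(1.0, 1.0)$evalue, 1.0)
  expect_error(evalue(-1), "positive")
  expect_error(evalue(1.4, 0), "positive")

  # strictly increasing in the observed ratio above one
  rs <- seq(1.05, 4, by = 0.05)
  es <- vapply(rs, function(r) evalue(r)$evalue, numeric(1))
  expect_true(all(diff(es) > 0))
  # invariant to inverting both ratios, and E(r, r) = 1
  for (r in c(0.3, 0.86, 1.43, 2.5)) {
    for (t in c(0.5, 1, 1.6)) {
      expect_equal(evalue(r, t)$evalue, evalue(1 / r, 1 / t)$evalue,
                   tolerance = 1e-12)
    }
    expect_equal(evalue(r, r)$evalue, 1.0)
  }
})

test_that("the negative-control battery reruns the pipeline per outcome", {
  tabs <- generate_cohort(generator_config(n_participants = 8000, seed = 23,
                                           conf_healthcare_on_exposure = 0.5,
                                           detection_bias_strength = 0.4))
  trial <- emulate_trial(tabs)$trial
  nc <- negative_control_battery(trial, tabs)
  expect_length(nc, 9L)
  expect_true(all(grepl("^negative_control:", names(nc))))
  est <- nc[["negative_control:influenza"]]
  expect_false(is.na(est$point))
  expect_true(is.logical(est$ci_excludes_1))

  # an empty class list gives an empty section; an absent class is flagged
  expect_length(negative_control_battery(trial, tabs, classes = character(0)),
                0L)
  nc2 <- negative_control_battery(trial, tabs,
                                  classes = c("influenza", "scurvy"))
  expect_true(is.na(nc2[["negative_control:scurvy"]]$point))
  expect_match(nc2[["negative_control:scurvy"]]$note, "absent")
  expect_false(is.na(nc2[["negative_control:influenza"]]$point))
})

test_that("the combined covariate effect behaves across signal strengths", {
  # constant scores are not estimable
  trial0 <- sim_trial(500, seed = 71)
  est0 <- combined_covariate_effect(trial0, rep(0.2, 500))
  expect_true(is.na(est0$point))
  expect_match(est0$note, "constant")

  # no covariate-outcome effects: RR per SD near 1
  zero_eff <- list(exposure = 0 * hatrial:::DEFAULT_COVARIATE_EFFECTS$exposure,
                   outcome = 0 * hatrial:::DEFAULT_COVARIATE_EFFECTS$outcome)
  tabs_null <- generate_cohort(generator_config(
    n_participants = 20000, seed = 72, covariate_effect_vector = zero_eff
  ))
  tr_null <- emulate_trial(tabs_null)$trial
  ps_null <- fit_propensity(tr_null)
  e_null <- combined_covariate_effect(tr_null, ps_null)
  expect_lt(abs(log(e_null$point)), 3 * e_null$log_se)

  # strong covariate-outcome effects push the per-SD RR above 1
  tabs_str <- generate_cohort(generator_config(n_participants = 50000,
                                               seed = 73))
  tr_str <- emulate_trial(tabs_str)$trial
  ps_str <- fit_propensity(tr_str)
  e_str <- combined_covariate_effect(tr_str, ps_str)
  expect_gt(e_str$point, 1)
  expect_gt(e_str$ci_lower, 1)
})

test_that("healthcare-use analyses find the built-in detection gradient", {
  tabs <- generate_cohort(generator_config(n_participants = 50000, seed = 74,
                                           detection_bias_strength = 0.6,
                                           conf_healthcare_on_outcome = 0.4))
  trial <- emulate_trial(tabs)$trial
  out <- healthcare_use_analyses(trial, tabs)
  top <- out[["dementia_by_pre_hosp_cat:>0.5"]]
  expect_gt(top$point, 1)
  expect_true(any(grepl("^ha_on_post_", names(out))))
})

test_that("healthcare-use contrasts handle degenerate category layouts", {
  trial <- data.frame(arm = rep(c("HA", "control"), each = 100),
                      time_zero = as.Date("2010-06-01"),
                      event_itt = rep(c(TRUE, FALSE), times = c(20, 180)),
                      hosp_cat = factor("0", levels = hatrial:::HOSP_CAT_LEVELS),
                      gp_cat = factor("[0,12]", levels = hatrial:::GP_CAT_LEVELS))
  tabs <- mini_tables(p_row(1:200),
                      healthcare_counts = hc_rows(1:200, 2015L))
  trial$id <- 1:200
  out <- healthcare_use_analyses(trial, tabs)
  pre <- out[grepl("^dementia_by_pre_", names(out))]
  expect_true(all(vapply(pre, function(e) is.na(e$point), logical(1))))

  # two categories with identical event rates and sizes give RR = 1 exactly
  trial2 <- trial
  trial2$hosp_cat <- factor(rep(c("0", "(0,0.2]"), 100),
                            levels = hatrial:::HOSP_CAT_LEVELS)
  trial2$event_itt <- rep(c(TRUE, TRUE, FALSE, FALSE), 50)
  out2 <- healthcare_use_analyses(trial2, tabs)
  expect_equal(out2[["dementia_by_pre_hosp_cat:(0,0.2]"]]$point, 1)
})

test_that("the sensitivity grid runs every named variant with its config delta", {
  grid <- run_sensitivity_grid(list(preset = "null", n_participants = 6000,
                                    seed = 25))
  expect_s3_class(grid, "sensitivity_grid")
  expect_identical(nrow(grid), 20L)
  expect_identical(sum(!grepl("^negative_control:", grid$variant)), 11L)
  expect_identical(sum(grepl("^negative_control:", grid$variant)), 9L)
  expect_setequal(
    sub("^negative_control:", "",
        grid$variant[grepl("^negative_control:", grid$variant)]),
    c("influenza", "liver_disease", "lower_respiratory", "asthma",
      "skin_disorder", "infectious_parasitic", "appendicitis",
      "hip_fracture", "transport_accident")
  )
  expect_true(all(nzchar(grid$config_delta)))
  expect_setequal(unique(grid$type),
                  c("basic", "sample change", "extra adjust.", "neg. control"))

  restricted <- run_sensitivity_grid(list(preset = "null",
                                          n_participants = 6000, seed = 25,
                                          variants = "basic_itt"))
  expect_identical(nrow(restricted), 1L)
  expect_identical(restricted$variant, "basic_itt")

  expect_error(
    run_sensitivity_grid(list(preset = "null", n_participants = 1000,
                              variants = "basic_itt_typo")),
    "unknown sensitivity variant"
  )
})
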