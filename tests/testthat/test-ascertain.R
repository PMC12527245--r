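test_that("the earliest source dates hearing loss, with the fixed tie order", {
  tabs <- mini_tables(
    p_row(1),
    visits = v_row(1, "2010-06-01", q1 = "yes", q2 = "yes"),
    ehr_events = e_row(1, "2008-03-01", "HL", source = "primary")
  )
  hl <- ascertain_hearing_loss(tabs)
  expect_equal(hl$hl_date, as.Date("2008-03-01"))
  expect_equal(hl$source, "ehr")

  # a same-month tie is attributed ehr > sin_test > self_report
  tie <- mini_tables(
    p_row(1),
    visits = v_row(1, "2010-06-01", sin = -4, q1 = "yes", q2 = "yes"),
    ehr_events = e_row(1, "2010-06-01", "HL")
  )
  expect_equal(ascertain_hearing_loss(tie)$source, "ehr")
  tie$ehr_events <- tie$ehr_events[0, ]
  expect_equal(ascertain_hearing_loss(tie)$source, "sin_test")
})

test_that("the SiN cutoff is -5.5 dB, poorer-hearing side inclusive", {
  tabs <- mini_tables(p_row(1:2), visits = rbind(
    v_row(1, "2009-05-01", sin = -6.0),
    v_row(2, "2009-05-01", sin = -5.5)
  ))
  hl <- ascertain_hearing_loss(tabs)
  expect_true(is.na(hl$hl_date[1]))   # -6.0 is better hearing than the cutoff
  expect_equal(hl$hl_date[2], as.Date("2009-05-01"))
  expect_equal(hl$source[2], "sin_test")
})

test_that("one affirmative plus one unanswered question makes self-report missing", {
  tabs <- mini_tables(p_row(1),
                      visits = v_row(1, "2009-05-01", q1 = "yes", q2 = ""))
  hl <- ascertain_hearing_loss(tabs)
  expect_true(is.na(hl$hl_date))
  expect_true(hl$self_missing)

  # 'do not know' is treated as missing, not as an answer
  dk <- mini_tables(p_row(1),
                    visits = v_row(1, "2009-05-01", q1 = "yes",
                                   q2 = "do not know"))
  expect_true(ascertain_hearing_loss(dk)$self_missing)

  bad <- mini_tables(p_row(1),
                     visits = v_row(1, "2009-05-01", q1 = "maybe"))
  expect_error(ascertain_hearing_loss(bad), "malformed answer")
})

test_that("EHR hearing loss with only undated codes is missing, not absent", {
  ev <- e_row(1, "2009-01-01", "HL")
  ev$event_date <- as.Date(NA)
  tabs <- mini_tables(p_row(1), ehr_events = ev)
  hl <- ascertain_hearing_loss(tabs)
  expect_true(is.na(hl$ehr_date))
  expect_true(hl$ehr_missing)
})

test_that("hearing-aid use is dated at the earliest record across sources", {
  tabs <- mini_tables(
    p_row(1:3),
    visits = rbind(v_row(1, "2012-03-01", ha = "yes"),
                   v_row(3, "2010-01-01", implant = "yes")),
    ehr_events = e_row(1, "2011-05-01", "HA")
  )
  ha <- ascertain_ha_use(tabs)
  expect_equal(ha$ha_date[1], as.Date("2011-05-01"))
  expect_equal(ha$ha_source[1], "ehr")
  expect_true(is.na(ha$ha_date[2]))
  expect_true(ha$implant[3])
  expect_false(ha$implant[1])
})

test_that("the eligibility cascade applies the rules in the quoted order", {
  tabs <- mini_tables(
    p_row(1:5),
    visits = rbind(
      v_row(1, "2007-01-01"), v_row(2, "2007-01-01"), v_row(3, "2007-01-01"),
      v_row(4, "2007-01-01", q1 = "yes", q2 = "yes"),
      v_row(5, "2007-01-01", q1 = "yes", q2 = "yes")
    ),
    ehr_events = rbind(
      e_row(2, "2009-01-01", "HL"), e_row(2, "2005-06-01", "dementia"),
      e_row(3, "2009-01-01", "HL"), e_row(3, "2008-01-01", "HA"),
      # id 5 fails two rules; the first (outcome before HL) must win
      e_row(5, "2006-01-01", "dementia"), e_row(5, "2004-01-01", "HA")
    )
  )
  hl <- ascertain_hearing_loss(tabs)
  ha <- ascertain_ha_use(tabs)
  elig <- apply_eligibility(hl, ha, tabs)
  led <- elig$ledger
  expect_equal(led$reason[led$id == 1], "no_hl_date")
  expect_equal(led$reason[led$id == 2], "outcome_before_hl")
  expect_equal(led$reason[led$id == 3], "ha_before_hl")
  expect_equal(led$reason[led$id == 5], "outcome_before_hl")
  expect_true(4 %in% elig$skeleton$id)         # fully eligible: a row, no entry
  expect_false(4 %in% led$id)
})

test_that("the pre-baseline rule can be dropped, resetting dates to study start", {
  tabs <- mini_tables(
    p_row(1),
    visits = v_row(1, "2007-03-01"),
    ehr_events = rbind(e_row(1, "2004-02-01", "HL", source = "primary"),
                       e_row(1, "2005-06-01", "HA"))
  )
  hl <- ascertain_hearing_loss(tabs)
  ha <- ascertain_ha_use(tabs)
  strict <- apply_eligibility(hl, ha, tabs, drop_prebaseline_rule = TRUE)
  expect_equal(strict$ledger$reason, "hl_before_baseline")
  relaxed <- apply_eligibility(hl, ha, tabs, drop_prebaseline_rule = FALSE)
  expect_equal(nrow(relaxed$ledger), 0L)
  expect_equal(relaxed$skeleton$time_zero, as.Date("2007-03-01"))
  expect_equal(relaxed$skeleton$ha_date, as.Date("2007-03-01"))
})

test_that("arms follow hearing-aid initiation within the grace period", {
  skel <- data.frame(
    id = 1:3,
    time_zero = as.Date(c("2008-01-01", "2008-01-01", "2008-01-01")),
    hl_source = "self_report",
    ha_date = as.Date(c("2008-05-01", "2009-07-01", NA)),  # +0.4 y, +1.5 y, never
    cessation_date = as.Date(NA),
    outcome_date = as.Date(c(NA, NA, "2016-01-01")),       # dementia at 8 y
    death_date = as.Date(NA),
    baseline_date = as.Date("2008-01-01"),
    admin_end = as.Date("2022-12-01"),
    stringsAsFactors = FALSE
  )
  itt <- assign_arms_and_followup(skel, grace_years = 1, contrast = "itt")
  expect_equal(itt$arm, c("HA", "control", "control"))
  expect_true(is.na(itt$pp_censor_date[1]))
  expect_true(itt$outcome_event[3])
  expect_equal(itt$followup_years[3], 8)

  pp <- assign_arms_and_followup(skel, grace_years = 1,
                                 contrast = "per_protocol")
  expect_equal(pp$arm, itt$arm)
  expect_equal(pp$pp_censor_date[2], as.Date("2009-07-01"))
  expect_lt(pp$followup_years[2], itt$followup_years[2])
  expect_true(pp$outcome_event[3])

  expect_error(assign_arms_and_followup(skel, grace_years = 0), "grace_years")
})

test_that("an infinite grace period with no cessation makes per-protocol equal ITT", {
  tabs <- generate_cohort(generator_config(n_participants = 1500, seed = 13))
  hl <- ascertain_hearing_loss(tabs)
  ha <- ascertain_ha_use(tabs)
  skel <- apply_eligibility(hl, ha, tabs, grace_years = 1)$skeleton
  itt <- assign_arms_and_followup(skel, grace_years = Inf, contrast = "itt")
  pp <- assign_arms_and_followup(skel, grace_years = Inf,
                                 contrast = "per_protocol")
  expect_identical(itt$followup_end, pp$followup_end)
  expect_identical(itt$outcome_event, pp$outcome_event)
})

test_that("covariates anchor to the closest visit, earlier on ties, within 5 years", {
  trial <- data.frame(id = 1:3,
                      time_zero = as.Date(rep("2010-01-01", 3)),
                      stringsAsFactors = FALSE)
  visits <- rbind(
    v_row(1, "2008-01-01", g = 1), v_row(1, "2014-01-01", g = 2),  # -2 vs +4
    v_row(2, "2007-01-01", g = 3), v_row(2, "2013-01-01", g = 4),  # -3 vs +3
    v_row(3, "2004-01-01", g = 5)                                  # -6: too far
  )
  tabs <- mini_tables(p_row(1:3), visits = visits)
  out <- measure_covariates(trial, tabs)
  expect_equal(out$g, c(1, 3, NA))
  expect_equal(out$cov_visit_date[1], as.Date("2008-01-01"))
})

test_that("healthcare use maps onto the published category boundaries", {
  ids <- 1:4
  tz <- as.Date(rep("2010-06-01", 4))
  counts <- rbind(
    hc_rows(1, 2005:2009, gp = 15L, hosp = c(0L, 1L, 0L, 1L, 1L)), # 0.6/yr? no: 3/5 = 0.6 -> >0.5
    hc_rows(2, 2005:2009, gp = 8L, hosp = c(1L, 0L, 0L, 0L, 0L)),  # 0.2/yr
    hc_rows(3, 2005:2009, gp = 30L, hosp = 0L),                    # zero hosp
    hc_rows(4, 2005:2009, gp = NA, hosp = c(0L, 1L, 1L, 0L, 0L))   # 0.4/yr, no gp data
  )
  hc <- categorize_healthcare_use(counts, ids, tz, window_years = 5,
                                  side = "pre")
  expect_equal(as.character(hc$hosp_cat), c(">0.5", "(0,0.2]", "0", "(0.2,0.5]"))
  expect_equal(as.character(hc$gp_cat), c("(12,24]", "[0,12]", ">24", NA))

  post <- categorize_healthcare_use(hc_rows(1, 2011:2015, gp = 5L, hosp = 0L),
                                    1L, tz[1], side = "post")
  expect_equal(as.character(post$hosp_cat), "0")

  bad <- hc_rows(1, 2009, gp = -1L)
  expect_error(categorize_healthcare_use(bad, 1L, tz[1]), "negative counts")
})

test_that("every generated participant lands in the trial or ledger exactly once", {
  for (preset in c("null", "healthcare_confounded", "combined")) {
    tabs <- generate_cohort(scenario_library(preset, n_participants = 3000,
                                             seed = 7))
    em <- emulate_trial(tabs)
    expect_identical(nrow(em$trial) + nrow(em$ledger), 3000L)
    expect_false(any(duplicated(c(em$trial$id, em$ledger$id))))
    expect_true(all(em$trial$fu_years_pp <= em$trial$fu_years_itt + 1e-12))
    expect_true(all(em$ledger$reason %in% hatrial:::ELIGIBILITY_REASONS))
  }
})
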