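## Synthetic EHR cohort generator.
##
## Emulates the data structure of a population cohort with linked electronic
## health records in which hearing loss (HL) is ascertained from three
## sources -- paired self-report questions, a speech-in-noise (SiN) threshold,
## and dated EHR codes -- hearing-aid (HA) initiation is recorded in the EHR
## and at assessment visits, and dementia, death and a set of negative-control
## conditions accrue over follow-up.  Two bias mechanisms are tunable:
## (i) healthcare-use confounding / detection bias -- a latent healthcare-use
## propensity raises HA uptake, (optionally) the true dementia hazard, and the
## probability that a dementia that occurs is *recorded*; and (ii) systematic
## late dating of HL for participants without primary-care linkage.

NEG_CONTROL_CLASSES <- c(
  "influenza", "liver_disease", "lower_respiratory", "asthma",
  "skin_disorder", "infectious_parasitic", "appendicitis",
  "hip_fracture", "transport_accident"
)

DEFAULT_COVARIATE_EFFECTS <- list(
  # log-odds / log-hazard effects of centred covariates
  exposure = c(age = 0.04, sexM = 0.10, education = 0.05,
               deprivation = -0.03, g = -0.05, sin = 0.35, tinnitus = 0.40),
  outcome  = c(age = 0.08, sexM = 0.15, education = -0.10,
               deprivation = 0.04, g = -0.25, sin = 0.05, tinnitus = 0.05)
)

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated generator configuration.  Defaults describe the study
#' conditions the package emulates: entry assessments in 2006-2010, EHR
#' follow-up to the end of 2022, 45.8% primary-care linkage, HL ascertained
#' roughly 55/42/3% from self-report / SiN test / EHR, and no treatment
#' effect, confounding, detection bias or dating error unless switched on.
#'
#' @param n_participants number of participants to generate.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   tables.
#' @param baseline_start,baseline_end calendar window of entry assessments.
#' @param followup_end administrative end of EHR follow-up.
#' @param p_primary_care_linkage probability of primary-care linkage.
#' @param true_log_rr_treatment log risk ratio of HA initiation on dementia
#'   (applied multiplicatively to the dementia hazard from initiation).
#' @param conf_healthcare_on_exposure log-odds effect of the latent
#'   healthcare-use propensity (SD units) on HA uptake.
#' @param conf_healthcare_on_outcome log-hazard effect of the latent
#'   healthcare-use propensity on dementia occurrence.
#' @param detection_bias_strength extra log-odds of a *recorded* dementia (or
#'   negative-control) diagnosis per hospital-use category (0-3).
#' @param detection_base_logodds baseline log-odds that an occurred condition
#'   is recorded in the EHR.
#' @param hl_dating_error_years mean (years) of the exponential forward shift
#'   of the recordable HL onset for participants without primary-care linkage.
#' @param covariate_effect_vector list with elements `exposure` and `outcome`,
#'   each a named vector of log-odds / log-hazard effects for
#'   age, sexM, education, deprivation, g, sin, tinnitus.
#' @param event_rate_baseline dementia occurrence hazard per year at reference
#'   covariate values.
#' @param death_rate_baseline death hazard per year at reference age.
#' @param p_ha_uptake baseline probability of ever initiating HA after a
#'   recorded HL.
#' @param ha_delay_mean_years mean delay (years) from recorded HL to HA
#'   initiation.
#' @param effect_grace_years window (years) after the recorded HL date
#'   within which HA initiation carries the treatment effect (the effect
#'   attaches to the assigned strategy; align with the analysis grace
#'   period).
#' @param p_ha_predate fraction of HA users whose record predates their HL
#'   record (exercises the HA-before-HL exclusion).
#' @param p_implant probability that an HA user has a cochlear-implant record.
#' @param p_sin_test probability that the SiN test is administered at a visit.
#' @param p_selfreport_both_yes probability that a participant with
#'   recordable HL answers both hearing questions affirmatively at a visit.
#' @param sin_mean_hl,sin_mean_nohl,sin_sd mean SiN threshold (dB; higher =
#'   poorer hearing) with / without HL and its between-person SD.
#' @param sin_meas_sd within-person measurement SD of the SiN threshold.
#' @param hl_hazard_base,hl_hazard_log_age HL onset hazard per year at age 60
#'   and its log-linear age slope (onset risk starts at age 40).
#' @param p_hl_ehr_primary,p_hl_ehr_inpatient probability of a dated EHR HL
#'   code (primary care, linked participants only; inpatient, anyone).
#' @param hl_ehr_delay_mean_years mean delay (years) from recordable onset to
#'   the primary-care HL code (inpatient codes take twice this mean); zero
#'   dates EHR codes exactly at onset.
#' @param control_outcome_rate occurrence hazard per year of each
#'   negative-control condition.
#' @param p_visit2,p_visit3 probabilities of attending the repeat assessments.
#' @param p_dementia_prevalent probability of a prevalent (pre-entry) dementia
#'   record.
#' @param p_tinnitus,p_mood,p_head_injury,p_social_isolation covariate
#'   prevalences.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 10000,
                             seed = 1L,
                             baseline_start = "2006-01-01",
                             baseline_end = "2010-12-01",
                             followup_end = "2022-12-01",
                             p_primary_care_linkage = 0.458,
                             true_log_rr_treatment = 0,
                             conf_healthcare_on_exposure = 0,
                             conf_healthcare_on_outcome = 0,
                             detection_bias_strength = 0,
                             detection_base_logodds = 2.2,
                             hl_dating_error_years = 0,
                             covariate_effect_vector = DEFAULT_COVARIATE_EFFECTS,
                             event_rate_baseline = 0.010,
                             death_rate_baseline = 0.012,
                             p_ha_uptake = 0.15,
                             ha_delay_mean_years = 0.35,
                             effect_grace_years = 1,
                             p_ha_predate = 0.03,
                             p_implant = 0.004,
                             p_sin_test = 0.55,
                             p_selfreport_both_yes = 0.78,
                             sin_mean_hl = -5.9,
                             sin_mean_nohl = -9.5,
                             sin_sd = 2.3,
                             sin_meas_sd = 0.5,
                             hl_hazard_base = 0.05,
                             hl_hazard_log_age = 0.08,
                             p_hl_ehr_primary = 0.10,
                             p_hl_ehr_inpatient = 0.02,
                             hl_ehr_delay_mean_years = 0.5,
                             control_outcome_rate = 0.004,
                             p_visit2 = 0.04,
                             p_visit3 = 0.15,
                             p_dementia_prevalent = 0.002,
                             p_tinnitus = 0.40,
                             p_mood = 0.11,
                             p_head_injury = 0.01,
                             p_social_isolation = 0.47) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  cfg$baseline_start <- floor_month(as.Date(cfg$baseline_start))
  cfg$baseline_end <- floor_month(as.Date(cfg$baseline_end))
  cfg$followup_end <- floor_month(as.Date(cfg$followup_end))
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stopf("invalid generator configuration: `%s` %s", field, what)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$n_participants) && cfg$n_participants >= 0 &&
        cfg$n_participants == round(cfg$n_participants),
      "n_participants", "must be a nonnegative integer")
  chk(num1(cfg$seed), "seed", "must be a single number")
  for (f in c("p_primary_care_linkage", "p_ha_uptake", "p_ha_predate",
              "p_implant", "p_sin_test", "p_selfreport_both_yes",
              "p_visit2", "p_visit3", "p_dementia_prevalent", "p_tinnitus",
              "p_mood", "p_head_injury", "p_social_isolation")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must be a probability in [0, 1]")
  }
  for (f in c("event_rate_baseline", "death_rate_baseline",
              "hl_hazard_base", "control_outcome_rate",
              "hl_dating_error_years", "ha_delay_mean_years",
              "effect_grace_years", "hl_ehr_delay_mean_years",
              "sin_sd", "sin_meas_sd")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a nonnegative number")
  }
  for (f in c("true_log_rr_treatment", "conf_healthcare_on_exposure",
              "conf_healthcare_on_outcome", "detection_bias_strength",
              "detection_base_logodds", "sin_mean_hl", "sin_mean_nohl",
              "hl_hazard_log_age")) {
    chk(num1(cfg[[f]]), f, "must be a single finite number")
  }
  ce <- cfg$covariate_effect_vector
  nm <- names(DEFAULT_COVARIATE_EFFECTS$exposure)
  chk(is.list(ce) && all(c("exposure", "outcome") %in% names(ce)) &&
        all(nm %in% names(ce$exposure)) && all(nm %in% names(ce$outcome)),
      "covariate_effect_vector",
      "must be a list with named `exposure` and `outcome` vectors")
  dates <- lapply(cfg[c("baseline_start", "baseline_end", "followup_end")],
                  function(d) tryCatch(as.Date(d), error = function(e) NA))
  chk(!anyNA(dates), "baseline_start/baseline_end/followup_end",
      "must be parseable dates")
  chk(dates$baseline_start <= dates$baseline_end, "baseline_end",
      "must not precede baseline_start")
  chk(dates$baseline_end <= dates$followup_end, "followup_end",
      "must not precede baseline_end")
  invisible(cfg)
}

#' Library of generator scenario presets
#'
#' Named presets covering the candidate explanations of a spurious
#' harmful-looking HA effect: `null` (all effect parameters zero, for
#' calibration), `protective` (true marginal risk ratio 0.86, measured
#' confounding only), `healthcare_confounded` (no true effect; healthcare use
#' raises HA uptake, the dementia hazard and the recording probability, so the
#' crude and basic adjusted estimates are biased upward), `dating_error` (no
#' true effect; HL of non-linked participants is recorded on average 5 years
#' late), and `combined` (mildly protective truth plus both bias mechanisms,
#' built to make the basic estimate exceed the healthcare-use-adjusted one).
#'
#' @param name preset name; `NULL` returns the full named list.
#' @param n_participants,seed passed to every preset.
#' @return A `generator_config`, or a named list of them when `name` is NULL.
#' @export
scenario_library <- function(name = NULL, n_participants = 10000, seed = 1L) {
  zero_eff <- list(
    exposure = 0 * DEFAULT_COVARIATE_EFFECTS$exposure,
    outcome = 0 * DEFAULT_COVARIATE_EFFECTS$outcome
  )
  presets <- list(
    null = generator_config(
      n_participants = n_participants, seed = seed,
      true_log_rr_treatment = 0,
      conf_healthcare_on_exposure = 0, conf_healthcare_on_outcome = 0,
      detection_bias_strength = 0, hl_dating_error_years = 0,
      covariate_effect_vector = zero_eff
    ),
    protective = generator_config(
      n_participants = n_participants, seed = seed,
      true_log_rr_treatment = log(0.86)
    ),
    healthcare_confounded = generator_config(
      n_participants = n_participants, seed = seed,
      true_log_rr_treatment = 0,
      conf_healthcare_on_exposure = 0.5,
      conf_healthcare_on_outcome = 0.3,
      detection_bias_strength = 0.4
    ),
    dating_error = generator_config(
      n_participants = n_participants, seed = seed,
      true_log_rr_treatment = 0,
      hl_dating_error_years = 5
    ),
    combined = generator_config(
      n_participants = n_participants, seed = seed,
      true_log_rr_treatment = log(0.9),
      conf_healthcare_on_exposure = 0.8,
      conf_healthcare_on_outcome = 0.4,
      detection_bias_strength = 0.6,
      hl_dating_error_years = 5
    )
  )
  patterns <- c(
    null = "all effect parameters zero; estimates centred on RR = 1",
    protective = "true marginal RR 0.86 in the treated; recoverable after adjustment",
    healthcare_confounded = "no true effect; crude and basic estimates biased above 1",
    dating_error = "no true effect; HL of non-linked participants dated ~5 y late",
    combined = "protective truth (RR 0.9) masked; basic estimate exceeds healthcare-use-adjusted estimate"
  )
  for (nm in names(presets)) presets[[nm]]$pattern <- patterns[[nm]]
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stopf("unknown scenario preset '%s' (available: %s)", name,
          paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

empty_cohort_tables <- function(config) {
  out <- list(
    participants = data.frame(
      id = integer(), birth_ym = as.Date(character()), sex = character(),
      ethnicity = character(), education = character(),
      deprivation = numeric(), region = character(), linked = logical(),
      death_date = as.Date(character()), stringsAsFactors = FALSE
    ),
    visits = data.frame(
      id = integer(), visit_date = as.Date(character()), sin_db = numeric(),
      sr_hearing_difficulty = character(), sr_background_noise = character(),
      g_score = numeric(), social_isolation = logical(),
      sr_ha_use = character(), sr_cochlear_implant = character(),
      stringsAsFactors = FALSE
    ),
    ehr_events = data.frame(
      id = integer(), event_date = as.Date(character()),
      event_class = character(), source = character(), stringsAsFactors = FALSE
    ),
    healthcare_counts = data.frame(
      id = integer(), year = integer(), gp_events = integer(),
      hospital_spells = integer(), stringsAsFactors = FALSE
    ),
    truth = data.frame(
      id = integer(), h_latent = numeric(), true_hl = logical(),
      true_onset = as.Date(character()), recordable_onset = as.Date(character()),
      recorded_hl = as.Date(character()), sin_level = numeric(),
      lambda_dementia = numeric(), ha_ever = logical(),
      ha_date = as.Date(character()), dementia_date_control = as.Date(character()),
      dementia_date_treated = as.Date(character()),
      dementia_date_actual = as.Date(character()), dementia_recorded = logical(),
      stringsAsFactors = FALSE
    ),
    config = config
  )
  class(out) <- "cohort_tables"
  out
}

#' Generate a synthetic cohort
#'
#' Draws a full set of cohort tables from a [generator_config()].  The return
#' value bundles the four observable tables (`participants`, `visits`,
#' `ehr_events`, `healthcare_counts`) with a latent-truth sidecar (`truth`)
#' holding true HL onsets, the latent healthcare-use propensity, individual
#' dementia hazards and counterfactual event dates.  The sidecar exists only
#' for recovery tests; no analysis stage reads it.
#'
#' @param config a `generator_config`.
#' @return A list of class `cohort_tables`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  n <- as.integer(config$n_participants)
  if (n == 0L) return(empty_cohort_tables(config))
  set.seed(as.integer(config$seed))

  fu_end <- config$followup_end
  id <- seq_len(n)

  ## -- participants -----------------------------------------------------
  baseline_date <- runif_month(n, config$baseline_start, config$baseline_end)
  age0 <- stats::runif(n, 40, 69)
  birth_ym <- add_months(baseline_date, -years_to_months(age0))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ethnicity <- ifelse(stats::runif(n) < 0.94, "White", "non-White")
  education <- sample(c("none", "secondary", "higher"), n, replace = TRUE,
                      prob = c(0.16, 0.33, 0.51))
  deprivation <- pmin(pmax(stats::rnorm(n, -2, 2.9), -6.5), 12)
  region <- sample(c("England", "Scotland", "Wales", "Unknown"), n,
                   replace = TRUE, prob = c(0.904, 0.022, 0.021, 0.053))
  linked <- stats::runif(n) < config$p_primary_care_linkage
  h_latent <- stats::rnorm(n)
  g_true <- stats::rnorm(n)
  social_isolation <- stats::runif(n) < config$p_social_isolation
  tinnitus <- stats::runif(n) < config$p_tinnitus
  mood <- stats::runif(n) < config$p_mood
  head_injury <- stats::runif(n) < config$p_head_injury

  ## -- true HL onset (age-dependent hazard from age 40) -----------------
  k <- config$hl_hazard_log_age
  h0 <- config$hl_hazard_base
  e_hl <- stats::rexp(n)
  onset_age <- if (abs(k) < 1e-12) {
    40 + e_hl / max(h0, 1e-300)
  } else {
    60 + log(pmax(k * e_hl / h0 + exp(k * (40 - 60)), 1e-300)) / k
  }
  onset_date <- add_months(birth_ym, years_to_months(onset_age))
  true_hl <- !is.na(onset_date) & onset_date <= fu_end
  onset_date[!true_hl] <- NA

  ## late dating: for non-linked participants the onset only becomes
  ## recordable (by any source) after an exponential delay
  rec_onset <- onset_date
  if (config$hl_dating_error_years > 0) {
    shift <- stats::rexp(n, rate = 1 / config$hl_dating_error_years)
    late <- !linked & true_hl
    rec_onset[late] <- add_months(onset_date[late], years_to_months(shift[late]))
  }

  sin_level <- ifelse(true_hl,
                      stats::rnorm(n, config$sin_mean_hl, config$sin_sd),
                      stats::rnorm(n, config$sin_mean_nohl, config$sin_sd))

  ## -- healthcare utilisation -------------------------------------------
  lambda_gp <- exp(2.4 + 0.5 * h_latent)
  lambda_hosp <- exp(-2.2 + 0.7 * h_latent)
  years <- seq(2000L, as.integer(format(fu_end, "%Y")))
  ny <- length(years)
  hc <- data.frame(
    id = rep(id, each = ny),
    year = rep(years, times = n),
    gp_events = NA_integer_,
    hospital_spells = stats::rpois(n * ny, rep(lambda_hosp, each = ny))
  )
  is_linked_row <- rep(linked, each = ny)
  hc$gp_events[is_linked_row] <-
    stats::rpois(sum(is_linked_row), rep(lambda_gp, each = ny)[is_linked_row])

  ## hospital-use category over the 5 years before entry drives how likely
  ## an occurred condition is to be *recorded*; computed from the same counts
  ## table the analysis sees, so adjusting for the observed category can
  ## actually remove the recording bias
  hs_mat <- matrix(hc$hospital_spells, nrow = ny)  # one column per id
  by <- date_year(baseline_date)
  mean_hosp <- rowSums(vapply(1:5, function(j) {
    hs_mat[cbind(by - j - years[1] + 1L, id)]
  }, numeric(n))) / 5
  hosp_cat <- cut(mean_hosp, c(-Inf, 0, 0.2, 0.5, Inf), labels = FALSE) - 1L
  p_record <- stats::plogis(config$detection_base_logodds +
                              config$detection_bias_strength * hosp_cat)

  ## -- visits ------------------------------------------------------------
  visit_list <- list(baseline_date)
  who_list <- list(id)
  has_v2 <- stats::runif(n) < config$p_visit2
  if (any(has_v2)) {
    visit_list <- c(visit_list, list(runif_month(sum(has_v2),
                                                 as.Date("2012-01-01"),
                                                 as.Date("2013-12-01"))))
    who_list <- c(who_list, list(id[has_v2]))
  }
  has_v3 <- stats::runif(n) < config$p_visit3
  if (any(has_v3)) {
    visit_list <- c(visit_list, list(runif_month(sum(has_v3),
                                                 as.Date("2014-01-01"),
                                                 as.Date("2019-12-01"))))
    who_list <- c(who_list, list(id[has_v3]))
  }
  v_id <- unlist(who_list)
  v_date <- as.Date(unlist(lapply(visit_list, as.numeric)),
                    origin = "1970-01-01")
  nv <- length(v_id)

  hl_visible <- true_hl[v_id] & !is.na(rec_onset[v_id]) &
    v_date >= rec_onset[v_id]

  ## paired self-report answers ("" = missing)
  u <- stats::runif(nv)
  q1 <- q2 <- rep("no", nv)
  p_by <- config$p_selfreport_both_yes
  yes_both <- hl_visible & u < p_by
  yes_miss <- hl_visible & u >= p_by & u < p_by + 0.06
  yes_no <- hl_visible & u >= p_by + 0.06 & u < p_by + 0.12
  q1[yes_both | yes_miss | yes_no] <- "yes"
  q2[yes_both] <- "yes"
  q2[yes_miss] <- ""
  ## occasional missingness without HL
  miss_both <- !hl_visible & u < 0.04
  q1[miss_both] <- ""
  q2[miss_both] <- ""

  sin_measured <- stats::runif(nv) < config$p_sin_test
  sin_db <- rep(NA_real_, nv)
  base_sin <- ifelse(hl_visible, sin_level[v_id],
                     ifelse(true_hl[v_id], config$sin_mean_nohl +
                              (sin_level[v_id] - config$sin_mean_hl),
                            sin_level[v_id]))
  sin_db[sin_measured] <- base_sin[sin_measured] +
    stats::rnorm(sum(sin_measured), 0, config$sin_meas_sd)

  g_score <- g_true[v_id] + stats::rnorm(nv, 0, 0.3)

  visits <- data.frame(
    id = v_id, visit_date = v_date, sin_db = sin_db,
    sr_hearing_difficulty = q1, sr_background_noise = q2,
    g_score = g_score, social_isolation = social_isolation[v_id],
    sr_ha_use = "no", sr_cochlear_implant = "no",
    stringsAsFactors = FALSE
  )

  ## -- EHR HL codes ------------------------------------------------------
  ehr <- list()
  ehr_delay <- function(k, mean_years) {
    if (mean_years <= 0) rep(0, k) else stats::rexp(k, 1 / mean_years)
  }
  prim_hl <- linked & true_hl & stats::runif(n) < config$p_hl_ehr_primary
  if (any(prim_hl)) {
    d <- add_months(rec_onset[prim_hl],
                    years_to_months(ehr_delay(sum(prim_hl),
                                              config$hl_ehr_delay_mean_years)))
    keep <- d <= fu_end
    ehr$hl_prim <- data.frame(id = id[prim_hl][keep], event_date = d[keep],
                              event_class = "HL", source = "primary",
                              stringsAsFactors = FALSE)
  }
  inpat_hl <- true_hl & stats::runif(n) < config$p_hl_ehr_inpatient
  if (any(inpat_hl)) {
    d <- add_months(rec_onset[inpat_hl],
                    years_to_months(ehr_delay(sum(inpat_hl),
                                              2 * config$hl_ehr_delay_mean_years)))
    keep <- d <= fu_end
    ehr$hl_inpat <- data.frame(id = id[inpat_hl][keep], event_date = d[keep],
                               event_class = "HL", source = "inpatient",
                               stringsAsFactors = FALSE)
  }

  ## realized earliest recorded HL date (the generator's own bookkeeping;
  ## the ascertain module recomputes this from the raw tables)
  min_by_id <- function(ids, dates) {
    out <- rep(NA_real_, n)
    if (length(ids)) {
      agg <- tapply(as.numeric(dates), ids, min)
      out[as.integer(names(agg))] <- agg
    }
    as.Date(out, origin = "1970-01-01")
  }
  sr_hit <- visits$sr_hearing_difficulty == "yes" &
    visits$sr_background_noise == "yes"
  self_date <- min_by_id(visits$id[sr_hit], visits$visit_date[sr_hit])
  sin_hit <- !is.na(visits$sin_db) & visits$sin_db >= -5.5
  sin_date <- min_by_id(visits$id[sin_hit], visits$visit_date[sin_hit])
  ehr_hl_all <- do.call(rbind, ehr)
  ehr_date <- if (is.null(ehr_hl_all)) as.Date(rep(NA_real_, n), origin = "1970-01-01") else
    min_by_id(ehr_hl_all$id, ehr_hl_all$event_date)
  recorded_hl <- pmin_date(self_date, sin_date, ehr_date)

  ## -- HA initiation -----------------------------------------------------
  ## HA uptake and dementia risk are driven by the *recorded* assessment
  ## values at the time of ascertainment -- age at the recorded HL date and
  ## the SiN / G measurements from the visit closest to it (the same values
  ## the covariate-anchoring rule will later pick), falling back to baseline
  ## measurements and then latent levels.  Adjustment for the measured
  ## covariates can therefore remove all non-healthcare confounding.
  ce <- config$covariate_effect_vector
  educ_num <- match(education, c("none", "secondary", "higher")) - 1L
  sin_obs_base <- sin_db[seq_len(n)]      # baseline visit rows come first
  g_obs_base <- g_score[seq_len(n)]
  sin_dgp <- ifelse(!is.na(sin_obs_base), sin_obs_base, base_sin[seq_len(n)])
  g_dgp <- g_obs_base
  age_dgp <- age0
  rec <- which(!is.na(recorded_hl))
  if (length(rec)) {
    nv_sin <- nearest_visit_value(id[rec], recorded_hl[rec], visits,
                                  "sin_db", 60L)
    nv_g <- nearest_visit_value(id[rec], recorded_hl[rec], visits,
                                "g_score", 60L)
    sin_dgp[rec] <- ifelse(!is.na(nv_sin$value), nv_sin$value, sin_dgp[rec])
    g_dgp[rec] <- ifelse(!is.na(nv_g$value), nv_g$value, g_dgp[rec])
    age_dgp[rec] <- years_between(birth_ym[rec], recorded_hl[rec])
  }
  x <- cbind(
    age = age_dgp - 62,
    sexM = (sex == "M") - 0.5,
    education = educ_num - 1.35,
    deprivation = deprivation + 2,
    g = g_dgp,
    sin = ifelse(true_hl, sin_dgp - config$sin_mean_hl,
                 sin_dgp - config$sin_mean_nohl),
    tinnitus = tinnitus - 0.4
  )
  nm <- colnames(x)
  xb_exp <- drop(x %*% ce$exposure[nm])
  xb_out <- drop(x %*% ce$outcome[nm])

  p_ha <- stats::plogis(stats::qlogis(config$p_ha_uptake) + xb_exp +
                          config$conf_healthcare_on_exposure * h_latent)
  ha_ever <- !is.na(recorded_hl) & stats::runif(n) < p_ha
  ha_date <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  if (any(ha_ever)) {
    delay <- stats::rexp(sum(ha_ever), rate = 1 / max(config$ha_delay_mean_years, 1e-9))
    ha_date[ha_ever] <- add_months(recorded_hl[ha_ever], years_to_months(delay))
    predates <- ha_ever & stats::runif(n) < config$p_ha_predate
    if (any(predates)) {
      ha_date[predates] <- add_months(recorded_hl[predates],
                                      -sample(1:24, sum(predates), replace = TRUE))
    }
    ha_ever <- ha_ever & ha_date <= fu_end
    ha_date[!ha_ever] <- NA
  }
  implant <- ha_ever & stats::runif(n) < config$p_implant

  if (any(ha_ever)) {
    ehr$ha <- data.frame(id = id[ha_ever], event_date = ha_date[ha_ever],
                         event_class = ifelse(implant[ha_ever], "implant", "HA"),
                         source = "inpatient", stringsAsFactors = FALSE)
    ## self-report of HA use at visits on/after initiation
    after <- !is.na(ha_date[visits$id]) & visits$visit_date >= ha_date[visits$id]
    visits$sr_ha_use[after & stats::runif(nv) < 0.9] <- "yes"
    imp_after <- after & implant[visits$id]
    visits$sr_cochlear_implant[imp_after] <- "yes"
  }

  ## -- death -------------------------------------------------------------
  lambda_death <- config$death_rate_baseline * exp(0.09 * (age0 - 62))
  t_death <- stats::rexp(n, rate = pmax(lambda_death, 1e-12))
  death_date <- add_months(baseline_date, years_to_months(t_death))
  death_date[death_date > fu_end] <- NA

  ## -- dementia occurrence + recording ----------------------------------
  ## the treatment effect is built as pointwise risk proportionality:
  ## F_treated(t) = a * F_control(t) with a = exp(true_log_rr_treatment),
  ## so the marginal risk ratio in the treated equals `a` exactly over any
  ## follow-up window and under any independent censoring.  The effect
  ## attaches to the assigned strategy: HA initiation within
  ## `effect_grace_years` of the recorded HL date.
  lambda_dem <- config$event_rate_baseline *
    exp(xb_out + config$conf_healthcare_on_outcome * h_latent)
  lam <- pmax(lambda_dem, 1e-12)
  u_dem <- stats::runif(n)
  t_ctrl <- -log(1 - u_dem) / lam
  a_eff <- exp(config$true_log_rr_treatment)
  u_sc <- pmin(u_dem / a_eff, 1 - 1e-16)
  t_trt <- ifelse(u_dem < a_eff, -log(1 - u_sc) / lam, Inf)
  dem_ctrl <- add_months(baseline_date, years_to_months(pmin(t_ctrl, 500)))
  dem_ctrl[t_ctrl > 400] <- NA
  dem_trt <- add_months(baseline_date, years_to_months(pmin(t_trt, 500)))
  dem_trt[t_trt > 400] <- NA
  effect_on <- ha_ever & !is.na(recorded_hl) &
    ha_date <= add_months(recorded_hl,
                          years_to_months(config$effect_grace_years))
  effect_on[is.na(effect_on)] <- FALSE
  dem_act <- dem_ctrl
  dem_act[effect_on] <- dem_trt[effect_on]
  prevalent <- stats::runif(n) < config$p_dementia_prevalent
  if (any(prevalent)) {
    prev_date <- add_months(baseline_date[prevalent],
                            -sample(1:120, sum(prevalent), replace = TRUE))
    dem_act[prevalent] <- pmin_date(dem_act[prevalent], prev_date)
  }
  observable <- !is.na(dem_act) & dem_act <= fu_end &
    (is.na(death_date) | dem_act <= death_date)
  dem_recorded <- observable & stats::runif(n) < p_record
  if (any(dem_recorded)) {
    ehr$dementia <- data.frame(id = id[dem_recorded],
                               event_date = dem_act[dem_recorded],
                               event_class = "dementia", source = "inpatient",
                               stringsAsFactors = FALSE)
  }

  ## -- negative-control conditions (occurrence independent of HA) -------
  for (cl in NEG_CONTROL_CLASSES) {
    t_cl <- stats::rexp(n, rate = max(config$control_outcome_rate, 1e-12))
    d_cl <- add_months(baseline_date, years_to_months(t_cl))
    obs <- !is.na(d_cl) & d_cl <= fu_end &
      (is.na(death_date) | d_cl <= death_date) &
      stats::runif(n) < p_record
    if (any(obs)) {
      ehr[[cl]] <- data.frame(id = id[obs], event_date = d_cl[obs],
                              event_class = cl, source = "inpatient",
                              stringsAsFactors = FALSE)
    }
  }

  ## -- history covariates as inpatient codes -----------------------------
  hist_event <- function(flag, class) {
    if (!any(flag)) return(NULL)
    data.frame(id = id[flag],
               event_date = add_months(baseline_date[flag],
                                       -sample(1:180, sum(flag), replace = TRUE)),
               event_class = class, source = "inpatient",
               stringsAsFactors = FALSE)
  }
  ehr$tinnitus <- hist_event(tinnitus, "tinnitus")
  ehr$mood <- hist_event(mood, "mood")
  ehr$head_injury <- hist_event(head_injury, "head_injury")

  ehr_events <- do.call(rbind, ehr[!vapply(ehr, is.null, logical(1))])
  rownames(ehr_events) <- NULL
  ehr_events$event_date <- pmin_date(ehr_events$event_date,
                                     rep(fu_end, nrow(ehr_events)))
  ehr_events <- ehr_events[order(ehr_events$id, ehr_events$event_date), ]

  participants <- data.frame(
    id = id, birth_ym = birth_ym, sex = sex, ethnicity = ethnicity,
    education = education, deprivation = deprivation, region = region,
    linked = linked, death_date = death_date, stringsAsFactors = FALSE
  )

  truth <- data.frame(
    id = id, h_latent = h_latent, true_hl = true_hl, true_onset = onset_date,
    recordable_onset = rec_onset, recorded_hl = recorded_hl,
    sin_level = sin_level, lambda_dementia = lambda_dem, ha_ever = ha_ever,
    ha_date = ha_date, dementia_date_control = dem_ctrl,
    dementia_date_treated = dem_trt,
    dementia_date_actual = dem_act, dementia_recorded = dem_recorded,
    stringsAsFactors = FALSE
  )

  out <- list(participants = participants, visits = visits,
              ehr_events = ehr_events, healthcare_counts = hc,
              truth = truth, config = config)
  class(out) <- "cohort_tables"
  out
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables>\n")
  cat(sprintf("  participants: %d\n", nrow(x$participants)))
  cat(sprintf("  visits: %d rows\n", nrow(x$visits)))
  cat(sprintf("  ehr_events: %d rows (%d classes)\n", nrow(x$ehr_events),
              length(unique(x$ehr_events$event_class))))
  cat(sprintf("  healthcare_counts: %d rows\n", nrow(x$healthcare_counts)))
  cat(sprintf("  follow-up ends: %s\n", format(x$config$followup_end)))
  invisible(x)
}
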