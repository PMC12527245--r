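## From raw cohort tables to an emulated trial.
##
## HL is ascertained from three sources (paired self-report questions, the
## SiN threshold, dated EHR codes) and dated at the earliest available
## source; the eligibility cascade and the complete-case filter produce one
## analysis row per eligible participant plus an exclusion ledger; arms are
## assigned by HA initiation within a grace period after time zero; and
## covariates are anchored to the assessment closest to time zero within a
## +/- 5-year window.

BASIC_COVARIATES <- c("age", "sex", "education", "deprivation", "ethnicity",
                      "region", "g", "sin", "tinnitus")

#' Canonical covariate sets
#'
#' `basic_covariates()` is the primary adjustment set (age, sex, education,
#' deprivation, ethnicity, region/EHR source, general cognition G, SiN
#' threshold, tinnitus history); `extra_covariates()` names the optional
#' additions used by the sensitivity battery.
#' @return character vector of covariate column names.
#' @export
basic_covariates <- function() BASIC_COVARIATES

#' @rdname basic_covariates
#' @export
extra_covariates <- function() {
  c("social_isolation", "mood", "head_injury", "hl_source",
    "hosp_cat", "gp_cat")
}

## normalize a self-report answer column; "do not know"/"prefer not to
## answer" are missing by convention
normalize_answers <- function(x, column) {
  x[is.na(x)] <- ""
  x[x %in% c("do not know", "prefer not to answer")] <- ""
  bad <- which(!x %in% c("yes", "no", ""))
  if (length(bad)) {
    stopf("malformed answer values in `%s` at rows: %s", column,
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  x
}

## first (minimum) date per id over a subset of rows, aligned to `ids`
first_date_by_id <- function(ids_universe, ids, dates) {
  out <- rep(NA_real_, length(ids_universe))
  keep <- !is.na(dates)
  ids <- ids[keep]; dates <- dates[keep]
  if (length(ids)) {
    agg <- tapply(as.numeric(dates), ids, min)
    pos <- match(as.numeric(names(agg)), ids_universe)
    ok <- !is.na(pos)
    out[pos[ok]] <- agg[ok]
  }
  as.Date(out, origin = "1970-01-01")
}

#' Ascertain hearing loss from all sources
#'
#' Applies the three-source rule: self-report HL requires both hearing
#' questions answered "yes" at the same visit (one "yes" plus one missing
#' makes the self-report source missing, not negative); SiN HL requires a
#' measured threshold at or above `sin_cutoff` (higher = poorer hearing);
#' EHR HL is the first HL-class event, missing if HL codes exist but carry
#' no date.  The overall HL date is the earliest available source date; a
#' tie is attributed to ehr, then sin_test, then self_report.
#'
#' @param tables a `cohort_tables` object.
#' @param sin_cutoff SiN threshold (dB) at or above which hearing is
#'   classified as impaired.
#' @return data.frame with one row per participant: per-source dates and
#'   missingness flags, overall `hl_date` and `source`.
#' @export
ascertain_hearing_loss <- function(tables, sin_cutoff = -5.5) {
  ids <- tables$participants$id
  v <- tables$visits
  q1 <- normalize_answers(v$sr_hearing_difficulty, "sr_hearing_difficulty")
  q2 <- normalize_answers(v$sr_background_noise, "sr_background_noise")

  both_yes <- q1 == "yes" & q2 == "yes"
  one_yes_one_missing <- (q1 == "yes" & q2 == "") | (q2 == "yes" & q1 == "")
  self_date <- first_date_by_id(ids, v$id[both_yes], v$visit_date[both_yes])
  has_ambiguous <- ids %in% v$id[one_yes_one_missing]
  self_missing <- is.na(self_date) & has_ambiguous

  measured <- !is.na(v$sin_db)
  sin_hit <- measured & v$sin_db >= sin_cutoff
  sin_date <- first_date_by_id(ids, v$id[sin_hit], v$visit_date[sin_hit])
  sin_missing <- !(ids %in% v$id[measured])

  e <- tables$ehr_events
  hl_rows <- e$event_class == "HL"
  ehr_date <- first_date_by_id(ids, e$id[hl_rows], e$event_date[hl_rows])
  has_undated_hl <- ids %in% e$id[hl_rows & is.na(e$event_date)]
  ehr_missing <- is.na(ehr_date) & has_undated_hl

  hl_date <- pmin_date(ehr_date, sin_date, self_date)
  ## argmin with fixed tie order ehr > sin_test > self_report
  source <- rep(NA_character_, length(ids))
  src_self <- !is.na(self_date) & !is.na(hl_date) & self_date == hl_date
  src_sin <- !is.na(sin_date) & !is.na(hl_date) & sin_date == hl_date
  src_ehr <- !is.na(ehr_date) & !is.na(hl_date) & ehr_date == hl_date
  source[src_self] <- "self_report"
  source[src_sin] <- "sin_test"
  source[src_ehr] <- "ehr"

  data.frame(id = ids, hl_date = hl_date, source = source,
             self_date = self_date, self_missing = self_missing,
             sin_date = sin_date, sin_missing = sin_missing,
             ehr_date = ehr_date, ehr_missing = ehr_missing,
             stringsAsFactors = FALSE)
}

#' Ascertain hearing-aid use and cochlear implants
#'
#' First HA date across self-reported use at visits and EHR HA codes;
#' cochlear-implant records are tracked separately because implant users at
#' confounder measurement are ineligible.
#'
#' @param tables a `cohort_tables` object.
#' @return data.frame: `id`, `ha_date`, `ha_source`, `implant`,
#'   `implant_date`, `cessation_date`.
#' @export
ascertain_ha_use <- function(tables) {
  ids <- tables$participants$id
  v <- tables$visits
  sr_ha <- normalize_answers(v$sr_ha_use %||% rep("", nrow(v)), "sr_ha_use")
  sr_imp <- normalize_answers(v$sr_cochlear_implant %||% rep("", nrow(v)),
                              "sr_cochlear_implant")
  self_date <- first_date_by_id(ids, v$id[sr_ha == "yes"],
                                v$visit_date[sr_ha == "yes"])
  e <- tables$ehr_events
  ehr_date <- first_date_by_id(ids, e$id[e$event_class == "HA"],
                               e$event_date[e$event_class == "HA"])
  imp_ehr <- first_date_by_id(ids, e$id[e$event_class == "implant"],
                              e$event_date[e$event_class == "implant"])
  imp_self <- first_date_by_id(ids, v$id[sr_imp == "yes"],
                               v$visit_date[sr_imp == "yes"])
  cess <- first_date_by_id(ids, e$id[e$event_class == "ha_cessation"],
                           e$event_date[e$event_class == "ha_cessation"])
  implant_date <- pmin_date(imp_ehr, imp_self)
  ha_date <- pmin_date(self_date, ehr_date, implant_date)
  ha_source <- ifelse(!is.na(ehr_date) & (is.na(self_date) | ehr_date <= self_date),
                      "ehr", ifelse(!is.na(self_date), "self_report", NA))
  data.frame(id = ids, ha_date = ha_date, ha_source = ha_source,
             implant = !is.na(implant_date), implant_date = implant_date,
             cessation_date = cess, stringsAsFactors = FALSE)
}

ELIGIBILITY_REASONS <- c("no_hl_date", "outcome_before_hl", "ha_before_hl",
                         "hl_before_baseline", "implant_at_baseline",
                         "no_followup", "missing_covariates")

#' Apply the eligibility cascade
#'
#' Excludes, in this fixed order: participants without an HL date; with a
#' dementia record at or before HL; with HA use strictly before HL; with HL
#' ascertained before their entry assessment (skipped when
#' `drop_prebaseline_rule = FALSE`, in which case pre-baseline HL/HA dates
#' are reset to the participant's entry date); with a cochlear implant at or
#' before time zero; and with time zero at or beyond the administrative end
#' of follow-up.  Each excluded id receives the first failing reason.
#'
#' @param hl output of [ascertain_hearing_loss()].
#' @param ha output of [ascertain_ha_use()].
#' @param tables the `cohort_tables`.
#' @param drop_prebaseline_rule exclude HL ascertained before the entry
#'   assessment (the primary analysis) or keep those participants with dates
#'   reset to study start (the sensitivity variant).
#' @param admin_end administrative censoring date; defaults to the
#'   generator's `followup_end`.
#' @param grace_years grace period that must be fully observable within
#'   follow-up: participants whose time zero leaves less than one grace
#'   period before `admin_end` cannot have their arm classified and are
#'   excluded (`no_followup`).
#' @return list with `skeleton` (one row per eligible id: time zero, HA and
#'   outcome dates) and `ledger` (id, reason).
#' @export
apply_eligibility <- function(hl, ha, tables, drop_prebaseline_rule = TRUE,
                              admin_end = NULL, grace_years = 1) {
  admin_end <- floor_month(as.Date(admin_end %||% tables$config$followup_end))
  ids <- tables$participants$id
  stopifnot(identical(hl$id, ids), identical(ha$id, ids))
  v <- tables$visits
  baseline_date <- first_date_by_id(ids, v$id, v$visit_date)
  e <- tables$ehr_events
  dem_date <- first_date_by_id(ids, e$id[e$event_class == "dementia"],
                               e$event_date[e$event_class == "dementia"])

  hl_date <- hl$hl_date
  ha_date <- ha$ha_date
  prebaseline <- !is.na(hl_date) & !is.na(baseline_date) &
    hl_date < baseline_date
  if (!drop_prebaseline_rule) {
    ## retained: dates of HL/HA reset to the date of study start
    hl_date[prebaseline] <- baseline_date[prebaseline]
    reset_ha <- prebaseline & !is.na(ha_date) & ha_date < baseline_date
    ha_date[reset_ha] <- baseline_date[reset_ha]
    prebaseline[] <- FALSE
  }

  reason <- rep(NA_character_, length(ids))
  flag <- function(cond, code) {
    hit <- is.na(reason) & cond & !is.na(cond)
    reason[hit] <<- code
  }
  flag(is.na(hl_date), "no_hl_date")
  flag(!is.na(dem_date) & dem_date <= hl_date, "outcome_before_hl")
  flag(!is.na(ha_date) & ha_date < hl_date, "ha_before_hl")
  flag(prebaseline, "hl_before_baseline")
  flag(ha$implant & !is.na(ha$implant_date) & ha$implant_date <= hl_date,
       "implant_at_baseline")
  ## the full grace period must fit inside follow-up, otherwise arm
  ## assignment is truncated differentially by entry date
  flag(add_months(hl_date, years_to_months(grace_years)) >= admin_end,
       "no_followup")

  keep <- is.na(reason)
  death_date <- tables$participants$death_date
  skeleton <- data.frame(
    id = ids[keep], time_zero = hl_date[keep], hl_source = hl$source[keep],
    ha_date = ha_date[keep], cessation_date = ha$cessation_date[keep],
    outcome_date = dem_date[keep], death_date = death_date[keep],
    baseline_date = baseline_date[keep],
    admin_end = rep(admin_end, sum(keep)),
    stringsAsFactors = FALSE
  )
  ledger <- data.frame(id = ids[!keep], reason = reason[!keep],
                       stringsAsFactors = FALSE)
  list(skeleton = skeleton, ledger = ledger)
}

#' Assign treatment arms and construct follow-up
#'
#' A participant is in the HA arm iff the first HA record falls within the
#' grace period after time zero.  Intention-to-treat follow-up runs to the
#' earliest of dementia, death and administrative end; the per-protocol
#' analogue additionally censors control rows at late HA initiation and HA
#' rows at recorded cessation.  Outcome events after a per-protocol censoring
#' date do not count.
#'
#' @param skeleton the `skeleton` element from [apply_eligibility()].
#' @param grace_years length of the grace period (years, > 0).
#' @param contrast `"itt"` or `"per_protocol"`.
#' @return the skeleton with `arm`, `followup_end`, `followup_years`,
#'   `outcome_event`, `death_event` and `pp_censor_date` columns.
#' @export
assign_arms_and_followup <- function(skeleton, grace_years = 1,
                                     contrast = c("itt", "per_protocol")) {
  contrast <- match.arg(contrast)
  if (!is.numeric(grace_years) || length(grace_years) != 1 ||
      is.na(grace_years) || grace_years <= 0) {
    stopf("`grace_years` must be a single positive number")
  }
  s <- skeleton
  grace_end <- if (is.finite(grace_years)) {
    add_months(s$time_zero, years_to_months(grace_years))
  } else {
    rep(as.Date("9999-12-01"), nrow(s))
  }
  arm <- ifelse(!is.na(s$ha_date) & s$ha_date <= grace_end, "HA", "control")

  fu_itt <- pmin_date(s$outcome_date, s$death_date,
                      rep(s$admin_end[1] %||% s$admin_end, nrow(s)))
  pp_censor <- as.Date(rep(NA_real_, nrow(s)), origin = "1970-01-01")
  late_ha <- arm == "control" & !is.na(s$ha_date)
  pp_censor[late_ha] <- s$ha_date[late_ha]
  cess <- arm == "HA" & !is.na(s$cessation_date)
  pp_censor[cess] <- s$cessation_date[cess]

  fu_end <- if (contrast == "itt") fu_itt else pmin_date(fu_itt, pp_censor)
  outcome_event <- !is.na(s$outcome_date) & s$outcome_date <= fu_end &
    s$outcome_date > s$time_zero
  death_event <- !outcome_event & !is.na(s$death_date) & s$death_date <= fu_end

  s$arm <- arm
  s$grace_end <- grace_end
  s$followup_end <- fu_end
  s$followup_years <- pmax(years_between(s$time_zero, fu_end), 0)
  s$outcome_event <- outcome_event
  s$death_event <- death_event
  s$pp_censor_date <- pp_censor
  s$contrast <- rep(contrast, nrow(s))
  s
}

## nearest non-missing visit value per field, within the anchoring window
nearest_visit_value <- function(trial_id, time_zero, visits, value_col,
                                window_months) {
  ok <- !is.na(visits[[value_col]])
  v <- visits[ok, c("id", "visit_date", value_col)]
  pos <- match(v$id, trial_id)
  inrange <- !is.na(pos)
  v <- v[inrange, ]; pos <- pos[inrange]
  dist <- abs(months_between(time_zero[pos], v$visit_date))
  keep <- dist <= window_months
  v <- v[keep, ]; pos <- pos[keep]; dist <- dist[keep]
  ord <- order(pos, dist, v$visit_date)
  v <- v[ord, ]; pos <- pos[ord]
  first <- !duplicated(pos)
  val <- rep(if (is.numeric(v[[value_col]])) NA_real_ else NA, length(trial_id))
  val[pos[first]] <- v[[value_col]][first]
  date <- as.Date(rep(NA_real_, length(trial_id)), origin = "1970-01-01")
  date[pos[first]] <- v$visit_date[first]
  list(value = val, visit_date = date)
}

#' Measure baseline covariates
#'
#' Visit-measured fields (G, SiN, social isolation) are taken from the visit
#' closest in time to time zero at which the field was recorded, ties broken
#' toward the earlier visit; fields farther than `window_years` from time
#' zero are missing.  History covariates (tinnitus, mood disorder, head
#' injury) are flags for any EHR record at or before time zero.
#' Healthcare-use categories come from [categorize_healthcare_use()] over the
#' window before time zero.
#'
#' @param trial output of [assign_arms_and_followup()].
#' @param tables the `cohort_tables`.
#' @param window_years covariate anchoring half-window (years).
#' @return `trial` with covariate columns and `cov_visit_date` /
#'   `cov_after_tz` bookkeeping added.
#' @export
measure_covariates <- function(trial, tables, window_years = 5) {
  p <- tables$participants
  i <- match(trial$id, p$id)
  wm <- years_to_months(window_years)
  trial$age <- years_between(p$birth_ym[i], trial$time_zero)
  trial$sex <- p$sex[i]
  trial$education <- p$education[i]
  trial$deprivation <- p$deprivation[i]
  trial$ethnicity <- p$ethnicity[i]
  trial$region <- p$region[i]
  trial$linked <- p$linked[i]

  g <- nearest_visit_value(trial$id, trial$time_zero, tables$visits,
                           "g_score", wm)
  s <- nearest_visit_value(trial$id, trial$time_zero, tables$visits,
                           "sin_db", wm)
  iso <- nearest_visit_value(trial$id, trial$time_zero, tables$visits,
                             "social_isolation", wm)
  trial$g <- g$value
  trial$sin <- s$value
  trial$social_isolation <- as.logical(iso$value)
  trial$cov_visit_date <- pmin_date(g$visit_date, s$visit_date)
  after <- function(d) !is.na(d) & d > trial$time_zero
  trial$cov_after_tz <- after(g$visit_date) | after(s$visit_date)

  e <- tables$ehr_events
  hist_flag <- function(class) {
    d <- first_date_by_id(trial$id, e$id[e$event_class == class],
                          e$event_date[e$event_class == class])
    !is.na(d) & d <= trial$time_zero
  }
  trial$tinnitus <- hist_flag("tinnitus")
  trial$mood <- hist_flag("mood")
  trial$head_injury <- hist_flag("head_injury")

  hc <- categorize_healthcare_use(tables$healthcare_counts, trial$id,
                                  trial$time_zero, window_years = 5,
                                  side = "pre")
  trial$hosp_cat <- hc$hosp_cat
  trial$gp_cat <- hc$gp_cat
  trial
}

HOSP_CAT_LEVELS <- c("0", "(0,0.2]", "(0.2,0.5]", ">0.5")
GP_CAT_LEVELS <- c("[0,12]", "(12,24]", ">24")

#' Categorize healthcare use around time zero
#'
#' Mean annual hospital spells over the window map to four categories
#' (0, (0,0.2], (0.2,0.5], >0.5); mean annual unique primary-care events map
#' to three ([0,12], (12,24], >24).  The `pre` side uses the `window_years`
#' calendar years strictly before the year of time zero; `post` the years
#' strictly after.
#'
#' @param counts the `healthcare_counts` table (id, year, gp_events,
#'   hospital_spells).
#' @param ids participant ids to score.
#' @param time_zero Date vector aligned with `ids`.
#' @param window_years window length in years.
#' @param side `"pre"` or `"post"`.
#' @return data.frame with `hosp_cat` and `gp_cat` factors (`gp_cat` is NA
#'   when no primary-care data fall in the window).
#' @export
categorize_healthcare_use <- function(counts, ids, time_zero,
                                      window_years = 5,
                                      side = c("pre", "post")) {
  side <- match.arg(side)
  if (!length(ids)) {
    return(data.frame(hosp_cat = factor(character(), HOSP_CAT_LEVELS),
                      gp_cat = factor(character(), GP_CAT_LEVELS)))
  }
  if (nrow(counts) &&
      (any(counts$hospital_spells < 0, na.rm = TRUE) ||
       any(counts$gp_events < 0, na.rm = TRUE))) {
    stopf("negative counts in healthcare_counts table")
  }
  tz_year <- date_year(time_zero)
  pos <- match(counts$id, ids)
  ok <- !is.na(pos)
  yr <- counts$year[ok]; pos <- pos[ok]
  hosp <- counts$hospital_spells[ok]; gp <- counts$gp_events[ok]
  inwin <- if (side == "pre") {
    yr >= tz_year[pos] - window_years & yr <= tz_year[pos] - 1L
  } else {
    yr >= tz_year[pos] + 1L & yr <= tz_year[pos] + window_years
  }
  mean_by <- function(x, p, keep) {
    p <- p[keep]; x <- x[keep]
    has <- !is.na(x)
    s <- rep(0, length(ids)); k <- rep(0L, length(ids))
    if (any(has)) {
      agg_s <- tapply(x[has], p[has], sum)
      agg_k <- tapply(rep(1L, sum(has)), p[has], sum)
      s[as.integer(names(agg_s))] <- agg_s
      k[as.integer(names(agg_k))] <- agg_k
    }
    ifelse(k > 0, s / k, NA_real_)
  }
  mean_hosp <- mean_by(hosp, pos, inwin)
  mean_gp <- mean_by(gp, pos, inwin)
  hosp_cat <- cut(mean_hosp, c(-Inf, 0, 0.2, 0.5, Inf),
                  labels = HOSP_CAT_LEVELS)
  gp_cat <- cut(mean_gp, c(-Inf, 12, 24, Inf), labels = GP_CAT_LEVELS)
  data.frame(hosp_cat = hosp_cat, gp_cat = gp_cat)
}

#' Emulate the target trial end to end
#'
#' Runs ascertainment, eligibility, arm assignment (both contrasts),
#' covariate measurement and the complete-case filter, and returns the
#' analysis table plus the exclusion ledger.  Every generated participant
#' appears exactly once: as an analysis row or as one ledger entry.
#'
#' @param tables a `cohort_tables` object.
#' @param sin_cutoff SiN HL cutoff (dB).
#' @param grace_years grace period (years).
#' @param drop_prebaseline_rule see [apply_eligibility()].
#' @param admin_end administrative censoring date.
#' @param window_years covariate anchoring half-window (years).
#' @param required_covariates covariates whose missingness triggers the
#'   complete-case exclusion.
#' @return list of class `emulated_trial` with elements `trial` (data.frame,
#'   ITT and per-protocol follow-up columns side by side) and `ledger`.
#' @export
emulate_trial <- function(tables, sin_cutoff = -5.5, grace_years = 1,
                          drop_prebaseline_rule = TRUE, admin_end = NULL,
                          window_years = 5,
                          required_covariates = basic_covariates()) {
  hl <- ascertain_hearing_loss(tables, sin_cutoff = sin_cutoff)
  ha <- ascertain_ha_use(tables)
  elig <- apply_eligibility(hl, ha, tables,
                            drop_prebaseline_rule = drop_prebaseline_rule,
                            admin_end = admin_end, grace_years = grace_years)
  itt <- assign_arms_and_followup(elig$skeleton, grace_years = grace_years,
                                  contrast = "itt")
  pp <- assign_arms_and_followup(elig$skeleton, grace_years = grace_years,
                                 contrast = "per_protocol")
  trial <- itt
  names(trial)[names(trial) == "followup_end"] <- "fu_end_itt"
  names(trial)[names(trial) == "followup_years"] <- "fu_years_itt"
  names(trial)[names(trial) == "outcome_event"] <- "event_itt"
  trial$contrast <- NULL
  trial$fu_end_pp <- pp$followup_end
  trial$fu_years_pp <- pp$followup_years
  trial$event_pp <- pp$outcome_event
  trial$pp_censor_date <- pp$pp_censor_date

  trial <- measure_covariates(trial, tables, window_years = window_years)

  miss <- Reduce(`|`, lapply(required_covariates,
                             function(cl) is.na(trial[[cl]])))
  ledger <- elig$ledger
  if (any(miss)) {
    ledger <- rbind(ledger, data.frame(id = trial$id[miss],
                                       reason = "missing_covariates",
                                       stringsAsFactors = FALSE))
    trial <- trial[!miss, ]
  }
  rownames(trial) <- NULL
  out <- list(trial = trial, ledger = ledger,
              n_generated = nrow(tables$participants))
  class(out) <- "emulated_trial"
  out
}

#' @export
print.emulated_trial <- function(x, ...) {
  cat("<emulated_trial>\n")
  cat(sprintf("  analysis rows: %d (HA %d / control %d)\n", nrow(x$trial),
              sum(x$trial$arm == "HA"), sum(x$trial$arm == "control")))
  cat(sprintf("  ITT events: %d; per-protocol events: %d\n",
              sum(x$trial$event_itt), sum(x$trial$event_pp)))
  if (nrow(x$ledger)) {
    tab <- table(x$ledger$reason)
    cat("  exclusions:\n")
    for (nm in names(tab)) cat(sprintf("    %-20s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Summarize the exclusion ledger
#' @param ledger the `ledger` element of an [emulate_trial()] result.
#' @return data.frame of reason codes and counts, in cascade order.
#' @export
ledger_counts <- function(ledger) {
  tab <- table(factor(ledger$reason, levels = ELIGIBILITY_REASONS))
  data.frame(reason = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
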