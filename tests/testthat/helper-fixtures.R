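# Hand-built cohort fixtures, assembled in code.

p_row <- function(id, birth = "1950-01-01", sex = "F", ethnicity = "White",
                  education = "higher", deprivation = 0, region = "England",
                  linked = TRUE, death = NA) {
  data.frame(id = id, birth_ym = as.Date(birth), sex = sex,
             ethnicity = ethnicity, education = education,
             deprivation = deprivation, region = region, linked = linked,
             death_date = as.Date(death), stringsAsFactors = FALSE)
}

v_row <- function(id, date, sin = NA_real_, q1 = "no", q2 = "no", g = 0,
                  iso = FALSE, ha = "no", implant = "no") {
  data.frame(id = id, visit_date = as.Date(date), sin_db = sin,
             sr_hearing_difficulty = q1, sr_background_noise = q2,
             g_score = g, social_isolation = iso, sr_ha_use = ha,
             sr_cochlear_implant = implant, stringsAsFactors = FALSE)
}

e_row <- function(id, date, class, source = "inpatient") {
  data.frame(id = id, event_date = as.Date(date), event_class = class,
             source = source, stringsAsFactors = FALSE)
}

hc_rows <- function(id, years, gp = 0L, hosp = 0L) {
  data.frame(id = id, year = years, gp_events = as.integer(gp),
             hospital_spells = as.integer(hosp), stringsAsFactors = FALSE)
}

mini_tables <- function(participants, visits = NULL, ehr_events = NULL,
                        healthcare_counts = NULL,
                        followup_end = "2022-12-01") {
  empty <- hatrial:::empty_cohort_tables(
    generator_config(n_participants = 0, followup_end = followup_end)
  )
  out <- empty
  out$participants <- participants
  if (!is.null(visits)) out$visits <- visits
  if (!is.null(ehr_events)) out$ehr_events <- ehr_events
  if (!is.null(healthcare_counts)) out$healthcare_counts <- healthcare_counts
  out
}

unit_adjustment <- function(n, name = "unit", ps = rep(0.5, n)) {
  hatrial:::new_adjustment(name, rep(1, n), rep(FALSE, n), ps)
}

# a small simulated analysis table that skips the emulation machinery:
# one continuous confounder, logistic treatment, binary outcome
sim_trial <- function(n, seed = 1, b_arm_g = 0, b_y_g = 0, b_y_arm = 0,
                      p_arm = 0.2, p_y = 0.1) {
  set.seed(seed)
  g <- rnorm(n)
  arm <- ifelse(runif(n) < plogis(qlogis(p_arm) + b_arm_g * g), "HA", "control")
  y <- runif(n) < plogis(qlogis(p_y) + b_y_g * g + b_y_arm * (arm == "HA"))
  data.frame(arm = arm, g = g, event_itt = y, event_pp = y,
             fu_years_itt = rep(10, n), fu_years_pp = rep(10, n),
             stringsAsFactors = FALSE)
}

# brute-force standardization oracle: average cell risks over the target
# distribution of the (categorical) covariate
enum_standardized_rr <- function(df, covariate = "l") {
  lev <- sort(unique(df[[covariate]]))
  p_target <- prop.table(table(factor(df[[covariate]][df$arm == "HA"], lev)))
  risk <- function(arm_val, l_val) {
    sel <- df$arm == arm_val & df[[covariate]] == l_val
    mean(df$event_itt[sel])
  }
  mu1 <- sum(sapply(lev, function(l) p_target[[as.character(l)]] * risk("HA", l)))
  mu0 <- sum(sapply(lev, function(l) p_target[[as.character(l)]] * risk("control", l)))
  mu1 / mu0
}

make_toy_2x2x2 <- function() {
  # printed toy: P(L=1) = 0.5 in the target; risks 10/100 vs 5/100 (L=0),
  # 30/100 vs 20/100 (L=1)
  counts <- list(c("HA", 0, 10), c("control", 0, 5),
                 c("HA", 1, 30), c("control", 1, 20))
  do.call(rbind, lapply(counts, function(z) {
    data.frame(arm = z[1], l = as.numeric(z[2]),
               event_itt = c(rep(TRUE, as.numeric(z[3])),
                             rep(FALSE, 100 - as.numeric(z[3]))),
               stringsAsFactors = FALSE)
  }))
}

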