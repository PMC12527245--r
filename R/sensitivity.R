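## Sensitivity battery: E-values, negative outcome controls, extra-adjustment
## model grid, combined covariate effect via standardized propensity scores,
## and pre/post-randomization healthcare-use analyses.

#' E-value for an observed risk ratio
#'
#' Minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both treatment and outcome to shift
#' the observed risk ratio to a candidate true value: with
#' `R = max(observed/true, true/observed)`, `E = R + sqrt(R * (R - 1))`.
#'
#' @param observed_rr observed risk ratio (> 0).
#' @param true_rr candidate true risk ratio (> 0); default 1 (full
#'   explaining-away).
#' @return list of class `evalue_result`: `observed_rr`, `true_rr`,
#'   `evalue` (>= 1; exactly 1 when the two ratios coincide).
#' @export
evalue <- function(observed_rr, true_rr = 1.0) {
  if (!is.numeric(observed_rr) || length(observed_rr) != 1 ||
      is.na(observed_rr) || observed_rr <= 0 ||
      !is.numeric(true_rr) || length(true_rr) != 1 ||
      is.na(true_rr) || true_rr <= 0) {
    stopf("`observed_rr` and `true_rr` must be single positive numbers")
  }
  r <- max(observed_rr / true_rr, true_rr / observed_rr)
  e <- r + sqrt(r * (r - 1))
  out <- list(observed_rr = observed_rr, true_rr = true_rr, evalue = e)
  class(out) <- "evalue_result"
  out
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("E-value %.2f (observed RR %.2f vs candidate true RR %.2f)\n",
              x$evalue, x$observed_rr, x$true_rr))
  invisible(x)
}

## One basic-ITT pipeline pass: propensity -> candidate adjustments ->
## balance selection -> doubly robust RR.  Shared by every grid variant.
pipeline_estimate <- function(trial, covariates = basic_covariates(),
                              contrast = "itt", smd_threshold = 0.1,
                              estimand = "ATT", match_seed = 1L,
                              adjustment_methods = c("att_ipw", "nn_match",
                                                     "stabilized")) {
  ps <- fit_propensity(trial, covariates)
  adjs <- make_adjustments(trial, ps, estimand = estimand,
                           match_seed = match_seed,
                           methods = adjustment_methods)
  adj <- select_adjustment(adjs, trial = trial, covariates = covariates,
                           smd_threshold = smd_threshold)
  est <- dr_risk_ratio(trial, adj, covariates = covariates,
                       contrast = contrast)
  list(estimate = est, adjustment = adj, propensity = ps,
       report = attr(adj, "report"))
}

not_estimable <- function(measure, contrast, note) {
  new_effect_estimate(measure, NA_real_, NA_real_,
                      c(HA = NA_integer_, control = NA_integer_),
                      c(HA = NA_integer_, control = NA_integer_),
                      contrast, NA_character_, note = note)
}

## swap the dementia outcome for a control-condition outcome, excluding rows
## with a control event on or before time zero
control_outcome_trial <- function(trial, tables, class, admin_end = NULL) {
  admin_end <- floor_month(as.Date(admin_end %||% tables$config$followup_end))
  e <- tables$ehr_events
  d <- first_date_by_id(trial$id, e$id[e$event_class == class],
                        e$event_date[e$event_class == class])
  keep <- is.na(d) | d > trial$time_zero
  t2 <- trial[keep, , drop = FALSE]
  d <- d[keep]
  fu <- pmin_date(d, t2$death_date, rep(admin_end, nrow(t2)))
  t2$event_itt <- !is.na(d) & d <= fu
  t2$fu_end_itt <- fu
  t2$fu_years_itt <- pmax(years_between(t2$time_zero, fu), 0)
  t2
}

#' Negative-outcome-control battery
#'
#' Reruns the basic intention-to-treat pipeline once per control condition
#' (influenza, liver disease, lower-respiratory disease, asthma, skin
#' disorders, infectious/parasitic disease, appendicitis, hip fracture,
#' transport accidents by default), each time excluding participants with a
#' control-condition record before time zero and re-fitting propensity,
#' weights and outcome model.
#'
#' @param trial analysis table (ITT columns are replaced per outcome).
#' @param tables the `cohort_tables` the trial came from.
#' @param classes control outcome classes.
#' @param covariates adjustment set.
#' @param smd_threshold balance-selection threshold.
#' @return named list of `effect_estimate`s (`negative_control:<class>`),
#'   each flagged `ci_excludes_1`; absent classes yield not-estimable rows.
#' @export
negative_control_battery <- function(trial, tables,
                                     classes = NEG_CONTROL_CLASSES,
                                     covariates = basic_covariates(),
                                     smd_threshold = 0.1) {
  out <- list()
  for (cl in classes) {
    nm <- paste0("negative_control:", cl)
    if (!cl %in% tables$ehr_events$event_class) {
      out[[nm]] <- not_estimable("RR", "itt",
                                 sprintf("outcome class '%s' absent", cl))
      next
    }
    out[[nm]] <- tryCatch({
      t2 <- control_outcome_trial(trial, tables, cl)
      est <- pipeline_estimate(t2, covariates = covariates,
                               smd_threshold = smd_threshold)$estimate
      est$ci_excludes_1 <- est$ci_lower > 1 || est$ci_upper < 1
      est
    }, error = function(e) {
      not_estimable("RR", "itt", conditionMessage(e))
    })
  }
  out
}

#' Combined effect of all covariates via standardized propensity scores
#'
#' Z-standardizes the propensity scores, regresses the outcome on the
#' standardized score within each arm stratum (modified Poisson with robust
#' SE, so the coefficient is a log risk ratio per SD), and pools the
#' strata by inverse-variance weighting.
#'
#' @param trial analysis table.
#' @param propensity `propensity_fit` or numeric scores.
#' @param contrast `"itt"` or `"per_protocol"`.
#' @return an `effect_estimate` (RR per 1-SD increase in the score).
#' @export
combined_covariate_effect <- function(trial, propensity,
                                      contrast = c("itt", "per_protocol")) {
  contrast <- match.arg(contrast)
  p <- if (inherits(propensity, "propensity_fit")) propensity$scores else propensity
  if (stats::sd(p) == 0) {
    return(not_estimable("RR", contrast, "constant propensity scores"))
  }
  z <- (p - mean(p)) / stats::sd(p)
  y <- as.numeric(trial[[outcome_column(contrast)]])
  est <- se2 <- numeric(0)
  for (lv in c("control", "HA")) {
    sel <- trial$arm == lv
    if (sum(y[sel]) == 0 || stats::sd(z[sel]) == 0) next
    fit <- suppressWarnings(stats::glm(y[sel] ~ z[sel], family = stats::poisson()))
    v <- sandwich::sandwich(fit)[2, 2]
    est <- c(est, stats::coef(fit)[2])
    se2 <- c(se2, v)
  }
  if (!length(est)) {
    return(not_estimable("RR", contrast, "no stratum estimable"))
  }
  wts <- 1 / se2
  log_rr <- sum(wts * est) / sum(wts)
  log_se <- sqrt(1 / sum(wts))
  a <- arm_indicator(trial)
  new_effect_estimate("RR", exp(log_rr), log_se,
                      c(HA = sum(a == 1), control = sum(a == 0)),
                      c(HA = sum(y[a == 1]), control = sum(y[a == 0])),
                      contrast, "normalized_ps")
}

## closed-form risk ratio for a 2x2 split with log-scale SE
rr_2x2 <- function(x1, n1, x0, n0, label, contrast = "itt",
                   adjustment = "crude") {
  if (n1 == 0 || n0 == 0 || x1 == 0 || x0 == 0) {
    return(not_estimable("RR", contrast,
                         sprintf("%s: empty cell", label)))
  }
  rr <- (x1 / n1) / (x0 / n0)
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
  new_effect_estimate("RR", rr, se, c(HA = n1, control = n0),
                      c(HA = x1, control = x0), contrast, adjustment)
}

#' Healthcare-use analyses around randomization
#'
#' (a) Risk of the outcome by pre-randomization healthcare-use category
#' (each category vs the lowest), for hospital spells and primary-care
#' events; (b) effect of HA-arm assignment on post-randomization
#' healthcare-use category membership, one pairwise contrast per
#' non-reference category.
#'
#' @param trial analysis table (with `hosp_cat` / `gp_cat` pre-randomization
#'   columns).
#' @param tables the `cohort_tables` (for post-randomization counts).
#' @param window_years window for the post-randomization categories.
#' @return named list of `effect_estimate`s.
#' @export
healthcare_use_analyses <- function(trial, tables, window_years = 5) {
  out <- list()
  y <- as.numeric(trial$event_itt)
  for (var in c("hosp_cat", "gp_cat")) {
    lev <- levels(as_covariate_frame(trial, var)[[var]])
    x <- as.character(trial[[var]])
    ref <- lev[1]
    for (l in lev[-1]) {
      nm <- sprintf("dementia_by_pre_%s:%s", var, l)
      sel1 <- !is.na(x) & x == l
      sel0 <- !is.na(x) & x == ref
      out[[nm]] <- rr_2x2(sum(y[sel1]), sum(sel1), sum(y[sel0]), sum(sel0),
                          nm)
    }
  }
  post <- categorize_healthcare_use(tables$healthcare_counts, trial$id,
                                    trial$time_zero,
                                    window_years = window_years,
                                    side = "post")
  a <- arm_indicator(trial)
  for (var in c("hosp_cat", "gp_cat")) {
    lev <- levels(post[[var]])
    x <- as.character(post[[var]])
    ref <- lev[1]
    for (l in lev[-1]) {
      nm <- sprintf("ha_on_post_%s:%s", var, l)
      sub <- !is.na(x) & x %in% c(ref, l)
      inl <- as.numeric(x == l)
      out[[nm]] <- rr_2x2(sum(inl[sub & a == 1]), sum(sub & a == 1),
                          sum(inl[sub & a == 0]), sum(sub & a == 0), nm)
    }
  }
  out
}

DEMENTIA_VARIANTS <- c("basic_itt", "basic_pp", "no_grace_censoring",
                       "covariates_before_tz_only", "extra_social_mood",
                       "extra_head_injury", "extra_hl_source",
                       "extra_hospital", "extra_primary_care", "extra_both",
                       "drop_prebaseline_variant")

variant_type <- function(v) {
  if (grepl("^negative_control:", v)) return("neg. control")
  switch(v,
         basic_itt = , basic_pp = "basic",
         no_grace_censoring = , covariates_before_tz_only = ,
         drop_prebaseline_variant = "sample change",
         "extra adjust.")
}

#' Run the full sensitivity grid
#'
#' Executes every requested model variant on one cohort: the basic
#' intention-to-treat and per-protocol models, the sample-change variants
#' (no grace-period censoring, covariates measured before time zero only,
#' pre-baseline HL retained with dates reset), the extra-adjustment variants
#' (each re-runs propensity fitting, weighting, balance selection and
#' estimation with the enlarged covariate set), and the negative outcome
#' controls.  All variants except `basic_pp` are intention-to-treat.
#'
#' @param scenario list: either `tables` (a `cohort_tables`), `input_path`
#'   (a [write_cohort()] directory) or `preset` (a [scenario_library()]
#'   name, with `n_participants` and `seed`); optional `grace_years`,
#'   `sin_cutoff`, `smd_threshold`, `variants`, `control_classes`.
#' @return data.frame of class `sensitivity_grid`: variant, type, measure,
#'   point, lower, upper, arm sizes, event counts, adjustment, and the
#'   config delta that produced each row.
#' @export
run_sensitivity_grid <- function(scenario) {
  sc <- scenario
  tables <- if (!is.null(sc$tables)) {
    sc$tables
  } else if (!is.null(sc$input_path)) {
    read_cohort(sc$input_path)
  } else if (!is.null(sc$preset)) {
    generate_cohort(scenario_library(sc$preset,
                                     n_participants = sc$n_participants %||% 10000,
                                     seed = sc$seed %||% 1L))
  } else {
    stopf("scenario must name `tables`, `input_path` or `preset`")
  }
  grace <- sc$grace_years %||% 1
  cutoff <- sc$sin_cutoff %||% -5.5
  thr <- sc$smd_threshold %||% 0.1
  variants <- sc$variants %||% c(DEMENTIA_VARIANTS,
                                 paste0("negative_control:",
                                        sc$control_classes %||% NEG_CONTROL_CLASSES))
  unknown <- setdiff(variants[!grepl("^negative_control:", variants)],
                     DEMENTIA_VARIANTS)
  if (length(unknown)) {
    stopf("unknown sensitivity variant(s): %s", paste(unknown, collapse = ", "))
  }

  em <- emulate_trial(tables, sin_cutoff = cutoff, grace_years = grace)
  trial <- em$trial

  run1 <- function(tr, covs, contrast = "itt") {
    tryCatch(pipeline_estimate(tr, covariates = covs, contrast = contrast,
                               smd_threshold = thr)$estimate,
             error = function(e) not_estimable("RR", contrast,
                                               conditionMessage(e)))
  }
  complete_on <- function(tr, covs) {
    miss <- Reduce(`|`, lapply(covs, function(cl) is.na(tr[[cl]])))
    tr[!miss, , drop = FALSE]
  }

  results <- list()
  delta <- character(0)
  for (v in variants) {
    if (grepl("^negative_control:", v)) next
    results[[v]] <- switch(
      v,
      basic_itt = run1(trial, basic_covariates(), "itt"),
      basic_pp = run1(trial, basic_covariates(), "per_protocol"),
      no_grace_censoring = {
        cens <- (!is.na(trial$outcome_date) &
                   trial$outcome_date <= trial$grace_end) |
          (!is.na(trial$death_date) & trial$death_date <= trial$grace_end)
        run1(trial[!cens, , drop = FALSE], basic_covariates())
      },
      covariates_before_tz_only =
        run1(trial[!trial$cov_after_tz, , drop = FALSE], basic_covariates()),
      extra_social_mood = {
        covs <- c(basic_covariates(), "social_isolation", "mood")
        run1(complete_on(trial, covs), covs)
      },
      extra_head_injury = {
        covs <- c(basic_covariates(), "head_injury")
        run1(complete_on(trial, covs), covs)
      },
      extra_hl_source = {
        covs <- c(basic_covariates(), "hl_source")
        run1(complete_on(trial, covs), covs)
      },
      extra_hospital = {
        covs <- c(basic_covariates(), "hosp_cat")
        run1(complete_on(trial, covs), covs)
      },
      extra_primary_care = {
        covs <- c(basic_covariates(), "gp_cat")
        run1(complete_on(trial, covs), covs)
      },
      extra_both = {
        covs <- c(basic_covariates(), "hosp_cat", "gp_cat")
        run1(complete_on(trial, covs), covs)
      },
      drop_prebaseline_variant = {
        em2 <- emulate_trial(tables, sin_cutoff = cutoff, grace_years = grace,
                             drop_prebaseline_rule = FALSE)
        run1(em2$trial, basic_covariates())
      }
    )
    delta[v] <- switch(
      v,
      basic_itt = "none",
      basic_pp = "contrast=per_protocol",
      no_grace_censoring = "drop rows censored in grace period",
      covariates_before_tz_only = "drop rows with covariate visit after time zero",
      extra_social_mood = "+social_isolation +mood",
      extra_head_injury = "+head_injury",
      extra_hl_source = "+hl_source",
      extra_hospital = "+hosp_cat",
      extra_primary_care = "+gp_cat (primary-care subsample)",
      extra_both = "+hosp_cat +gp_cat (primary-care subsample)",
      drop_prebaseline_variant = "drop_prebaseline_rule=FALSE"
    )
  }

  nc_classes <- sub("^negative_control:", "",
                    grep("^negative_control:", variants, value = TRUE))
  if (length(nc_classes)) {
    nc <- negative_control_battery(trial, tables, classes = nc_classes,
                                   smd_threshold = thr)
    for (nm in names(nc)) {
      results[[nm]] <- nc[[nm]]
      delta[nm] <- paste0("outcome=", sub("^negative_control:", "", nm))
    }
  }

  grid <- do.call(rbind, lapply(names(results), function(nm) {
    e <- results[[nm]]
    data.frame(variant = nm, type = variant_type(nm), measure = e$measure,
               point = e$point, lower = e$ci_lower, upper = e$ci_upper,
               n_treated = e$n_treated, n_control = e$n_control,
               events_treated = e$events_treated,
               events_control = e$events_control,
               adjustment = e$adjustment, config_delta = delta[nm],
               note = e$note, stringsAsFactors = FALSE)
  }))
  rownames(grid) <- NULL
  class(grid) <- c("sensitivity_grid", "data.frame")
  attr(grid, "ledger") <- em$ledger
  grid
}
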