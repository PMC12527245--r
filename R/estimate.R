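## Causal contrasts: doubly robust marginal risk ratio, weighted
## Kaplan-Meier curves, weighted Cox hazard ratios.
##
## The risk ratio combines the exposure model (through the adjustment's
## inverse-probability weights) with an outcome regression: a weighted
## logistic model of the event on arm + covariates, standardized
## (g-computation) over the target population -- the treated rows under the
## ATT estimand.  The variance treats the weights as fixed and stacks the
## outcome-model score with the two standardization means in one
## M-estimation sandwich; a bootstrap mode that refits the propensity model
## per resample is available as a cross-check.

new_effect_estimate <- function(measure, point, log_se, n_arm, events_arm,
                                contrast, adjustment_name, note = NA_character_) {
  lo <- if (is.na(point)) NA_real_ else exp(log(point) - 1.96 * log_se)
  hi <- if (is.na(point)) NA_real_ else exp(log(point) + 1.96 * log_se)
  out <- list(measure = measure, point = point, log_se = log_se,
              ci_lower = lo, ci_upper = hi,
              n_treated = n_arm[["HA"]], n_control = n_arm[["control"]],
              events_treated = events_arm[["HA"]],
              events_control = events_arm[["control"]],
              contrast = contrast, adjustment = adjustment_name, note = note)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (is.na(x$point)) {
    cat(sprintf("<effect_estimate> %s (%s): not estimable (%s)\n",
                x$measure, x$contrast, x$note))
  } else {
    cat(sprintf("<effect_estimate> %s = %.3f (95%% CI %.3f-%.3f), %s, %s\n",
                x$measure, x$point, x$ci_lower, x$ci_upper, x$contrast,
                x$adjustment))
    cat(sprintf("  n: %d HA / %d control; events: %d / %d\n", x$n_treated,
                x$n_control, x$events_treated, x$events_control))
  }
  invisible(x)
}

outcome_column <- function(contrast) {
  switch(contrast, itt = "event_itt", per_protocol = "event_pp",
         stopf("unknown contrast '%s'", contrast))
}

## outcome-model design: [intercept, arm, X] or, with treatment-covariate
## interactions (the saturated g-computation form), [intercept, arm, X, arm*X]
outcome_design <- function(trial, covariates, a, interactions = FALSE) {
  xcov <- build_design(trial, covariates)
  xc <- xcov[, -1, drop = FALSE]
  x <- cbind(`(Intercept)` = xcov[, 1], arm = a, xc)
  des <- list(x = x, arm_col = 2L, int_cols = integer(0),
              base_cols = integer(0))
  if (interactions && ncol(xc)) {
    int <- a * xc
    colnames(int) <- paste0("arm:", colnames(xc))
    des$x <- cbind(x, int)
    des$base_cols <- 2L + seq_len(ncol(xc))
    des$int_cols <- 2L + ncol(xc) + seq_len(ncol(xc))
  }
  des
}

set_arm_design <- function(des, v) {
  x <- des$x
  x[, des$arm_col] <- v
  if (length(des$int_cols)) {
    x[, des$int_cols] <- v * x[, des$base_cols, drop = FALSE]
  }
  x
}

## core g-computation on a fitted weighted logistic model; a sparse factor
## level with no events separates the outcome model and would make the
## sandwich system singular, so such columns (never intercept, arm or
## interaction terms) are dropped and the model refitted
standardized_rr_point <- function(des, y, w, target) {
  for (attempt in 1:3) {
    fit <- suppressWarnings(
      stats::glm.fit(des$x, y, weights = w, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100,
                                                  epsilon = 1e-10))
    )
    if (!fit$converged) stopf("outcome model did not converge")
    beta <- fit$coefficients
    sep <- which(abs(beta) > 15 | is.na(beta))
    sep <- setdiff(sep, c(1L, des$arm_col, des$int_cols))
    if (!length(sep) || length(des$int_cols)) break
    keep <- setdiff(seq_len(ncol(des$x)), sep)
    des$x <- des$x[, keep, drop = FALSE]
  }
  if (anyNA(beta)) stopf("outcome model is rank deficient")
  p1 <- stats::plogis(drop(set_arm_design(des, 1) %*% beta))
  p0 <- stats::plogis(drop(set_arm_design(des, 0) %*% beta))
  mu1 <- mean(p1[target]); mu0 <- mean(p0[target])
  list(fit = fit, p1 = p1, p0 = p0, mu1 = mu1, mu0 = mu0, des = des)
}

#' Doubly robust marginal risk ratio
#'
#' Fits a weighted logistic outcome model (`event ~ arm + covariates`) using
#' the adjustment's weights and standardizes the predicted risks over the
#' target population (treated rows under ATT; all rows under ATE) with arm
#' set to HA and to control.  The standard error on the log risk ratio
#' treats the weights as fixed (M-estimation sandwich, delta method);
#' `se_method = "bootstrap"` instead resamples participants and refits the
#' propensity model, weights and outcome model per resample.
#'
#' @param trial analysis table from [emulate_trial()].
#' @param adjustment an `adjustment` (from [make_adjustments()] /
#'   [select_adjustment()]).
#' @param covariates outcome-model covariates.
#' @param contrast `"itt"` or `"per_protocol"`.
#' @param se_method `"sandwich"` (default) or `"bootstrap"`.
#' @param n_boot,boot_seed bootstrap replicates and seed.
#' @param prop_covariates propensity covariates used when the bootstrap
#'   refits the weights (defaults to the adjustment's own, then to
#'   `covariates`).
#' @param interactions include treatment-covariate interaction terms in the
#'   outcome model (the saturated g-computation form; with fully categorical
#'   covariates the standardized risks then equal direct enumeration).
#' @return an `effect_estimate` with measure `"RR"`.
#' @export
dr_risk_ratio <- function(trial, adjustment, covariates = basic_covariates(),
                          contrast = c("itt", "per_protocol"),
                          se_method = c("sandwich", "bootstrap"),
                          n_boot = 500, boot_seed = 1L,
                          prop_covariates = NULL, interactions = FALSE) {
  contrast <- match.arg(contrast)
  se_method <- match.arg(se_method)
  y <- as.numeric(trial[[outcome_column(contrast)]])
  a <- arm_indicator(trial)
  w <- adjustment$weights
  stopifnot(length(w) == nrow(trial))
  keep <- w > 0
  des <- outcome_design(trial[keep, , drop = FALSE], covariates, a[keep],
                        interactions = interactions)
  target <- if (identical(adjustment$estimand, "ATT")) a == 1 else rep(TRUE, length(a))
  target <- target & keep

  n_arm <- c(HA = sum(a == 1 & keep), control = sum(a == 0 & keep))
  ev_arm <- c(HA = sum(y[a == 1 & keep]), control = sum(y[a == 0 & keep]))
  if (any(ev_arm == 0)) {
    stopf("risk ratio undefined: zero events in the %s arm",
          paste(names(ev_arm)[ev_arm == 0], collapse = " and "))
  }

  st <- standardized_rr_point(des, y[keep], w[keep], target[keep])
  if (st$mu1 <= 0 || st$mu0 <= 0) {
    stopf("risk ratio undefined: zero predicted events in an arm")
  }
  rr <- st$mu1 / st$mu0

  if (se_method == "sandwich") {
    log_se <- dr_sandwich_log_se(st$des, y[keep], w[keep], st, target[keep])
  } else {
    log_se <- dr_bootstrap_log_se(trial, adjustment, covariates, contrast,
                                  n_boot, boot_seed, prop_covariates,
                                  interactions)
  }
  est <- new_effect_estimate("RR", rr, log_se, n_arm, ev_arm, contrast,
                             adjustment$name)
  est$mu_treated <- st$mu1
  est$mu_control <- st$mu0
  est
}

## stacked sandwich: outcome-model score + the two standardization means
dr_sandwich_log_se <- function(des, y, w, st, target) {
  x <- des$x
  beta <- st$fit$coefficients
  p_hat <- stats::plogis(drop(x %*% beta))
  x1 <- set_arm_design(des, 1)
  x0 <- set_arm_design(des, 0)
  p1 <- stats::plogis(drop(x1 %*% beta))
  p0 <- stats::plogis(drop(x0 %*% beta))
  tgt <- as.numeric(target)
  np <- ncol(x)

  psi <- cbind(w * (y - p_hat) * x,
               tgt * (p1 - st$mu1),
               tgt * (p0 - st$mu0))

  a11 <- crossprod(x, w * p_hat * (1 - p_hat) * x)
  a21 <- -colSums(tgt * p1 * (1 - p1) * x1)
  a31 <- -colSums(tgt * p0 * (1 - p0) * x0)
  nt <- sum(tgt)
  amat <- rbind(cbind(a11, 0, 0),
                c(a21, nt, 0),
                c(a31, 0, nt))
  bmat <- crossprod(psi)
  ainv <- tryCatch(solve(amat), error = function(e) {
    ## near-separated columns carry ~zero information; invert in the
    ## informative subspace
    sv <- svd(amat)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  vmat <- ainv %*% bmat %*% t(ainv)
  d <- c(rep(0, np), 1 / st$mu1, -1 / st$mu0)
  sqrt(drop(t(d) %*% vmat %*% d))
}

## rebuild the adjustment on a resampled trial and recompute the point
dr_bootstrap_log_se <- function(trial, adjustment, covariates, contrast,
                                n_boot, boot_seed, prop_covariates,
                                interactions = FALSE) {
  prop_cov <- prop_covariates %||% adjustment$params$prop_covariates %||%
    covariates
  y_col <- outcome_column(contrast)
  set.seed(as.integer(boot_seed))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(trial), replace = TRUE)
    tb <- trial[idx, ]
    est_b <- tryCatch({
      ps <- fit_propensity(tb, prop_cov)
      adj <- rebuild_adjustment(adjustment, tb, ps)
      yb <- as.numeric(tb[[y_col]])
      ab <- arm_indicator(tb)
      wb <- adj$weights
      keep <- wb > 0
      des_b <- outcome_design(tb[keep, , drop = FALSE], covariates, ab[keep],
                              interactions = interactions)
      tgt <- if (identical(adj$estimand, "ATT")) ab == 1 else rep(TRUE, length(ab))
      st <- standardized_rr_point(des_b, yb[keep], wb[keep], (tgt & keep)[keep])
      if (st$mu1 <= 0 || st$mu0 <= 0) NA_real_ else log(st$mu1 / st$mu0)
    }, error = function(e) NA_real_)
    vals[b] <- est_b
  }
  stats::sd(vals, na.rm = TRUE)
}

## recreate an adjustment of the same method on new data
rebuild_adjustment <- function(adjustment, trial, propensity) {
  pars <- adjustment$params
  adjs <- make_adjustments(trial, propensity,
                           caliper = pars$caliper %||% 0.2,
                           match_seed = pars$match_seed %||% 1L,
                           estimand = adjustment$estimand,
                           truncate_pct = pars$truncate_pct,
                           methods = adjustment$name)
  adjs[[adjustment$name]]
}

#' Inverse-probability-weighted Kaplan-Meier curves
#'
#' Product-limit estimator with weighted risk sets and event counts, one
#' curve per arm; discarded rows (weight 0) leave the risk set entirely.
#'
#' @param trial analysis table.
#' @param adjustment an `adjustment`.
#' @param contrast `"itt"` or `"per_protocol"`.
#' @return data.frame of class `survival_curve`: `time` (years since time
#'   zero), `survival`, `arm`; each arm starts at S(0) = 1.
#' @export
weighted_km <- function(trial, adjustment, contrast = c("itt", "per_protocol")) {
  contrast <- match.arg(contrast)
  tcol <- switch(contrast, itt = "fu_years_itt", per_protocol = "fu_years_pp")
  ecol <- outcome_column(contrast)
  w <- adjustment$weights
  keep <- w > 0
  df <- data.frame(time = trial[[tcol]][keep],
                   event = as.numeric(trial[[ecol]][keep]),
                   arm = factor(trial$arm[keep], levels = c("control", "HA")),
                   w = w[keep])
  out_list <- lapply(levels(df$arm), function(lv) {
    sub <- df[df$arm == lv, ]
    if (!nrow(sub)) return(NULL)
    if (sum(sub$event) == 0) {
      return(data.frame(time = c(0, max(sub$time)), survival = c(1, 1),
                        arm = lv, stringsAsFactors = FALSE))
    }
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                            weights = sub$w)
    data.frame(time = c(0, sf$time), survival = c(1, sf$surv), arm = lv,
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, out_list)
  rownames(curve) <- NULL
  class(curve) <- c("survival_curve", "data.frame")
  curve
}

#' Weighted Cox proportional-hazards ratio for the arm effect
#'
#' Weighted partial likelihood with the Efron tie correction and robust
#' (score-residual) standard errors.
#'
#' @param trial analysis table.
#' @param adjustment an `adjustment`.
#' @param covariates additional covariates (NULL for the arm-only model).
#' @param contrast `"itt"` or `"per_protocol"`.
#' @return an `effect_estimate` with measure `"HR"`.
#' @export
cox_hazard_ratio <- function(trial, adjustment,
                             covariates = basic_covariates(),
                             contrast = c("itt", "per_protocol")) {
  contrast <- match.arg(contrast)
  if (anyDuplicated(covariates)) {
    stopf("rank-deficient Cox model: duplicated covariates (%s)",
          paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  }
  tcol <- switch(contrast, itt = "fu_years_itt", per_protocol = "fu_years_pp")
  ecol <- outcome_column(contrast)
  w <- adjustment$weights
  keep <- w > 0
  df <- trial[keep, , drop = FALSE]
  df$.time <- pmax(df[[tcol]], 1 / 24)  # half-month floor at month precision
  df$.event <- as.numeric(df[[ecol]])
  df$.arm <- factor(df$arm, levels = c("control", "HA"))
  for (e in c("HA", "control")) {
    if (sum(df$.event[df$arm == e]) < 1) {
      stopf("Cox model requires at least one event per arm")
    }
  }
  rhs <- c(".arm", covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(rhs, collapse = " + ")))
  if (length(covariates)) {
    dd <- as_covariate_frame(df, covariates)
    for (cl in names(dd)) {
      df[[cl]] <- if (is.factor(dd[[cl]])) droplevels(dd[[cl]]) else dd[[cl]]
    }
  }
  df$.w <- w[keep]
  fit <- tryCatch(
    survival::coxph(fml, data = df, weights = .w,
                    robust = TRUE, ties = "efron"),
    warning = function(wn) {
      msg <- conditionMessage(wn)
      ## a sparse covariate level with monotone likelihood is tolerated;
      ## failure to converge, or an unbounded arm coefficient, is not
      if (grepl("Ran out of iterations|did not converge", msg) ||
          (grepl("infinite", msg) && grepl("\\.arm", msg))) {
        stopf("Cox model did not converge")
      }
      suppressWarnings(survival::coxph(fml, data = df, weights = .w,
                                       robust = TRUE, ties = "efron"))
    }
  )
  cf <- stats::coef(fit)
  if (is.na(cf[".armHA"])) {
    stopf("rank-deficient Cox model: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  i <- grep("^\\.armHA$", names(cf))
  se <- sqrt(diag(fit$var))[i]
  a <- arm_indicator(trial)
  y <- as.numeric(trial[[ecol]])
  new_effect_estimate("HR", exp(cf[i]), se,
                      c(HA = sum(a == 1 & keep), control = sum(a == 0 & keep)),
                      c(HA = sum(y[a == 1 & keep]),
                        control = sum(y[a == 0 & keep])),
                      contrast, adjustment$name)
}

#' Write effect estimates as a delimited-text table
#' @param estimates a named list of `effect_estimate` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  rows <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(model = nm, contrast = e$contrast, measure = e$measure,
               point = e$point, lower = e$ci_lower, upper = e$ci_upper,
               n_treated = e$n_treated, n_control = e$n_control,
               events_treated = e$events_treated,
               events_control = e$events_control,
               adjustment = e$adjustment, stringsAsFactors = FALSE)
  }))
  write_table_tsv(rows, path)
  invisible(path)
}
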