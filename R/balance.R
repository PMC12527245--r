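## Propensity estimation, weighting/matching candidates, balance scoring.
##
## The estimand defaults to the ATT (effect in HA initiators): treated rows
## keep weight 1 and controls are reweighted to the treated covariate
## profile.  Candidate adjustments are scored by covariate balance (SMD,
## variance ratio, weighted Kolmogorov-Smirnov statistic) and the selection
## rule prefers methods that discard no observations.

FACTOR_LEVELS <- list(
  sex = c("F", "M"),
  education = c("none", "secondary", "higher"),
  ethnicity = c("White", "non-White"),
  region = c("England", "Scotland", "Wales", "Unknown"),
  hl_source = c("self_report", "sin_test", "ehr"),
  hosp_cat = c("0", "(0,0.2]", "(0.2,0.5]", ">0.5"),
  gp_cat = c("[0,12]", "(12,24]", ">24")
)

as_covariate_frame <- function(trial, covariates) {
  out <- trial[covariates]
  for (cl in names(out)) {
    x <- out[[cl]]
    if (is.logical(x)) out[[cl]] <- as.numeric(x)
    else if (is.character(x) || is.factor(x)) {
      lev <- FACTOR_LEVELS[[cl]] %||% sort(unique(as.character(x)))
      out[[cl]] <- factor(as.character(x), levels = lev)
    }
  }
  out
}

## design matrix with intercept, reference coding, unused levels dropped
build_design <- function(trial, covariates) {
  if (!length(covariates)) {
    return(matrix(1, nrow(trial), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as_covariate_frame(trial, covariates)
  for (cl in names(df)) if (is.factor(df[[cl]])) df[[cl]] <- droplevels(df[[cl]])
  stats::model.matrix(~ ., data = df)
}

arm_indicator <- function(trial) as.numeric(trial$arm == "HA")

#' Fit the propensity model
#'
#' Logistic regression of HA-arm membership on the covariate set, with
#' reference coding for categorical covariates.  Perfect separation or
#' non-convergence raises an estimation error naming the covariates
#' involved.
#'
#' @param trial the analysis table from [emulate_trial()] (`$trial`).
#' @param covariates covariate column names; default [basic_covariates()].
#' @return list of class `propensity_fit`: `scores` in (0,1), `coef`,
#'   `covariates`, `converged`.
#' @export
fit_propensity <- function(trial, covariates = basic_covariates()) {
  a <- arm_indicator(trial)
  if (length(unique(a)) < 2L) stopf("both arms must be nonempty")
  x <- build_design(trial, covariates)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stopf("propensity design is rank deficient (columns: %s)",
          paste(drop_cols, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(x, a, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50))
  )
  p <- fit$fitted.values
  eps <- 1e-8
  at_bound <- mean(p < eps | p > 1 - eps)
  if (!fit$converged || at_bound > 0.02) {
    bad <- names(fit$coefficients)[abs(fit$coefficients) > 15]
    if (!length(bad)) bad <- "(fitted probabilities at 0/1)"
    stopf("propensity model did not converge or separated (%s)",
          paste(bad, collapse = ", "))
  }
  ## isolated structural zeros (e.g. one sparse factor level with no treated
  ## rows) are tolerated: clamp the scores, their ATT weights vanish
  p <- pmin(pmax(p, eps), 1 - eps)
  out <- list(scores = as.numeric(p), coef = fit$coefficients,
              covariates = covariates, converged = fit$converged)
  class(out) <- "propensity_fit"
  out
}

new_adjustment <- function(name, weights, discarded, ps,
                           estimand = "ATT", degenerate = FALSE,
                           params = list()) {
  stopifnot(all(weights >= 0), all(weights[discarded] == 0))
  out <- list(name = name, weights = weights, discarded = discarded,
              ps = ps, estimand = estimand, degenerate = degenerate,
              params = params)
  class(out) <- "adjustment"
  out
}

#' @export
print.adjustment <- function(x, ...) {
  cat(sprintf("<adjustment '%s'> %s, %d rows (%d discarded)%s\n", x$name,
              x$estimand, length(x$weights), sum(x$discarded),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

att_weights <- function(a, p) ifelse(a == 1, 1, p / (1 - p))

#' Build the candidate adjustment set
#'
#' Three candidates: `att_ipw` (treated weight 1, controls `p/(1-p)`),
#' `stabilized` (full-sample stabilized inverse-probability weights), and
#' `nn_match` (1:1 nearest-neighbour matching on the logit propensity score
#' without replacement, caliper in SD units of the logit score, random
#' treated order under a fixed seed).  A caliper that excludes every control
#' flags the matching candidate as degenerate rather than erroring.
#'
#' @param trial analysis table.
#' @param propensity a `propensity_fit` (or numeric score vector).
#' @param caliper caliper width in SDs of the logit propensity score.
#' @param match_seed seed for the random matching order.
#' @param estimand `"ATT"` (default) or `"ATE"` (affects the IPW candidates).
#' @param truncate_pct optional upper percentile (e.g. 99) at which weights
#'   are truncated; off by default.
#' @param methods which candidates to build (subset of `"att_ipw"`,
#'   `"nn_match"`, `"stabilized"`).
#' @return named list of `adjustment` objects.
#' @export
make_adjustments <- function(trial, propensity, caliper = 0.2,
                             match_seed = 1L, estimand = c("ATT", "ATE"),
                             truncate_pct = NULL,
                             methods = c("att_ipw", "nn_match", "stabilized")) {
  estimand <- match.arg(estimand)
  methods <- match.arg(methods, several.ok = TRUE)
  p <- if (inherits(propensity, "propensity_fit")) propensity$scores else propensity
  stopifnot(length(p) == nrow(trial), all(p > 0 & p < 1))
  a <- arm_indicator(trial)
  none <- rep(FALSE, length(a))
  params <- list(caliper = caliper, match_seed = match_seed,
                 estimand = estimand, truncate_pct = truncate_pct,
                 prop_covariates = if (inherits(propensity, "propensity_fit"))
                   propensity$covariates)

  w_ipw <- if (estimand == "ATT") att_weights(a, p) else
    ifelse(a == 1, 1 / p, 1 / (1 - p))
  pbar <- mean(a)
  w_stab <- if (estimand == "ATT") {
    ## ATT stabilization leaves treated at 1; controls get odds scaled by
    ## the marginal odds so weights average near 1
    ifelse(a == 1, 1, (p / (1 - p)) * ((1 - pbar) / pbar))
  } else {
    ifelse(a == 1, pbar / p, (1 - pbar) / (1 - p))
  }
  if (!is.null(truncate_pct)) {
    cap <- function(w) pmin(w, stats::quantile(w, truncate_pct / 100))
    w_ipw <- cap(w_ipw); w_stab <- cap(w_stab)
  }

  out <- list()
  if ("att_ipw" %in% methods) {
    out$att_ipw <- new_adjustment("att_ipw", w_ipw, none, p, estimand,
                                  params = params)
  }
  if ("nn_match" %in% methods) {
    ## 1:1 nearest-neighbour match on logit score with caliper
    lp <- stats::qlogis(p)
    cal <- caliper * stats::sd(lp)
    treated <- which(a == 1)
    controls <- which(a == 0)
    ord_c <- controls[order(lp[controls])]
    lp_c <- lp[ord_c]
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(match_seed)
    t_order <- sample(treated)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    nC <- length(ord_c)
    used <- rep(FALSE, nC)
    match_of <- rep(NA_integer_, length(a))
    for (t in t_order) {
      j <- findInterval(lp[t], lp_c)
      best <- NA_integer_; bestd <- cal
      lo <- j; hi <- j + 1L
      while (lo >= 1L || hi <= nC) {
        dlo <- if (lo >= 1L) lp[t] - lp_c[lo] else Inf
        dhi <- if (hi <= nC) lp_c[hi] - lp[t] else Inf
        if (dlo > bestd && dhi > bestd) break
        if (dlo <= dhi) {
          if (!used[lo] && dlo <= bestd) { best <- lo; bestd <- dlo }
          lo <- lo - 1L
        } else {
          if (!used[hi] && dhi <= bestd) { best <- hi; bestd <- dhi }
          hi <- hi + 1L
        }
      }
      if (!is.na(best)) {
        used[best] <- TRUE
        match_of[t] <- ord_c[best]
      }
    }
    matched_t <- !is.na(match_of) & a == 1
    matched_rows <- c(which(matched_t), match_of[matched_t])
    w_match <- rep(0, length(a)); w_match[matched_rows] <- 1
    out$nn_match <- new_adjustment("nn_match", w_match, w_match == 0, p,
                                   estimand,
                                   degenerate = sum(matched_t) == 0L,
                                   params = params)
  }
  if ("stabilized" %in% methods) {
    out$stabilized <- new_adjustment("stabilized", w_stab, none, p, estimand,
                                     params = params)
  }
  out
}

## expand covariates to numeric columns (one indicator per factor level)
balance_columns <- function(trial, covariates) {
  df <- as_covariate_frame(trial, covariates)
  cols <- list()
  for (cl in names(df)) {
    x <- df[[cl]]
    if (is.factor(x)) {
      for (lev in levels(x)) cols[[paste0(cl, ":", lev)]] <- as.numeric(x == lev)
    } else {
      cols[[cl]] <- as.numeric(x)
    }
  }
  cols
}

wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

## max gap between weighted eCDFs of x in two groups
weighted_ks <- function(x, g, w) {
  ord <- order(x)
  x <- x[ord]; g <- g[ord]; w <- w[ord]
  w1 <- ifelse(g == 1, w, 0); w0 <- ifelse(g == 0, w, 0)
  if (sum(w1) == 0 || sum(w0) == 0) return(NA_real_)
  c1 <- cumsum(w1) / sum(w1)
  c0 <- cumsum(w0) / sum(w0)
  last <- c(x[-1] != x[-length(x)], TRUE)  # evaluate at distinct values
  max(abs(c1[last] - c0[last]))
}

#' Covariate balance report for an adjustment
#'
#' Per covariate (factors expanded to level indicators): standardized mean
#' difference with the pooled pre-adjustment SD as fixed denominator,
#' variance ratio, and the maximum weighted eCDF gap (KS statistic), before
#' and after weighting.  Covariates with zero pooled SD are reported with NA
#' SMD.
#'
#' @param trial analysis table.
#' @param adjustment an `adjustment` object.
#' @param covariates covariate columns to balance-check.
#' @return data.frame of class `balance_report`; attributes `method`,
#'   `max_abs_smd`, `max_ks`, `retained_frac`.
#' @export
balance_report <- function(trial, adjustment, covariates = basic_covariates()) {
  stopifnot(length(adjustment$weights) == nrow(trial))
  a <- arm_indicator(trial)
  w_pre <- rep(1, nrow(trial))
  w_post <- adjustment$weights
  cols <- balance_columns(trial, covariates)
  one <- function(x) {
    sd_pool <- sqrt((stats::var(x[a == 1]) + stats::var(x[a == 0])) / 2)
    stat <- function(w) {
      ww1 <- w[a == 1]; ww0 <- w[a == 0]
      if (sum(ww1) == 0 || sum(ww0) == 0) return(c(NA, NA, NA))
      m1 <- wmean(x[a == 1], ww1); m0 <- wmean(x[a == 0], ww0)
      v1 <- wvar(x[a == 1], ww1); v0 <- wvar(x[a == 0], ww0)
      smd <- if (is.na(sd_pool) || sd_pool == 0) NA_real_ else (m1 - m0) / sd_pool
      vr <- if (v0 > 0) v1 / v0 else NA_real_
      c(smd, vr, weighted_ks(x, a, w))
    }
    c(stat(w_pre), stat(w_post))
  }
  m <- t(vapply(cols, one, numeric(6)))
  rep_df <- data.frame(
    covariate = names(cols),
    smd_before = m[, 1], smd_after = m[, 4],
    vr_before = m[, 2], vr_after = m[, 5],
    ks_before = m[, 3], ks_after = m[, 6],
    stringsAsFactors = FALSE
  )
  rownames(rep_df) <- NULL
  class(rep_df) <- c("balance_report", "data.frame")
  attr(rep_df, "method") <- adjustment$name
  attr(rep_df, "max_abs_smd") <- suppressWarnings(max(abs(rep_df$smd_after), na.rm = TRUE))
  attr(rep_df, "max_ks") <- suppressWarnings(max(rep_df$ks_after, na.rm = TRUE))
  attr(rep_df, "retained_frac") <- 1 - mean(adjustment$discarded)
  rep_df
}

#' Select the adjustment by balance, preferring no-discard methods
#'
#' Among candidates discarding no rows (and not degenerate), picks the one
#' with the smallest maximum absolute SMD; only if every no-discard candidate
#' exceeds `smd_threshold` are discarding methods considered.  Ties break to
#' fewer discarded rows, then lexicographic name.
#'
#' @param adjustments named list of `adjustment` objects.
#' @param reports named list of matching [balance_report()]s (computed if
#'   NULL).
#' @param trial,covariates needed only when `reports` is NULL.
#' @param smd_threshold acceptable max |SMD| for a no-discard method.
#' @return the chosen `adjustment`, with its report attached as attribute
#'   `report`.
#' @export
select_adjustment <- function(adjustments, reports = NULL, trial = NULL,
                              covariates = basic_covariates(),
                              smd_threshold = 0.1) {
  if (!length(adjustments)) stopf("empty candidate set")
  if (is.null(reports)) {
    if (is.null(trial)) stopf("either `reports` or `trial` must be supplied")
    reports <- lapply(adjustments, balance_report, trial = trial,
                      covariates = covariates)
  }
  nm <- names(adjustments)
  info <- data.frame(
    name = nm,
    max_smd = vapply(reports[nm], attr, numeric(1), which = "max_abs_smd"),
    n_disc = vapply(adjustments, function(x) sum(x$discarded), numeric(1)),
    degenerate = vapply(adjustments, function(x) isTRUE(x$degenerate), logical(1)),
    stringsAsFactors = FALSE
  )
  info <- info[!info$degenerate & is.finite(info$max_smd), ]
  if (!nrow(info)) stopf("no usable adjustment candidate")
  nodisc <- info[info$n_disc == 0, ]
  pool <- if (nrow(nodisc) && min(nodisc$max_smd) <= smd_threshold) nodisc
          else info
  pool <- pool[order(pool$max_smd, pool$n_disc, pool$name), ]
  chosen <- adjustments[[pool$name[1]]]
  attr(chosen, "report") <- reports[[pool$name[1]]]
  chosen
}

#' Write a balance report (or a list of them) as delimited text
#' @param reports a `balance_report` or named list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(reports, path) {
  if (inherits(reports, "balance_report")) {
    reports <- stats::setNames(list(reports), attr(reports, "method"))
  }
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cbind(method = nm, as.data.frame(r))
  }))
  write_table_tsv(rows, path)
  invisible(path)
}
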