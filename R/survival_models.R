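#' Validate a survival record table
#'
#' @param records data.frame with columns `time_months` (> 0), `event`
#'   (0/1) and optionally `sample_id` plus covariate columns.
#' @return the validated data.frame, invisibly coerced.
#' @export
surv_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("time_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0))
    stop("time_months must be positive and finite")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)")
  records
}

#' Kaplan-Meier estimate with per-group step functions
#'
#' Product-limit estimator of overall survival, optionally stratified by a
#' grouping covariate; returns the step function and median survival per
#' group.
#'
#' @param records survival records (see [surv_records()]).
#' @param group optional name of a grouping column.
#' @return list with `groups`, a named list of data.frames (time, n_risk,
#'   n_event, surv), `median` (named vector of median survival), and the
#'   underlying `survfit` object.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- surv_records(records)
  if (is.null(group)) {
    records$.grp <- "all"; group <- ".grp"
  }
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste0("`", group, "`")))
  fit <- survival::survfit(f, data = records)
  s <- summary(fit)
  grp <- if (is.null(s$strata)) rep("all", length(s$time)) else
    sub("^[^=]*=", "", as.character(s$strata))
  groups <- split(data.frame(time = s$time, n_risk = s$n.risk,
                             n_event = s$n.event, surv = s$surv),
                  grp)
  med <- summary(fit)$table
  med <- if (is.null(dim(med))) stats::setNames(med[["median"]], "all") else
    stats::setNames(med[, "median"], sub("^[^=]*=", "", rownames(med)))
  list(groups = groups, median = med, fit = fit)
}

fit_to_result <- function(fit, family) {
  s <- summary(fit)
  if (family == "coxph") {
    co <- s$coefficients
    se <- stats::setNames(co[, "se(coef)"], rownames(co))
    est <- stats::setNames(co[, "coef"], rownames(co))
    lrt <- s$logtest
    res <- list(family = "coxph",
                coefficients = stats::setNames(est, rownames(co)),
                se = stats::setNames(se, rownames(co)),
                hr = exp(est),
                ci95 = cbind(lower = stats::setNames(exp(est - 1.96 * se),
                                                     rownames(co)),
                             upper = exp(est + 1.96 * se)),
                p = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
                lrt_stat = unname(lrt["test"]), lrt_p = unname(lrt["pvalue"]),
                loglik = fit$loglik[2], fit = fit)
  } else {
    co <- s$table
    keep <- setdiff(rownames(co), "Log(scale)")
    est <- stats::setNames(co[keep, "Value"], keep)
    se <- stats::setNames(co[keep, "Std. Error"], keep)
    shape <- 1 / fit$scale
    lrt_stat <- 2 * (fit$loglik[2] - fit$loglik[1])
    df <- sum(!is.na(fit$coefficients)) - 1L
    lrt_p <- if (df > 0) stats::pchisq(lrt_stat, df, lower.tail = FALSE)
             else NA_real_
    # AFT coefficient b maps to PH log-hazard -b * shape
    hr <- exp(-est * shape)
    res <- list(family = "weibull",
                coefficients = stats::setNames(est, keep),
                se = stats::setNames(se, keep),
                hr = hr,
                ci95 = cbind(lower = exp((-est - 1.96 * se) * shape),
                             upper = exp((-est + 1.96 * se) * shape)),
                p = co[keep, "p"],
                shape = shape, scale = unname(exp(est["(Intercept)"])),
                lrt_stat = lrt_stat, lrt_p = lrt_p,
                loglik = fit$loglik[2], fit = fit)
    # for HR, order CI so lower < upper (sign flip from -b*shape)
    res$ci95 <- t(apply(res$ci95, 1L, sort))
    colnames(res$ci95) <- c("lower", "upper")
  }
  rownames(res$ci95) <- names(res$coefficients)
  class(res) <- "SurvivalFit"
  res
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("SurvivalFit (%s): LRT p = %.4g\n", x$family, x$lrt_p))
  cov <- setdiff(names(x$coefficients), "(Intercept)")
  if (length(cov)) {
    tab <- data.frame(coef = x$coefficients[cov],
                      HR = x$hr[cov],
                      lower95 = x$ci95[cov, "lower"],
                      upper95 = x$ci95[cov, "upper"],
                      p = x$p[cov])
    print(round(tab, 4))
  }
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Efron handling of tied event times),
#' with Wald 95% confidence intervals per covariate and a likelihood-ratio
#' test against the null model.
#'
#' @param records survival records.
#' @param covariates character vector of covariate column names.
#' @return a `SurvivalFit`.
#' @export
cox_fit <- function(records, covariates) {
  records <- surv_records(records)
  if (sum(records$event) < 1L) stop("need at least one event")
  x <- stats::model.matrix(
    stats::as.formula(paste("~", paste0("`", covariates, "`",
                                        collapse = "+"))), records)
  if (qr(x)$rank < ncol(x)) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(x)[-1], collapse = ", "))
  }
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste0("`", covariates, "`", collapse = "+")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("coxph did not converge (possible monotone likelihood / ",
             "perfect separation): ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  fit_to_result(fit, "coxph")
}

#' Weibull accelerated-failure-time fit
#'
#' Maximum-likelihood Weibull regression with right censoring
#' (location-scale parameterization); reports the shape (1/scale of the
#' log-time model), baseline scale, AFT coefficients, PH-scale hazard
#' ratios and a likelihood-ratio test against the intercept-only model.
#'
#' @param records survival records.
#' @param covariates character vector of covariate column names (may be
#'   empty for a baseline-only fit).
#' @param fix_shape optionally fix the Weibull shape (shape = 1 gives the
#'   exponential model).
#' @return a `SurvivalFit` with extra fields `shape` and `scale`.
#' @export
weibull_fit <- function(records, covariates = character(0),
                        fix_shape = NULL) {
  records <- surv_records(records)
  if (sum(records$event) < 2L) stop("need at least two events")
  rhs <- if (length(covariates))
    paste0("`", covariates, "`", collapse = "+") else "1"
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~", rhs))
  fit <- if (is.null(fix_shape))
    survival::survreg(f, data = records, dist = "weibull")
  else
    survival::survreg(f, data = records, dist = "weibull",
                      scale = 1 / fix_shape)
  if (!is.null(fit$flag) && fit$flag > 0 && any(!is.finite(fit$coefficients)))
    stop("weibull fit did not converge")
  fit_to_result(fit, "weibull")
}

#' Univariable Cox screen over a covariate list
#'
#' One single-covariate Cox fit per covariate; covariates with a single
#' observed level are skipped with a warning.
#'
#' @param records survival records.
#' @param covariates character vector of covariate column names.
#' @return data.frame with one row per fitted covariate: covariate, hr,
#'   lower95, upper95, p, lrt_p; skipped covariates are absent.
#' @export
univariable_screen <- function(records, covariates) {
  records <- surv_records(records)
  rows <- lapply(covariates, function(cv) {
    v <- records[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("covariate '", cv, "' has a single level; skipped")
      return(NULL)
    }
    ft <- cox_fit(records, cv)
    i <- 1L  # first (only) coefficient row
    data.frame(covariate = cv, coef = unname(ft$coefficients[i]),
               hr = unname(ft$hr[i]),
               lower95 = unname(ft$ci95[i, "lower"]),
               upper95 = unname(ft$ci95[i, "upper"]),
               p = unname(ft$p[i]), lrt_p = ft$lrt_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Multivariable Cox fit with an events-per-variable guard
#'
#' Refuses to fit when events per covariate fall below `min_epv` (small-n
#' instability), unless `force = TRUE`.
#'
#' @param records survival records.
#' @param covariates covariate column names.
#' @param min_epv minimum events per variable (default 5).
#' @param force fit anyway.
#' @return a `SurvivalFit`.
#' @export
multivariable_cox <- function(records, covariates, min_epv = 5, force = FALSE) {
  records <- surv_records(records)
  epv <- sum(records$event) / length(covariates)
  if (epv < min_epv && !force)
    stop(sprintf(paste0("events per variable %.1f < %g; multivariable fit ",
                        "is unstable at this sample size (use force = TRUE ",
                        "to override)"), epv, min_epv))
  cox_fit(records, covariates)
}
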