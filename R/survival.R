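#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimates `S(t) = prod(1 - d_i / n_i)` per group
#' over event times, and the log-rank chi-square from observed-minus-expected
#' events across the pooled event times (via [survival::survfit()] and
#' [survival::survdiff()]).
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = relapse/event, 0 = censored).
#' @param group group labels (factor or character).
#' @return list with `curves` (data.frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p_value` (NA with a message when no
#'   events occurred), and the `survfit` object as `fit`.
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0, na.rm = TRUE)) stop("times must be positive")
  keep <- stats::complete.cases(time, event, group)
  time <- time[keep]; event <- event[keep]; group <- factor(group[keep])
  if (nlevels(group) < 2L) stop("need at least two groups")

  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    surv = fit$surv
  )

  if (sum(event) == 0L) {
    message("no events observed; log-rank p undefined")
    return(list(curves = curves, chisq = NA_real_,
                df = nlevels(group) - 1L, p_value = NA_real_, fit = fit))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(curves = curves, chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       fit = fit)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood Cox regression with Efron tie handling (Breslow
#' available) and Wald p-values. Categorical covariates (cluster membership,
#' mutation status, copy-number status) are expanded to indicator terms by
#' the model formula. Supply one covariate for a univariate fit or several
#' for a multivariate fit.
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param covariates data.frame of covariates (rows align with `time`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list with `table` (data.frame `term`, `coef`, `hr`, `se`,
#'   `hr_lower`, `hr_upper`, `p_value`) and the `coxph` fit as `fit`.
#' @export
cox_regression <- function(time, event, covariates,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  keep <- stats::complete.cases(time, event, covariates)
  time <- time[keep]; event <- event[keep]
  covariates <- covariates[keep, , drop = FALSE]
  if (sum(event) < 1L) stop("at least one event is required")
  const <- vapply(covariates, function(v) length(unique(v)) == 1L, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ .,
    data = dat, ties = ties
  )
  if (!is.null(fit$info) || anyNA(stats::coef(fit))) {
    stop("Cox fit failed to converge (iterations: ", fit$iter, ")")
  }
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  list(
    table = data.frame(
      term = rownames(co),
      coef = co[, "coef"],
      hr = co[, "exp(coef)"],
      se = co[, "se(coef)"],
      hr_lower = ci[, "lower .95"],
      hr_upper = ci[, "upper .95"],
      p_value = co[, "Pr(>|z|)"],
      row.names = NULL
    ),
    fit = fit
  )
}
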