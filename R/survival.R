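# CIS-proportion survival stratification: median split per subtype,
# Kaplan-Meier curves, log-rank test, Cox hazard ratio, optional 5-year
# endpoint (1825 days).

#' Split samples into median-high / median-low CIS groups
#'
#' The median CIS proportion is computed independently within each
#' subtype; group = "high" if the sample's proportion is strictly above
#' its subtype median, else "low" (ties therefore fall to "low"). If all
#' proportions of a subtype are equal every sample is "low" and a warning
#' is emitted.
#'
#' @param cis_proportions named numeric vector (names = sample IDs).
#' @param clinical clinical data.frame with sample_id (and optionally
#'   subtype; a single pseudo-subtype is assumed if absent).
#' @return the clinical table with a \code{group} column and a
#'   \code{cis_proportion} column.
#' @export
split_by_cis <- function(cis_proportions, clinical) {
  miss <- setdiff(clinical$sample_id, names(cis_proportions))
  if (length(miss))
    stop("missing CIS proportion for sample(s): ",
         paste(miss, collapse = ", "))
  clinical$cis_proportion <- unname(cis_proportions[clinical$sample_id])
  if (is.null(clinical$subtype)) clinical$subtype <- "all"
  clinical$group <- NA_character_
  for (st in unique(clinical$subtype)) {
    sel <- clinical$subtype == st
    p <- clinical$cis_proportion[sel]
    med <- stats::median(p)
    if (all(p == p[1L]))
      warning("all CIS proportions equal in subtype ", st,
              ": every sample assigned 'low'")
    clinical$group[sel] <- ifelse(p > med, "high", "low")
  }
  clinical
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood-based confidence intervals
#' (via \code{survival::survfit}).
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param conf_level confidence level.
#' @return data.frame time, n_risk, n_event, survival, lower, upper.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.int = conf_level)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Two-group log-rank test
#'
#' @param time_a,event_a times and 0/1 events of group A.
#' @param time_b,event_b times and 0/1 events of group B.
#' @return list(statistic, p_value) for the 1-df chi-square.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for the high vs low CIS groups
#'
#' Single binary covariate, Efron tie handling.
#'
#' @param clinical data.frame with time_days, event, group
#'   ("high"/"low").
#' @param conf_level confidence level for the HR interval.
#' @return list(hr, ci_lower, ci_upper, log_hr, p_value).
#' @export
cox_hazard_ratio <- function(clinical, conf_level = 0.95) {
  if (sum(clinical$event) == 0) stop("no events: Cox model undefined")
  if (length(unique(clinical$group)) < 2L)
    stop("need both 'high' and 'low' groups")
  clinical$group <- factor(clinical$group, levels = c("low", "high"))
  fit <- survival::coxph(
    survival::Surv(time_days, event) ~ group, data = clinical,
    ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci_lower = exp(beta - zq * se),
       ci_upper = exp(beta + zq * se), log_hr = beta,
       p_value = summary(fit)$coefficients[1, "Pr(>|z|)"])
}

#' Truncate follow-up at the 5-year endpoint (1825 days)
#'
#' Times beyond 1825 days are set to 1825 with the event flag cleared
#' (administrative censoring); a time of exactly 1825 days is left
#' untouched. Truncation never increases the event count.
#'
#' @param clinical clinical data.frame with time_days and event.
#' @param cutoff_days endpoint in days (default 1825 = 5 years).
#' @return truncated clinical table.
#' @export
truncate_5year <- function(clinical, cutoff_days = 1825) {
  over <- clinical$time_days > cutoff_days
  clinical$event[over] <- 0L
  clinical$time_days[over] <- cutoff_days
  clinical
}

#' Per-subtype CIS survival analysis
#'
#' Runs the median split, Kaplan-Meier estimates per group, the log-rank
#' test, and the Cox hazard ratio within each subtype (never pooled).
#'
#' @param cis_proportions named per-sample CIS proportions.
#' @param clinical clinical table (sample_id, time_days, event, subtype).
#' @param five_year truncate at 1825 days first.
#' @return named list per subtype: list(clinical, km (per group),
#'   logrank, cox).
#' @export
cis_survival_analysis <- function(cis_proportions, clinical,
                                  five_year = FALSE) {
  clin <- split_by_cis(cis_proportions, clinical)
  if (five_year) clin <- truncate_5year(clin)
  out <- list()
  for (st in unique(clin$subtype)) {
    d <- clin[clin$subtype == st, , drop = FALSE]
    hi <- d[d$group == "high", , drop = FALSE]
    lo <- d[d$group == "low", , drop = FALSE]
    lr <- if (nrow(hi) && nrow(lo))
      logrank_test(hi$time_days, hi$event, lo$time_days, lo$event)
    else list(statistic = NA_real_, p_value = NA_real_)
    cox <- tryCatch(cox_hazard_ratio(d), error = function(e)
      list(hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
           log_hr = NA_real_, p_value = NA_real_))
    out[[st]] <- list(
      clinical = d,
      km = list(high = if (nrow(hi)) km_estimate(hi$time_days, hi$event),
                low = if (nrow(lo)) km_estimate(lo$time_days, lo$event)),
      logrank = lr,
      cox = cox)
  }
  out
}
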