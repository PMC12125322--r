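# Kaplan-Meier estimation, endpoint derivation, and the log-rank test.

#' Derive overall- and disease-specific survival endpoints
#'
#' Overall survival uses any-cause death as the event; disease-specific
#' survival treats death from other causes as censoring at the same time.
#'
#' @param records data.frame with `os_time`, `os_event`, `dss_event`.
#' @return List with elements `os` and `dss`, each `list(time, event)`.
#' @export
derive_endpoints <- function(records) {
  stopifnot(all(c("os_time", "os_event", "dss_event") %in% names(records)))
  if (any(records$os_time < 0)) stop("negative survival time")
  if (any(records$dss_event & !records$os_event))
    stop("disease-specific events must be a subset of overall events")
  list(os = list(time = records$os_time, event = as.logical(records$os_event)),
       dss = list(time = records$os_time,
                  event = as.logical(records$dss_event)))
}

#' Kaplan-Meier product-limit estimate
#'
#' Greenwood variance with a log-scale 95% confidence interval clipped to
#' \[0, 1\].
#'
#' @param time Non-negative follow-up times.
#' @param event Logical event indicator (FALSE = censored).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `km_curve`: `time` (distinct event times),
#'   `surv`, `var_log_surv`, `lower`, `upper`, `n_risk`, `n_event`, `n`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop("negative survival time")
  if (all(time == 0)) stop("all follow-up times are zero")
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  n_event <- vapply(et, function(t) sum(event & time == t), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  incr <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), NA)
  var_log <- cumsum(ifelse(is.na(incr), 0, incr))
  var_log[cumsum(is.na(incr)) > 0] <- NA  # variance undefined once S hits 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  lower <- ifelse(surv > 0, pmin(1, pmax(0, exp(log(surv) - z * sqrt(var_log)))), 0)
  upper <- ifelse(surv > 0, pmin(1, pmax(0, exp(log(surv) + z * sqrt(var_log)))), 0)
  structure(list(time = et, surv = surv, var_log_surv = var_log,
                 lower = lower, upper = upper, n_risk = n_risk,
                 n_event = n_event, n = length(time),
                 conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              x$n, length(x$time)))
  print(head(data.frame(time = x$time, n_risk = x$n_risk,
                        n_event = x$n_event, surv = round(x$surv, 4),
                        lower = round(x$lower, 4),
                        upper = round(x$upper, 4)), 10L), row.names = FALSE)
  if (length(x$time) > 10L) cat("...\n")
  invisible(x)
}

#' Survival estimate at a time point
#'
#' @param curve A [km_estimate()] result.
#' @param t Time point (vectorised).
#' @return data.frame with `time`, `surv`, `lower`, `upper` (step-function
#'   lookup; survival is 1 before the first event).
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$time)
  get <- function(v, default) ifelse(idx >= 1L, v[pmax(idx, 1L)], default)
  data.frame(time = t,
             surv = get(curve$surv, 1),
             lower = get(curve$lower, 1),
             upper = get(curve$upper, 1))
}

#' Log-rank test for k groups
#'
#' Standard observed-minus-expected statistic over pooled event times, with
#' hypergeometric variance; chi-square with k - 1 degrees of freedom.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Group labels (factor or vector), at least two nonempty
#'   groups.
#' @return List of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` per group. With no events the statistic is
#'   undefined and reported as `NA`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least two groups")
  if (any(table(group) == 0L)) stop("each group must be nonempty")
  event <- as.logical(event)
  out <- structure(list(statistic = NA_real_, df = k - 1L,
                        p_value = NA_real_,
                        observed = setNames(rep(NA_real_, k), levels(group)),
                        expected = setNames(rep(NA_real_, k), levels(group))),
                   class = "logrank_test")
  if (!any(event)) return(out)
  et <- sort(unique(time[event]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event & time == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 integer(1))
    dg <- vapply(levels(group), function(g)
      sum(event & time == t & group == g), integer(1))
    p <- ng / n
    O <- O + dg
    E <- E + d * p
    if (n > 1L)
      V <- V + d * (n - d) / (n - 1) * (diag(p, k) - tcrossprod(p))
  }
  oe <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(oe) %*% solve(Vsub, oe)), error = function(e) NA)
  out$statistic <- stat
  out$p_value <- if (is.na(stat)) NA_real_ else
    pchisq(stat, df = k - 1L, lower.tail = FALSE)
  out$observed <- setNames(O, levels(group))
  out$expected <- setNames(E, levels(group))
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  invisible(x)
}
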