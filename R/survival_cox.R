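# Cox proportional-hazards regression: Newton-Raphson maximisation of the
# Efron-corrected partial likelihood, Wald inference, the enter-method
# univariable/multivariable pipeline, and Schoenfeld-residual diagnostics.

# Efron partial log-likelihood, score and information at beta.
.cox_loglik <- function(beta, x, time, event) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)  # process times from largest down
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t_cur <- time[ord[i]]
    # add everyone with this time to the risk set
    j <- i
    while (j <= n && time[ord[j]] == t_cur) {
      k <- ord[j]
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * x[k, ]
      S2 <- S2 + w[k] * tcrossprod(x[k, ])
      j <- j + 1L
    }
    dead <- ord[i:(j - 1L)][event[ord[i:(j - 1L)]]]
    d <- length(dead)
    if (d > 0L) {
      S0D <- sum(w[dead])
      xd <- x[dead, , drop = FALSE]
      S1D <- drop(crossprod(xd, w[dead]))
      S2D <- crossprod(xd * w[dead], xd)
      ll <- ll + sum(eta[dead])
      for (l in seq_len(d) - 1L) {
        phi <- l / d
        s0 <- S0 - phi * S0D
        s1 <- S1 - phi * S1D
        s2 <- S2 - phi * S2D
        ll <- ll - log(s0)
        U <- U - s1 / s0
        I <- I + s2 / s0 - tcrossprod(s1 / s0)
      }
      U <- U + colSums(xd)
    }
    i <- j
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the partial likelihood with the Efron
#' correction for tied event times, Wald confidence intervals and p-values.
#'
#' @param x Covariate matrix (numeric, no constant columns), or a
#'   data.frame whose factors are expanded by reference-level dummy coding.
#' @param time,event Follow-up times and event indicators.
#' @param max_iter Newton iteration cap (a fit that has not converged is
#'   flagged and reports no hazard ratios).
#' @param tol Convergence tolerance on the score norm.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `cox_fit`: `coefficients`, `hr`, `se`, `ci`
#'   (matrix lower/upper), `z`, `p_value`, `loglik` (null and fitted),
#'   `vcov`, `converged`, `iter`, `n`, `n_event`, `ties = "efron"`.
#' @export
cox_fit <- function(x, time, event, max_iter = 100L, tol = 1e-9,
                    conf_level = 0.95) {
  if (is.data.frame(x)) {
    mm <- stats::model.matrix(~ ., data = x)
    x <- mm[, -1L, drop = FALSE]
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  event <- as.logical(event)
  if (any(time < 0)) stop("negative survival time")
  const <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  if (sum(event) < ncol(x))
    stop("fewer events than covariates")
  # centre covariates for numerical stability; beta is unaffected
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)

  p <- ncol(x)
  beta <- numeric(p)
  ev0 <- .cox_loglik(beta, xc, time, event)
  ll_null <- ev0$loglik
  ll <- ll_null; ev <- ev0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) NULL)
    if (is.null(step)) break
    newbeta <- beta + step
    newev <- .cox_loglik(newbeta, xc, time, event)
    halves <- 0L
    while ((!is.finite(newev$loglik) || newev$loglik < ll - 1e-12) &&
           halves < 20L) {
      step <- step / 2
      newbeta <- beta + step
      newev <- .cox_loglik(newbeta, xc, time, event)
      halves <- halves + 1L
    }
    beta <- newbeta; ev <- newev
    if (sqrt(sum(ev$score^2)) < tol ||
        abs(newev$loglik - ll) < tol * (abs(ll) + tol)) {
      ll <- newev$loglik
      converged <- TRUE
      break
    }
    ll <- newev$loglik
  }
  if (any(abs(beta) > 15))
    warning("possible separation: very large coefficient(s)")
  vcov <- tryCatch(solve(ev$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  zq <- qnorm(1 - (1 - conf_level) / 2)
  names(beta) <- names(se) <- colnames(x)
  out <- list(
    coefficients = beta,
    hr = if (converged) exp(beta) else setNames(rep(NA_real_, p), names(beta)),
    se = se,
    ci = cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se)),
    z = z,
    p_value = 2 * pnorm(-abs(z)),
    loglik = c(null = ll_null, fitted = ll),
    vcov = vcov,
    converged = converged,
    iter = iter,
    n = nrow(x), n_event = sum(event),
    ties = "efron",
    conf_level = conf_level,
    x = x, time = time, event = event
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties): n = %d, events = %d%s\n",
              x$n, x$n_event,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (x$converged) {
    tab <- data.frame(coef = round(x$coefficients, 4),
                      HR = round(x$hr, 3),
                      lower = round(x$ci[, "lower"], 3),
                      upper = round(x$ci[, "upper"], 3),
                      p = signif(x$p_value, 3))
    print(tab)
  }
  invisible(x)
}

#' Subtype factor with CMS2-like reference
#'
#' Orders subtype labels so that CMS2-like (the best-prognosis group) is
#' the reference level in regression contrasts.
#'
#' @param labels Character vector of subtype labels.
#' @return Factor with levels CMS2-like, CMS1-like, CMS3-like, CMS4-like.
#' @export
subtype_factor <- function(labels) {
  factor(labels, levels = c("CMS2-like", "CMS1-like", "CMS3-like",
                            "CMS4-like"))
}

#' Enter-method univariable/multivariable Cox pipeline
#'
#' Fits one univariable Cox model per candidate variable; variables where
#' any level reaches a Wald p-value at or below `alpha` are entered jointly
#' into the multivariable model (the "enter" method: all selected
#' covariates simultaneously, no stepwise removal).
#'
#' @param data data.frame of candidate covariates (factors allowed).
#' @param time,event Follow-up times and event indicators.
#' @param vars Candidate variable names (default: all columns of `data`).
#' @param alpha Univariable selection threshold, default 0.05.
#' @return List of class `enter_method`: `univariable` (named list of
#'   `cox_fit`), `selected` (character), `multivariable` (`cox_fit` or NULL
#'   when nothing was selected), and `table` (one row per non-reference
#'   level: variable, level, univariable HR/CI/p and multivariable HR/CI/p
#'   where entered).
#' @export
enter_method_pipeline <- function(data, time, event, vars = names(data),
                                  alpha = 0.05) {
  stopifnot(all(vars %in% names(data)))
  uni <- list()
  selected <- character(0)
  for (v in vars) {
    fit <- tryCatch(cox_fit(data[, v, drop = FALSE], time, event),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("univariable fit failed for '", v, "': ",
              conditionMessage(fit))
      next
    }
    uni[[v]] <- fit
    if (fit$converged && any(fit$p_value <= alpha, na.rm = TRUE))
      selected <- c(selected, v)
  }
  multi <- NULL
  if (length(selected)) {
    multi <- cox_fit(data[, selected, drop = FALSE], time, event)
  } else {
    message("no variable significant univariably; multivariable step skipped")
  }
  rows <- list()
  for (v in names(uni)) {
    fit <- uni[[v]]
    for (term in names(fit$coefficients)) {
      mrow <- if (!is.null(multi) && term %in% names(multi$coefficients)) {
        c(multi$hr[term], multi$ci[term, ], multi$p_value[term])
      } else rep(NA_real_, 4)
      rows[[paste(v, term)]] <- data.frame(
        variable = v, term = term,
        hr_uni = fit$hr[term], lower_uni = fit$ci[term, "lower"],
        upper_uni = fit$ci[term, "upper"], p_uni = fit$p_value[term],
        hr_multi = mrow[1], lower_multi = mrow[2], upper_multi = mrow[3],
        p_multi = mrow[4], stringsAsFactors = FALSE)
    }
  }
  structure(list(univariable = uni, selected = selected,
                 multivariable = multi,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "enter_method")
}

#' @export
print.enter_method <- function(x, ...) {
  cat("Enter-method Cox pipeline; selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Schoenfeld-residual proportional-hazards check
#'
#' Scaled Schoenfeld residuals at event times plus a Pearson
#' correlation-with-time test per covariate. By default time is transformed
#' through one minus the pooled Kaplan-Meier estimate; `transform =
#' "identity"` uses raw time.
#'
#' @param fit A converged [cox_fit()] with at least two events.
#' @param transform `"km"` or `"identity"`.
#' @return List of class `schoenfeld_check`: `time` (event times),
#'   `residuals` (scaled, events x covariates), `correlation` and `p_value`
#'   per covariate, `transform`.
#' @export
schoenfeld_check <- function(fit, transform = c("km", "identity")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (!fit$converged) stop("fit did not converge")
  if (fit$n_event < 2L) {
    message("fewer than 2 events; check skipped")
    return(invisible(NULL))
  }
  x <- fit$x; time <- fit$time; event <- fit$event
  beta <- fit$coefficients
  w <- exp(drop(x %*% beta))
  ev_idx <- which(event)
  ev_idx <- ev_idx[order(time[ev_idx])]
  p <- ncol(x)
  resid <- matrix(NA_real_, length(ev_idx), p,
                  dimnames = list(NULL, colnames(x)))
  for (r in seq_along(ev_idx)) {
    i <- ev_idx[r]
    at_risk <- time >= time[i]
    s0 <- sum(w[at_risk])
    s1 <- drop(crossprod(x[at_risk, , drop = FALSE], w[at_risk]))
    resid[r, ] <- x[i, ] - s1 / s0
  }
  m <- length(ev_idx)
  scaled <- resid %*% (m * fit$vcov) +
    matrix(beta, m, p, byrow = TRUE)
  tt <- time[ev_idx]
  g <- if (transform == "km") {
    km <- km_estimate(time, event)
    1 - survival_at(km, tt)$surv
  } else tt
  corr <- pval <- setNames(numeric(p), colnames(x))
  for (j in seq_len(p)) {
    ct <- stats::cor.test(g, scaled[, j], method = "pearson")
    corr[j] <- unname(ct$estimate)
    pval[j] <- ct$p.value
  }
  structure(list(time = tt, residuals = scaled, correlation = corr,
                 p_value = pval, transform = transform),
            class = "schoenfeld_check")
}

#' @export
print.schoenfeld_check <- function(x, ...) {
  cat("Schoenfeld PH check (", x$transform, " time):\n", sep = "")
  print(data.frame(covariate = names(x$correlation),
                   correlation = round(x$correlation, 4),
                   p = signif(x$p_value, 3)), row.names = FALSE)
  invisible(x)
}
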