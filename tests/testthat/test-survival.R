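# The Cox/KM/log-rank implementations are checked against closed forms, a
# brute-force partial-likelihood grid, a permutation oracle, and the
# survival package as an independent reference.

test_that("endpoint derivation separates OS from disease-specific survival", {
  rec <- data.frame(os_time = c(2, 3, 5),
                    os_event = c(TRUE, TRUE, FALSE),
                    dss_event = c(TRUE, FALSE, FALSE))
  ep <- derive_endpoints(rec)
  expect_equal(ep$os$event, c(TRUE, TRUE, FALSE))
  # non-CRC death is censored for DSS at the same time
  expect_equal(ep$dss$event, c(TRUE, FALSE, FALSE))
  expect_equal(ep$dss$time, ep$os$time)
  expect_error(derive_endpoints(data.frame(os_time = -1, os_event = TRUE,
                                           dss_event = TRUE)), "negative")
  expect_error(derive_endpoints(data.frame(os_time = 1, os_event = FALSE,
                                           dss_event = TRUE)), "subset")
})

test_that("Kaplan-Meier matches hand computation and closed forms", {
  d <- hand_km_data()
  km <- km_estimate(d$time, d$event)
  expect_equal(survival_at(km, 2)$surv, 0.5)
  expect_equal(survival_at(km, 4)$surv, 0)
  expect_equal(survival_at(km, 0.5)$surv, 1)
  # survival is non-increasing and starts at 1
  expect_true(all(diff(km$surv) <= 0))
  expect_lte(km$surv[1], 1)

  # no events: flat at 1
  km1 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_equal(survival_at(km1, 10)$surv, 1)

  # no censoring: equals the empirical survival function
  set.seed(51)
  t <- rexp(200)
  km2 <- km_estimate(t, rep(TRUE, 200))
  ts <- quantile(t, c(0.25, 0.5, 0.9))
  expect_equal(survival_at(km2, ts)$surv, unname(vapply(ts, function(u)
    mean(t > u), numeric(1))), tolerance = 1e-12)
  expect_error(km_estimate(c(0, 0), c(TRUE, TRUE)), "zero")
})

test_that("Kaplan-Meier estimate and log-scale CI match the survival package", {
  skip_if_not_installed("survival")
  set.seed(52)
  t <- round(rexp(150, 0.2), 1) + 0.1
  ev <- runif(150) < 0.6
  km <- km_estimate(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1, conf.type = "log")
  i <- which(sf$n.event > 0)
  expect_equal(km$surv, sf$surv[i], tolerance = 1e-12)
  expect_equal(km$lower, ifelse(is.na(sf$lower[i]), 0, sf$lower[i]),
               tolerance = 1e-10)
  expect_true(all(km$lower <= km$surv + 1e-12 & km$surv <= km$upper + 1e-12))
})

test_that("log-rank: null self-comparison, oracle agreement, permutation check", {
  set.seed(53)
  t <- rexp(40); ev <- runif(40) < 0.8
  # two identical groups built by duplication
  lr0 <- logrank_test(c(t, t), c(ev, ev), rep(c("a", "b"), each = 40))
  expect_equal(lr0$statistic, 0, tolerance = 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-10)

  skip_if_not_installed("survival")
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  lr <- logrank_test(t, ev, g)
  sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)

  # permutation oracle on a small dataset
  set.seed(54)
  t2 <- rexp(20, rate = c(rep(1, 10), rep(2, 10)))
  ev2 <- rep(TRUE, 20)
  g2 <- rep(c("a", "b"), each = 10)
  obs <- logrank_test(t2, ev2, g2)
  perm <- replicate(1500, logrank_test(t2, ev2, sample(g2))$statistic)
  p_perm <- mean(perm >= obs$statistic)
  se <- sqrt(p_perm * (1 - p_perm) / 1500)
  expect_lt(abs(obs$p_value - p_perm), 0.04 + 3 * se)
})

test_that("Cox fit matches a brute-force grid oracle on a tiny dataset", {
  set.seed(55)
  n <- 18
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.5 * exp(0.8 * x))
  ev <- rep(TRUE, n)
  fit <- cox_fit(matrix(x, ncol = 1), t, ev)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, grid_cox_loglik, numeric(1), x = x, time = t,
               event = ev)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)],
               tolerance = 1e-4)
  expect_equal(unname(fit$loglik["fitted"]), max(ll), tolerance = 1e-6)
})

test_that("Cox fit agrees with coxph under Efron ties and flags bad inputs", {
  skip_if_not_installed("survival")
  set.seed(56)
  n <- 250
  x <- cbind(age = rnorm(n), grp = rbinom(n, 1, 0.4))
  t <- round(rexp(n, 0.1 * exp(0.4 * x[, 1] - 0.5 * x[, 2])), 1) + 0.05
  ev <- runif(n) < 0.7
  fit <- cox_fit(x, t, ev)
  or <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "efron")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(or)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(or)))),
               tolerance = 1e-6)
  expect_equal(unname(fit$hr), unname(exp(coef(or))), tolerance = 1e-6)

  expect_error(cox_fit(matrix(1, n, 1), t, ev), "constant")
  expect_error(cox_fit(x, t, rep(FALSE, n)), "fewer events")
  expect_error(cox_fit(x, -t, ev), "negative")
})

test_that("factor covariates use reference coding with CMS2-like reference", {
  set.seed(57)
  coh <- generate_cohort(cohort_config(n_patients = 400, seed = 57))
  calls <- classify_cohort(coh$patients, coh$spots, coh$bcat)
  keep <- calls$label != "unclassified"
  df <- data.frame(subtype = subtype_factor(calls$label[keep]))
  p <- coh$patients[keep, ]
  fit <- cox_fit(df, p$os_time, p$os_event)
  expect_true(fit$converged)
  expect_named(fit$coefficients, c("subtypeCMS1-like", "subtypeCMS3-like",
                                   "subtypeCMS4-like"))
})

test_that("enter-method pipeline selects and jointly fits significant variables", {
  set.seed(58)
  n <- 500
  grp <- factor(rbinom(n, 1, 0.5), labels = c("a", "b"))
  age <- rnorm(n)
  noise <- factor(rbinom(n, 1, 0.5), labels = c("x", "y"))
  t <- rexp(n, 0.1 * exp(0.8 * (grp == "b") + 0.5 * age))
  ev <- runif(n) < 0.8
  em <- enter_method_pipeline(data.frame(grp = grp, age = age,
                                         noise = noise), t, ev)
  expect_true(all(c("grp", "age") %in% em$selected))
  expect_false("noise" %in% em$selected)
  expect_true(!is.null(em$multivariable))
  # one table row per non-reference level of every candidate
  expect_equal(nrow(em$table), 3)
  expect_true(all(is.na(em$table$hr_multi[em$table$variable == "noise"])))

  # null data: selection usually empty, multivariable skipped
  set.seed(59)
  t0 <- rexp(150, 0.2); ev0 <- runif(150) < 0.7
  x0 <- data.frame(a = rnorm(150), b = factor(rbinom(150, 1, 0.5)))
  em0 <- suppressMessages(enter_method_pipeline(x0, t0, ev0))
  expect_true(is.null(em0$multivariable) || length(em0$selected) >= 1)
})

test_that("Schoenfeld residuals: structure and sensitivity to non-proportionality", {
  set.seed(60)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.2 * exp(0.5 * x))
  ev <- runif(n) < 0.8
  fit <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")), t, ev)
  sc <- schoenfeld_check(fit)
  expect_equal(nrow(sc$residuals), fit$n_event)
  expect_equal(length(sc$time), fit$n_event)
  expect_true(all(diff(sc$time) >= 0))

  # strongly time-varying effect: the exposed group's hazard is high early
  # and low late (event times stretched past t = 1), violating PH
  x1 <- rep(c(1, 0), each = 150)
  sig <- vapply(1:20, function(s) {
    set.seed(600 + s)
    u <- rexp(300, 0.5)
    tv <- ifelse(x1 == 1 & u > 1, 1 + (u - 1) * 4, u)
    f <- cox_fit(matrix(x1, ncol = 1), tv, rep(TRUE, 300))
    schoenfeld_check(f)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})
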