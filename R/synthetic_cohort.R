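# Synthetic cohort generator.
#
# Emulates a TMA-based CRC cohort with four latent subtypes: per-subtype
# marker score distributions with epithelial vs mesenchymal directionality
# (CMS4-like: low CDX2/KER, ZEB1 present, high HTR2B/FRMD6; CMS1/2/3-like
# the converse), beta-catenin nuclear positivity concentrated in CMS2-like,
# mismatch-repair deficiency concentrated in CMS1-like, clinicopathological
# covariates drawn from subtype-conditional distributions, and
# proportional-hazards survival with subtype-specific log hazard ratios.

.default_marker_params <- function() {
  epi <- list(
    cdx2 = list(intensity = c(2.5, 0.35), pct = c(85, 8)),
    frmd6 = list(intensity = c(0.6, 0.35), pct = c(15, 8)),
    htr2b = list(intensity = c(0.6, 0.35)),
    ker = list(intensity = c(2.5, 0.35), pct = c(85, 8)),
    zeb1 = list(pct = c(0.5, 0.6))
  )
  mes <- list(
    cdx2 = list(intensity = c(0.7, 0.35), pct = c(25, 10)),
    frmd6 = list(intensity = c(2.2, 0.35), pct = c(70, 10)),
    htr2b = list(intensity = c(2.2, 0.35)),
    ker = list(intensity = c(0.8, 0.35), pct = c(30, 10)),
    zeb1 = list(pct = c(10, 5))
  )
  list(CMS1L = epi, CMS2L = epi, CMS3L = epi, CMS4L = mes)
}

.default_bcat_params <- function() {
  list(
    CMS1L = list(intensity = c(0.30, 0.30, 0.30, 0.10),
                 pct = c(0.30, 0.30, 0.20, 0.15, 0.05)),
    CMS2L = list(intensity = c(0.02, 0.08, 0.50, 0.40),
                 pct = c(0.05, 0.15, 0.40, 0.30, 0.10)),
    CMS3L = list(intensity = c(0.60, 0.35, 0.04, 0.01),
                 pct = c(0.60, 0.35, 0.04, 0.01, 0.00)),
    CMS4L = list(intensity = c(0.30, 0.40, 0.20, 0.10),
                 pct = c(0.30, 0.40, 0.20, 0.08, 0.02))
  )
}

# Subtype-conditional clinicopathological distributions (defaults follow the
# column percentages of the source cohort's association table).
.default_clinical_params <- function() {
  norm <- function(m) sweep(m, 1L, rowSums(m), "/")
  list(
    age_ge69 = c(0.500, 0.446, 0.600, 0.462),
    male = c(0.461, 0.536, 0.551, 0.538),
    stage = norm(rbind(c(0.118, 0.329, 0.355, 0.197),
                       c(0.222, 0.317, 0.335, 0.126),
                       c(0.200, 0.281, 0.341, 0.178),
                       c(0.135, 0.250, 0.442, 0.173))),
    pT = norm(rbind(c(0.001, 0.151, 0.712, 0.137),
                    c(0.060, 0.211, 0.663, 0.066),
                    c(0.044, 0.236, 0.615, 0.104),
                    c(0.038, 0.154, 0.673, 0.135))),
    pN = norm(rbind(c(0.500, 0.311, 0.189),
                    c(0.564, 0.283, 0.157),
                    c(0.525, 0.293, 0.182),
                    c(0.423, 0.212, 0.365))),
    grade_high = c(0.208, 0.093, 0.102, 0.157),
    location = norm(rbind(c(0.605, 0.132, 0.263),
                          c(0.173, 0.315, 0.512),
                          c(0.292, 0.243, 0.465),
                          c(0.231, 0.135, 0.635))),
    mucinous = c(0.157, 0.014, 0.075, 0.102)
  )
}

#' Default survival-generator parameters
#'
#' Exponential baseline (Weibull shape 1) with a yearly baseline hazard
#' giving roughly 60% five-year survival in the reference (CMS2-like) group,
#' subtype log hazard ratios matching published univariable effect sizes
#' (CMS1-like exp(0.451), CMS3-like and CMS4-like exp(0.372), CMS2-like
#' reference), independent exponential censoring targeting the given
#' censoring fraction, administrative censoring at the follow-up horizon,
#' and Bernoulli cause-of-death attribution for the disease-specific
#' endpoint.
#'
#' @return Named list of parameters (see [generate_survival()]).
#' @export
default_survival_params <- function() {
  list(
    baseline_hazard = 0.102,
    weibull_shape = 1,
    log_hr = c(CMS1L = log(1.57), CMS2L = 0, CMS3L = log(1.45),
               CMS4L = log(1.45)),
    censoring_rate = 0.25,
    horizon = 15,
    dss_given_os = 0.6
  )
}

#' Synthetic cohort configuration
#'
#' @param n_patients Number of patients (> 0).
#' @param subtype_prevalence Length-4 probability vector over the latent
#'   subtypes CMS1-like..CMS4-like; must sum to 1. The default is the
#'   classified-cohort distribution of the source series.
#' @param spots_per_patient TMA spots punched per tumor, 1-4.
#' @param spot_dropout_prob Probability that an individual spot is lost
#'   (at least one spot is always retained).
#' @param marker_params Per-subtype location/spread of each marker's
#'   continuous intensity (0-3) and percent positive (0-100); see
#'   `cmsihc:::.default_marker_params` for the layout.
#' @param bcat_params Per-subtype categorical distributions over
#'   beta-catenin nuclear intensity (0-3) and percent category (0-4).
#' @param mmr_deficiency_prob Per-subtype probability of deficient mismatch
#'   repair (near 1 for CMS1-like, near 0 otherwise).
#' @param clinical_params Subtype-conditional covariate distributions.
#' @param survival_params See [default_survival_params()].
#' @param seed Integer seed driving every draw.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 538,
                          subtype_prevalence = c(0.158, 0.349, 0.385, 0.108),
                          spots_per_patient = 4L,
                          spot_dropout_prob = 0.05,
                          marker_params = .default_marker_params(),
                          bcat_params = .default_bcat_params(),
                          mmr_deficiency_prob = c(0.95, 0.02, 0.02, 0.02),
                          clinical_params = .default_clinical_params(),
                          survival_params = default_survival_params(),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients <= 0)
    .stop_config("n_patients must be a positive integer")
  .check_simplex(subtype_prevalence, "subtype_prevalence")
  if (!spots_per_patient %in% 1:4)
    .stop_config("spots_per_patient must be in {1, 2, 3, 4}")
  .check_prob(spot_dropout_prob, "spot_dropout_prob")
  .check_prob(mmr_deficiency_prob, "mmr_deficiency_prob")
  if (length(mmr_deficiency_prob) != 4L)
    .stop_config("mmr_deficiency_prob must have one entry per subtype")
  if (any(unlist(survival_params[c("baseline_hazard", "weibull_shape")]) <= 0))
    .stop_config("baseline hazard and shape must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    subtype_prevalence = subtype_prevalence,
    spots_per_patient = as.integer(spots_per_patient),
    spot_dropout_prob = spot_dropout_prob,
    marker_params = marker_params,
    bcat_params = bcat_params,
    mmr_deficiency_prob = mmr_deficiency_prob,
    clinical_params = clinical_params,
    survival_params = survival_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_patients, "patients,",
      x$spots_per_patient, "spots/patient\n")
  cat("  prevalence:", paste(sprintf("%s %.3f", .subtype_labels,
                                     x$subtype_prevalence), collapse = ", "),
      "\n  seed:", x$seed, "\n")
  invisible(x)
}

.draw_spot_panels <- function(subtype, n_spots, mp) {
  p <- mp[[subtype]]
  draw_int <- function(par) .rtruncnorm(n_spots, par[1], par[2], 0, 3)
  draw_pct <- function(par) .rtruncnorm(n_spots, par[1], par[2], 0, 100)
  cont <- data.frame(
    cdx2_intensity_cont = draw_int(p$cdx2$intensity),
    cdx2_pct = draw_pct(p$cdx2$pct),
    frmd6_intensity_cont = draw_int(p$frmd6$intensity),
    frmd6_pct = draw_pct(p$frmd6$pct),
    htr2b_intensity_cont = draw_int(p$htr2b$intensity),
    ker_intensity_cont = draw_int(p$ker$intensity),
    ker_pct = draw_pct(p$ker$pct),
    zeb1_pct = draw_pct(p$zeb1$pct)
  )
  cont$cdx2_intensity <- round_intensity(cont$cdx2_intensity_cont)
  cont$frmd6_intensity <- round_intensity(cont$frmd6_intensity_cont)
  cont$htr2b_intensity <- round_intensity(cont$htr2b_intensity_cont)
  cont$ker_intensity <- round_intensity(cont$ker_intensity_cont)
  cont
}

.draw_clinical <- function(idx, cp) {
  n <- length(idx)
  stage <- .sample_categorical(cp$stage[idx, , drop = FALSE],
                               c("I", "II", "III", "IV"))
  data.frame(
    age_group = ifelse(runif(n) < cp$age_ge69[idx], ">=69", "<69"),
    sex = ifelse(runif(n) < cp$male[idx], "male", "female"),
    stage = stage,
    pT = as.integer(.sample_categorical(cp$pT[idx, , drop = FALSE],
                                        c("1", "2", "3", "4"))),
    pN = as.integer(.sample_categorical(cp$pN[idx, , drop = FALSE],
                                        c("0", "1", "2"))),
    pM = as.integer(stage == "IV"),
    grade = ifelse(runif(n) < cp$grade_high[idx], "high", "low"),
    location = .sample_categorical(cp$location[idx, , drop = FALSE],
                                   c("right colon", "left colon", "rectum")),
    histology = ifelse(runif(n) < cp$mucinous[idx], "mucinous",
                       "non-mucinous"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Draws latent subtypes, clinicopathological covariates, MMR status,
#' per-spot five-marker panels (continuous intensities on the 0-3 scale plus
#' their rounded integer values), per-spot beta-catenin scores, and
#' proportional-hazards survival. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List: `patients` (one row per patient, including `latent_subtype`
#'   ground truth, covariates, `mmr_deficient`, `os_time`, `os_event`,
#'   `dss_event`), `spots` (one row per retained spot), `bcat` (one row per
#'   retained spot), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, {
    n <- config$n_patients
    subtype <- .subtypes[
      .sample_categorical(matrix(config$subtype_prevalence, n, 4,
                                 byrow = TRUE), 1:4)]
    idx <- match(subtype, .subtypes)
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      latent_subtype = subtype,
      stringsAsFactors = FALSE
    )
    patients <- cbind(patients, .draw_clinical(idx, config$clinical_params))
    patients$mmr_deficient <- runif(n) < config$mmr_deficiency_prob[idx]

    # spot retention: per-spot dropout, at least one spot kept
    kept <- lapply(seq_len(n), function(i) {
      k <- which(runif(config$spots_per_patient) >= config$spot_dropout_prob)
      if (!length(k)) k <- 1L
      k
    })
    spots <- do.call(rbind, lapply(seq_len(n), function(i) {
      ki <- kept[[i]]
      cbind(data.frame(patient_id = patients$patient_id[i],
                       spot_index = ki, stringsAsFactors = FALSE),
            .draw_spot_panels(subtype[i], length(ki), config$marker_params))
    }))
    bcat <- do.call(rbind, lapply(seq_len(n), function(i) {
      ki <- kept[[i]]
      bp <- config$bcat_params[[subtype[i]]]
      data.frame(
        patient_id = patients$patient_id[i], spot_index = ki,
        nuclear_intensity = sample(0:3, length(ki), replace = TRUE,
                                   prob = bp$intensity),
        nuclear_pct_category = sample(0:4, length(ki), replace = TRUE,
                                      prob = bp$pct),
        stringsAsFactors = FALSE
      )
    }))
    rownames(spots) <- rownames(bcat) <- NULL
    patients <- generate_survival(patients, config$survival_params,
                                  seed = NULL)
    list(patients = patients, spots = spots, bcat = bcat, config = config)
  })
}

#' Fill survival records under a proportional-hazards model
#'
#' Event times follow a Weibull proportional-hazards model with
#' subtype-specific log hazard ratios over a baseline hazard; censoring is
#' an independent exponential whose rate is chosen so that roughly
#' `censoring_rate` of reference-group subjects are censored before their
#' event (`censoring_rate = 1` censors everyone at time zero,
#' `censoring_rate = 0` leaves administrative censoring at the horizon
#' only). A disease-specific event is attributed to each any-cause event
#' with probability `dss_given_os`, so disease-specific events are a subset
#' of overall events.
#'
#' @param patients data.frame with a `latent_subtype` column.
#' @param params List as from [default_survival_params()].
#' @param seed Optional integer seed (NULL continues the caller's stream).
#' @return `patients` with `os_time`, `os_event`, `dss_event` columns.
#' @export
generate_survival <- function(patients, params = default_survival_params(),
                              seed = NULL) {
  stopifnot(is.data.frame(patients), "latent_subtype" %in% names(patients))
  if (params$baseline_hazard <= 0 || params$weibull_shape <= 0)
    .stop_config("baseline hazard and Weibull shape must be positive")
  if (any(!is.finite(params$log_hr)))
    .stop_config("log hazard ratios must be finite")
  .check_prob(params$censoring_rate, "censoring_rate")
  .check_prob(params$dss_given_os, "dss_given_os")
  .with_seed(seed, {
    n <- nrow(patients)
    lhr <- params$log_hr[patients$latent_subtype]
    if (anyNA(lhr)) .stop_config("log_hr must cover every latent subtype")
    # inverse-CDF Weibull PH draw: S(t) = exp(-lambda * exp(x'b) * t^shape)
    u <- runif(n)
    t_event <- (-log(u) / (params$baseline_hazard * exp(lhr)))^
      (1 / params$weibull_shape)
    cr <- params$censoring_rate
    c_time <- if (cr >= 1) rep(0, n)
      else if (cr <= 0) rep(Inf, n)
      else rexp(n, rate = params$baseline_hazard * cr / (1 - cr))
    c_time <- pmin(c_time, params$horizon)
    patients$os_time <- pmin(t_event, c_time)
    patients$os_event <- t_event <= c_time
    patients$dss_event <- patients$os_event &
      (runif(n) < params$dss_given_os)
    patients
  })
}
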