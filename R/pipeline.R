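# End-to-end pipeline driver: simulate -> quantify -> classify ->
# associate -> survive -> validate, with stage selection, structured logs
# on stderr, and a JSON run manifest.

.log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_patients Cohort size for the simulate stage.
#' @param outdir Output directory.
#' @return Config list (serialisable to JSON).
#' @export
default_pipeline_config <- function(seed = 1L, n_patients = 538L,
                                    outdir = "cmsihc_out") {
  list(seed = as.integer(seed), n_patients = as.integer(n_patients),
       outdir = outdir,
       quantify = list(n_images = 4L, dab_levels = c(0, 1, 2, 3)),
       validate = list(n_regions = 10L, n_validators = 3L,
                       boundary_jitter = 1.5),
       associate = list(vars = c("age_group", "sex", "stage", "pT", "pN",
                                 "pM", "grade", "location", "histology")))
}

.read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    user <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- modifyList(default_pipeline_config(), user)
  }
  if (!is.list(config) || is.null(config$seed))
    stop("config must be a list (or JSON path) with a 'seed' field")
  config
}

#' Run the full pipeline
#'
#' Runs the requested stages in dependency order on a synthetic cohort:
#' `simulate` writes patient/spot/beta-catenin tables; `quantify` generates
#' and scores synthetic spot images; `classify` applies the hierarchical
#' classifier; `associate` runs the covariate association scan; `survive`
#' fits Kaplan-Meier curves, log-rank tests and the enter-method Cox
#' pipeline; `validate` compares segmentation masks against simulated
#' annotators. A JSON manifest with the config snapshot, seed and output
#' hashes is always written.
#'
#' @param config Config list or path to a JSON config (see
#'   [default_pipeline_config()]).
#' @param stages Stage subset to run.
#' @param outdir Output directory override.
#' @return Named list of per-stage outputs (paths and key summaries),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("simulate", "quantify", "classify",
                                    "associate", "survive", "validate"),
                         outdir = NULL) {
  config <- .read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$outdir, f)
  outputs <- character(0)
  results <- list()

  if ("simulate" %in% stages) {
    .log("INFO", "simulate: n = %d, seed = %d", config$n_patients,
         config$seed)
    cc <- cohort_config(n_patients = config$n_patients, seed = config$seed)
    cohort <- generate_cohort(cc)
    write_table_csv(cohort$patients, pth("patients.csv"), config)
    write_table_csv(cohort$spots, pth("spots.csv"), config)
    write_table_csv(cohort$bcat, pth("bcat.csv"), config)
    outputs <- c(outputs, pth("patients.csv"), pth("spots.csv"),
                 pth("bcat.csv"))
    results$simulate <- cohort
  }

  if ("quantify" %in% stages) {
    .log("INFO", "quantify: %d synthetic spot images",
         length(config$quantify$dab_levels))
    rows <- lapply(seq_along(config$quantify$dab_levels), function(i) {
      lv <- config$quantify$dab_levels[i]
      spec <- image_spec(dab_intensity_level = lv,
                         seed = config$seed + i)
      gen <- generate_spot_image(spec)
      q <- quantify_spot(gen$image)
      data.frame(image = i, dab_level = lv,
                 continuous_intensity = q$continuous_intensity,
                 rounded_intensity = q$rounded_intensity,
                 percent_positive = q$percent_positive,
                 truth_percent = gen$truth$percent_positive,
                 area = q$area_analyzed)
    })
    qdf <- do.call(rbind, rows)
    write_table_csv(qdf, pth("quant.csv"), config)
    outputs <- c(outputs, pth("quant.csv"))
    results$quantify <- qdf
  }

  if ("classify" %in% stages) {
    patients <- read_validated_table(pth("patients.csv"), "patients")
    spots <- read_validated_table(pth("spots.csv"), "spots")
    bcat <- read_validated_table(pth("bcat.csv"), "bcat")
    .log("INFO", "classify: %d patients", nrow(patients))
    calls <- classify_cohort(patients, spots, bcat)
    write_table_csv(calls, pth("calls.csv"), config)
    rep <- cohort_classification_report(calls)
    jsonlite::write_json(rep, pth("classification_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(outputs, pth("calls.csv"),
                 pth("classification_summary.json"))
    results$classify <- list(calls = calls, report = rep)
  }

  if ("associate" %in% stages) {
    patients <- read_validated_table(pth("patients.csv"), "patients")
    calls <- read_validated_table(pth("calls.csv"), "calls")
    .log("INFO", "associate: %d covariates",
         length(config$associate$vars))
    rep <- table1_report(patients, calls,
                         vars = intersect(config$associate$vars,
                                          names(patients)),
                         seed = config$seed)
    write_table_csv(rep$summary, pth("associations.csv"), config)
    outputs <- c(outputs, pth("associations.csv"))
    results$associate <- rep
  }

  if ("survive" %in% stages) {
    patients <- read_validated_table(pth("patients.csv"), "patients")
    calls <- read_validated_table(pth("calls.csv"), "calls")
    lab <- calls$label[match(patients$patient_id, calls$patient_id)]
    keep <- lab %in% .subtype_labels
    .log("INFO", "survive: %d classified patients", sum(keep))
    ep <- derive_endpoints(patients[keep, ])
    grp <- subtype_factor(lab[keep])
    lr <- logrank_test(ep$os$time, ep$os$event, grp)
    km5 <- lapply(split(seq_along(grp), grp), function(ix) {
      cv <- km_estimate(ep$os$time[ix], ep$os$event[ix])
      survival_at(cv, 5)
    })
    cox_df <- data.frame(subtype = grp,
                         age_group = patients$age_group[keep],
                         stage = patients$stage[keep],
                         stringsAsFactors = TRUE)
    em <- enter_method_pipeline(cox_df, ep$os$time, ep$os$event)
    write_table_csv(em$table, pth("cox_os.csv"), config)
    surv_json <- list(
      logrank = list(statistic = lr$statistic, df = lr$df,
                     p_value = lr$p_value),
      five_year_os = lapply(km5, function(d) as.list(d[1, -1])),
      selected = em$selected
    )
    jsonlite::write_json(surv_json, pth("survival_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(outputs, pth("cox_os.csv"), pth("survival_summary.json"))
    results$survive <- list(logrank = lr, five_year_os = km5,
                            enter_method = em)
  }

  if ("validate" %in% stages) {
    nv <- config$validate$n_validators
    .log("INFO", "validate: %d regions x %d validators",
         config$validate$n_regions, nv)
    regions <- lapply(seq_len(config$validate$n_regions), function(i) {
      gen <- generate_spot_image(image_spec(seed = config$seed + 100L + i))
      model_mask <- segment_epithelium(gen$image)
      validators <- setNames(lapply(seq_len(nv), function(v)
        perturb_annotation(gen$mask, config$validate$boundary_jitter,
                           seed = config$seed + 1000L + i * 10L + v)),
        paste0("validator", seq_len(nv)))
      q <- quantify_spot(gen$image)
      list(model = model_mask, validators = validators,
           model_score = q$rounded_intensity,
           validator_scores = setNames(
             as.list(rep(gen$truth$rounded_intensity, nv)),
             paste0("validator", seq_len(nv))))
    })
    vrep <- validation_report(regions)
    jsonlite::write_json(
      list(model_vs_validator = vrep$model_vs_validator,
           validator_vs_validator = vrep$validator_vs_validator,
           matching_intensity_model_validator =
             vrep$matching_intensity_model_validator,
           matching_intensity_between_validators =
             vrep$matching_intensity_between_validators),
      pth("validation_report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    outputs <- c(outputs, pth("validation_report.json"))
    results$validate <- vrep
  }

  write_manifest(config, outputs, pth("manifest.json"))
  .log("INFO", "done: %d outputs in %s", length(outputs), config$outdir)
  invisible(results)
}
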