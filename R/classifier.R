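# Hierarchical CMS-resembling classification:
#   1. dMMR tumors -> CMS1-like (gate; spots and beta-catenin are ignored).
#   2. Five-marker logistic score per TMA spot -> epithelial (E) or
#      mesenchymal (M); majority vote over 1-4 spots, tie -> inconclusive.
#      Majority E -> CMS2/3-like, majority M -> CMS4-like.
#   3. Beta-catenin nuclear positivity splits CMS2/3-like:
#      positive -> CMS2-like, negative -> CMS3-like, tie -> inconclusive.

#' ZEB1 presence call
#'
#' ZEB1 enters the epithelial/mesenchymal classifier as a binary presence
#' indicator rather than a continuous percentage: values below a 2% cut-off
#' are treated as absent to suppress false-positive staining.
#'
#' @param zeb1_pct Percentage of ZEB1-positive epithelial cells, in
#'   \[0, 100\]. Vectorised.
#' @return Logical: `TRUE` when `zeb1_pct >= 2`.
#' @export
#' @examples
#' zeb1_presence(c(0, 1.9, 2, 80))
zeb1_presence <- function(zeb1_pct) {
  if (!is.numeric(zeb1_pct) || anyNA(zeb1_pct) ||
      any(zeb1_pct < 0 | zeb1_pct > 100))
    stop("zeb1_pct must be in [0, 100]")
  zeb1_pct >= 2
}

#' Logistic epithelial-vs-mesenchymal spot model
#'
#' The per-spot classifier is a logistic score over the five-marker panel
#' (CDX2, FRMD6, HTR2B, KER as intensity/percent features, ZEB1 as a presence
#' indicator). The published pipeline delegates this step to an external
#' online tool whose coefficients are not public, so the model here is fully
#' pluggable; the default coefficients fix the signs by marker biology (CDX2
#' and cytokeratin epithelial-positive; FRMD6, HTR2B and ZEB1
#' mesenchymal-positive) with magnitudes calibrated once on the synthetic
#' generator and frozen.
#'
#' @param coefficients Named numeric vector over the feature names
#'   `cdx2_intensity`, `cdx2_pct`, `frmd6_intensity`, `frmd6_pct`,
#'   `htr2b_intensity`, `ker_intensity`, `ker_pct`, `zeb1_present`.
#'   Missing names default to 0.
#' @param intercept Intercept of the linear score.
#' @param threshold Decision threshold on the epithelial probability,
#'   in (0, 1). A probability `>= threshold` is called epithelial.
#' @return A `classifier_model` object.
#' @seealso [spot_epithelial_probability()], [classify_patient()]
#' @export
classifier_model <- function(coefficients = NULL, intercept = 0,
                             threshold = 0.5) {
  feat <- c("cdx2_intensity", "cdx2_pct", "frmd6_intensity", "frmd6_pct",
            "htr2b_intensity", "ker_intensity", "ker_pct", "zeb1_present")
  beta <- setNames(numeric(length(feat)), feat)
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% feat))
      stop("coefficients must be named from: ", paste(feat, collapse = ", "))
    beta[names(coefficients)] <- coefficients
  }
  if (!all(is.finite(beta)) || !is.finite(intercept))
    stop("coefficients and intercept must be finite")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  structure(list(coefficients = beta, intercept = intercept,
                 threshold = threshold),
            class = "classifier_model")
}

#' @rdname classifier_model
#' @export
default_classifier_model <- function() {
  classifier_model(
    coefficients = c(
      cdx2_intensity  =  0.8,  cdx2_pct  =  0.02,
      frmd6_intensity = -0.8,  frmd6_pct = -0.02,
      htr2b_intensity = -0.8,
      ker_intensity   =  0.8,  ker_pct   =  0.02,
      zeb1_present    = -2.0
    ),
    intercept = 0, threshold = 0.5
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("Epithelial/mesenchymal spot classifier (logistic)\n")
  cat("  intercept:", format(x$intercept), " threshold:",
      format(x$threshold), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

.panel_features <- function(panel) {
  need <- c("cdx2_intensity", "cdx2_pct", "frmd6_intensity", "frmd6_pct",
            "htr2b_intensity", "ker_intensity", "ker_pct", "zeb1_pct")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("spot panel is missing fields: ", paste(miss, collapse = ", "))
  vals <- unlist(panel[need], use.names = FALSE)
  if (anyNA(vals)) return(NULL)  # incomplete panel: skip the spot
  c(cdx2_intensity = panel$cdx2_intensity, cdx2_pct = panel$cdx2_pct,
    frmd6_intensity = panel$frmd6_intensity, frmd6_pct = panel$frmd6_pct,
    htr2b_intensity = panel$htr2b_intensity,
    ker_intensity = panel$ker_intensity, ker_pct = panel$ker_pct,
    zeb1_present = as.numeric(zeb1_presence(panel$zeb1_pct)))
}

#' Per-spot epithelial probability
#'
#' @param panel A list or one-row data.frame with the spot's marker scores
#'   (`cdx2_intensity`, `cdx2_pct`, `frmd6_intensity`, `frmd6_pct`,
#'   `htr2b_intensity`, `ker_intensity`, `ker_pct`, `zeb1_pct`).
#' @param model A [classifier_model()].
#' @return Probability in (0, 1) that the spot is epithelial-type, or `NA`
#'   if the panel is incomplete.
#' @export
spot_epithelial_probability <- function(panel, model = default_classifier_model()) {
  stopifnot(inherits(model, "classifier_model"))
  x <- .panel_features(panel)
  if (is.null(x)) return(NA_real_)
  eta <- model$intercept + sum(model$coefficients[names(x)] * x)
  1 / (1 + exp(-eta))
}

#' Epithelial/mesenchymal call from a spot probability
#'
#' Ties at the threshold are resolved to epithelial ("E"); the tie-break is
#' deterministic and configurable through the model threshold.
#'
#' @param prob Epithelial probability (vectorised).
#' @param threshold Decision threshold, default 0.5.
#' @return Character vector of `"E"` / `"M"` (`NA` propagated).
#' @export
classify_spot <- function(prob, threshold = 0.5) {
  ifelse(is.na(prob), NA_character_, ifelse(prob >= threshold, "E", "M"))
}

#' Majority vote over per-spot epithelial/mesenchymal calls
#'
#' The most frequent class across a tumor's 1-4 evaluable spots is chosen;
#' an exact tie is inconclusive and the tumor is excluded downstream.
#'
#' @param calls Character vector of `"E"`/`"M"` calls (NAs dropped).
#' @return `"CMS2/3-like"`, `"CMS4-like"`, `"inconclusive"`, or
#'   `"missing"` when no evaluable call exists.
#' @export
aggregate_spot_calls <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return("missing")
  if (!all(calls %in% c("E", "M"))) stop("calls must be 'E' or 'M'")
  ne <- sum(calls == "E"); nm <- sum(calls == "M")
  if (ne > nm) "CMS2/3-like" else if (nm > ne) "CMS4-like" else "inconclusive"
}

#' Beta-catenin nuclear positivity
#'
#' Nuclear intensity is scored 0-3 (negative/low/moderate/high) and the
#' percentage of positive nuclei as a 0-4 category (0 negative, 1 = 1-10%,
#' 2 = 11-50%, 3 = 51-90%, 4 = >= 90%). A spot is positive when either
#' score is >= 2.
#'
#' @param nuclear_intensity Integer 0-3 (vectorised).
#' @param nuclear_pct_category Integer 0-4 (vectorised).
#' @return Logical positivity call.
#' @export
beta_catenin_call <- function(nuclear_intensity, nuclear_pct_category) {
  if (any(!nuclear_intensity %in% 0:3, na.rm = TRUE))
    stop("nuclear_intensity must be in {0,1,2,3}")
  if (any(!nuclear_pct_category %in% 0:4, na.rm = TRUE))
    stop("nuclear_pct_category must be in {0,1,2,3,4}")
  nuclear_intensity >= 2 | nuclear_pct_category >= 2
}

#' Majority vote over per-spot beta-catenin calls
#'
#' @param calls Logical vector of per-spot positivity (NAs dropped).
#' @return `"positive"`, `"negative"`, `"inconclusive"` (exact tie), or
#'   `"missing"`.
#' @export
aggregate_bcat <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return("missing")
  np <- sum(calls); nn <- sum(!calls)
  if (np > nn) "positive" else if (nn > np) "negative" else "inconclusive"
}

#' Classify one patient
#'
#' Applies the full three-stage rule. Deficient mismatch repair short-circuits
#' to CMS1-like; otherwise the spot vote separates CMS2/3-like from
#' CMS4-like, and the beta-catenin consensus splits CMS2/3-like into
#' CMS2-like (positive) and CMS3-like (negative). Any inconclusive or missing
#' stage yields `"unclassified"` with the stage recorded in the provenance.
#'
#' @param mmr_deficient Logical MMR status (TRUE = deficient).
#' @param spots data.frame of spot marker panels (0-4 rows) with the panel
#'   columns of [spot_epithelial_probability()].
#' @param bcat data.frame of beta-catenin scores (columns
#'   `nuclear_intensity`, `nuclear_pct_category`), may be empty.
#' @param model A [classifier_model()].
#' @return A list of class `subtype_call`: `label`, `stage_provenance`,
#'   `spot_probs`, `spot_calls`, `bcat_consensus`.
#' @export
classify_patient <- function(mmr_deficient, spots = NULL, bcat = NULL,
                             model = default_classifier_model()) {
  .check_flag(mmr_deficient, "mmr_deficient")
  out <- list(label = "unclassified", stage_provenance = NA_character_,
              spot_probs = numeric(0), spot_calls = character(0),
              bcat_consensus = NA_character_)
  class(out) <- "subtype_call"
  if (mmr_deficient) {
    out$label <- "CMS1-like"; out$stage_provenance <- "MMR gate"
    return(out)
  }
  nspots <- if (is.null(spots)) 0L else nrow(spots)
  if (nspots < 1L) {
    out$stage_provenance <- "missing-data"
    return(out)
  }
  probs <- vapply(seq_len(nspots), function(i)
    spot_epithelial_probability(as.list(spots[i, , drop = FALSE]), model),
    numeric(1))
  calls <- classify_spot(probs, model$threshold)
  out$spot_probs <- probs; out$spot_calls <- calls
  vote <- aggregate_spot_calls(calls)
  if (vote == "missing") {
    out$stage_provenance <- "missing-data"; return(out)
  }
  if (vote == "inconclusive") {
    out$stage_provenance <- "inconclusive-at-vote"; return(out)
  }
  if (vote == "CMS4-like") {
    out$label <- "CMS4-like"; out$stage_provenance <- "spot vote"
    return(out)
  }
  # CMS2/3-like: split on beta-catenin consensus
  nb <- if (is.null(bcat)) 0L else nrow(bcat)
  if (nb < 1L) {
    out$stage_provenance <- "missing-data"; return(out)
  }
  bc <- beta_catenin_call(bcat$nuclear_intensity, bcat$nuclear_pct_category)
  cons <- aggregate_bcat(bc)
  out$bcat_consensus <- cons
  if (cons == "missing") {
    out$stage_provenance <- "missing-data"
  } else if (cons == "inconclusive") {
    out$stage_provenance <- "inconclusive-at-bcat"
  } else {
    out$label <- if (cons == "positive") "CMS2-like" else "CMS3-like"
    out$stage_provenance <- "beta-catenin split"
  }
  out
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("Subtype call:", x$label, "(", x$stage_provenance, ")\n")
  if (length(x$spot_calls))
    cat("  spots:", paste(x$spot_calls, collapse = " "),
        " bcat:", x$bcat_consensus, "\n")
  invisible(x)
}

#' Classify a whole cohort
#'
#' @param patients data.frame with `patient_id` and `mmr_deficient`.
#' @param spots data.frame of spot panels with a `patient_id` column.
#' @param bcat data.frame of beta-catenin scores with a `patient_id` column.
#' @param model A [classifier_model()].
#' @return data.frame with one row per patient: `patient_id`, `label`,
#'   `stage_provenance`, `n_spots`, `bcat_consensus`.
#' @export
classify_cohort <- function(patients, spots, bcat,
                            model = default_classifier_model()) {
  stopifnot(is.data.frame(patients), "patient_id" %in% names(patients),
            "mmr_deficient" %in% names(patients))
  res <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    sp <- spots[spots$patient_id == pid, , drop = FALSE]
    bc <- bcat[bcat$patient_id == pid, , drop = FALSE]
    call <- classify_patient(patients$mmr_deficient[i], sp, bc, model)
    data.frame(patient_id = pid, label = call$label,
               stage_provenance = call$stage_provenance,
               n_spots = length(call$spot_calls),
               bcat_consensus = call$bcat_consensus,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cohort-level classification summary
#'
#' Counts and percentages per label. Percentages are reported with both the
#' classified-patient denominator (as in a results table restricted to
#' successfully classified tumors) and the full-cohort denominator (as in an
#' abstract quoting percentages of all patients); published reports use both
#' and they differ.
#'
#' @param labels Character vector of per-patient labels
#'   (`"CMS1-like"`..`"CMS4-like"` or `"unclassified"`), or a data.frame
#'   from [classify_cohort()].
#' @return List with `n`, `n_classified`, `classified_fraction` (percent),
#'   and a data.frame `table` of counts, `pct_of_classified`,
#'   `pct_of_cohort`.
#' @export
cohort_classification_report <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (!length(labels)) stop("no labels")
  known <- c(.subtype_labels, "unclassified")
  if (!all(labels %in% known))
    stop("unknown labels: ", paste(setdiff(labels, known), collapse = ", "))
  n <- length(labels)
  counts <- vapply(.subtype_labels, function(l) sum(labels == l), integer(1))
  ncl <- sum(counts)
  tab <- data.frame(
    label = .subtype_labels,
    count = as.integer(counts),
    pct_of_classified = if (ncl > 0) 100 * counts / ncl else rep(NA_real_, 4),
    pct_of_cohort = 100 * counts / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(n = n, n_classified = ncl,
       classified_fraction = 100 * ncl / n, table = tab)
}
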