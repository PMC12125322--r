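# Model-versus-annotator validation arithmetic: area-overlap precision and
# sensitivity, their harmonic mean (F1), and the percentage of matching
# rounded intensity scores. Comparisons run model-vs-each-validator and
# validator-vs-validator, averaged as unweighted means over regions and
# then validators.

.mask_logical <- function(m) {
  if (is.logical(m)) m else m > 0
}

#' Area precision of a model mask against an annotation
#'
#' Fraction of the model's result area that lies within the annotator's
#' area: |model intersect annot| / |model|.
#'
#' @param model,annot Binary masks of equal dimensions.
#' @return Value in \[0, 1\]; `NA` when the model mask is empty.
#' @export
area_precision <- function(model, annot) {
  model <- .mask_logical(model); annot <- .mask_logical(annot)
  stopifnot(identical(dim(model), dim(annot)))
  nm <- sum(model)
  if (nm == 0L) return(NA_real_)
  sum(model & annot) / nm
}

#' Area sensitivity of a model mask against an annotation
#'
#' Fraction of the annotator's area recovered by the model:
#' |model intersect annot| / |annot|.
#'
#' @inheritParams area_precision
#' @return Value in \[0, 1\]; `NA` when the annotation mask is empty.
#' @export
area_sensitivity <- function(model, annot) {
  model <- .mask_logical(model); annot <- .mask_logical(annot)
  stopifnot(identical(dim(model), dim(annot)))
  na <- sum(annot)
  if (na == 0L) return(NA_real_)
  sum(model & annot) / na
}

#' F1 score
#'
#' Harmonic mean of precision and sensitivity; defined as 0 when both are 0.
#'
#' @param precision,sensitivity Values in \[0, 1\] (vectorised).
#' @return Value in \[0, 1\].
#' @export
f1_score <- function(precision, sensitivity) {
  if (any(precision < 0 | precision > 1 | sensitivity < 0 | sensitivity > 1,
          na.rm = TRUE))
    stop("precision and sensitivity must be in [0, 1]")
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Matching-intensity percentage
#'
#' Percentage of regions where the model's rounded intensity score equals
#' the validator's score.
#'
#' @param model_scores,validator_scores Equal-length integer vectors (0-3).
#' @return Percentage in \[0, 100\].
#' @export
matching_intensity <- function(model_scores, validator_scores) {
  if (length(model_scores) != length(validator_scores))
    stop("score sequences must have equal length")
  if (!length(model_scores)) stop("empty score sequences")
  100 * mean(model_scores == validator_scores)
}

#' Validation report over regions and validators
#'
#' For every region, the model mask is compared against each validator's
#' mask (and validators pairwise); precision, sensitivity and F1 are
#' averaged as unweighted means over regions, then over validator (pairs).
#' Regions where a ratio is undefined (empty mask) are dropped from the
#' affected mean with a warning. Intensity scores, when provided, yield
#' matching-intensity percentages for both comparison types.
#'
#' @param regions List of regions; each a list with `model` (mask),
#'   `validators` (named list of masks), and optionally `model_score` /
#'   `validator_scores` (integer intensity scores 0-3).
#' @return List of class `validation_report`: data.frame `model_vs_validator`
#'   (one row per validator), data.frame `validator_vs_validator` (one row
#'   per pair), and matching-intensity percentages.
#' @export
validation_report <- function(regions) {
  stopifnot(length(regions) >= 1L)
  vnames <- names(regions[[1L]]$validators)
  if (is.null(vnames) || !length(vnames)) stop("no validators")

  pair_stats <- function(get_a, get_b) {
    p <- vapply(regions, function(r) area_precision(get_a(r), get_b(r)),
                numeric(1))
    s <- vapply(regions, function(r) area_sensitivity(get_a(r), get_b(r)),
                numeric(1))
    if (anyNA(p) || anyNA(s))
      warning("regions with empty masks dropped from validation means")
    f <- f1_score(p, s)
    c(precision = mean(p, na.rm = TRUE), sensitivity = mean(s, na.rm = TRUE),
      f1 = mean(f, na.rm = TRUE))
  }

  mv <- do.call(rbind, lapply(vnames, function(v) {
    st <- pair_stats(function(r) r$model, function(r) r$validators[[v]])
    data.frame(validator = v, t(st), stringsAsFactors = FALSE)
  }))

  vv <- NULL
  if (length(vnames) >= 2L) {
    pairs <- utils::combn(vnames, 2L, simplify = FALSE)
    vv <- do.call(rbind, lapply(pairs, function(pr) {
      st <- pair_stats(function(r) r$validators[[pr[1]]],
                       function(r) r$validators[[pr[2]]])
      data.frame(validator_a = pr[1], validator_b = pr[2], t(st),
                 stringsAsFactors = FALSE)
    }))
  }

  match_mv <- match_vv <- NA_real_
  has_scores <- all(vapply(regions, function(r)
    !is.null(r$model_score) && !is.null(r$validator_scores), logical(1)))
  if (has_scores) {
    ms <- vapply(regions, function(r) r$model_score, numeric(1))
    vs <- sapply(vnames, function(v)
      vapply(regions, function(r) r$validator_scores[[v]], numeric(1)))
    vs <- matrix(vs, nrow = length(regions),
                 dimnames = list(NULL, vnames))
    match_mv <- mean(vapply(vnames, function(v)
      matching_intensity(ms, vs[, v]), numeric(1)))
    if (length(vnames) >= 2L) {
      prs <- utils::combn(vnames, 2L, simplify = FALSE)
      match_vv <- mean(vapply(prs, function(pr)
        matching_intensity(vs[, pr[1]], vs[, pr[2]]), numeric(1)))
    }
  }

  structure(list(model_vs_validator = mv, validator_vs_validator = vv,
                 matching_intensity_model_validator = match_mv,
                 matching_intensity_between_validators = match_vv,
                 n_regions = length(regions)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation over", x$n_regions, "regions\n")
  cat("Model vs validators:\n")
  print(x$model_vs_validator, row.names = FALSE)
  if (!is.null(x$validator_vs_validator)) {
    cat("Validator vs validator:\n")
    print(x$validator_vs_validator, row.names = FALSE)
  }
  if (!is.na(x$matching_intensity_model_validator))
    cat(sprintf("Matching intensity: model-validator %.1f%%%s\n",
                x$matching_intensity_model_validator,
                if (!is.na(x$matching_intensity_between_validators))
                  sprintf(", validator-validator %.1f%%",
                          x$matching_intensity_between_validators) else ""))
  invisible(x)
}
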