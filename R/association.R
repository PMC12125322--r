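# Association scan between subtype labels and clinicopathological
# categories, in the layout of a clinical characteristics table: one
# contingency table (covariate level x subtype) and one exact p-value per
# covariate, with column percentages per subtype.

#' Association test between subtype and one categorical covariate
#'
#' Builds the covariate-by-subtype contingency table (dropping unclassified
#' patients and missing covariate values) and runs [fisher_exact_rxc()].
#'
#' @param labels Character vector of subtype labels per patient.
#' @param covariate Vector (factor or character) of covariate values.
#' @param ... Passed to [fisher_exact_rxc()] (`method`, `reps`, `seed`).
#' @return List: `table` (contingency_table with column percentages as
#'   attribute `col_pct`), `p_value`, `method`.
#' @export
association_test <- function(labels, covariate, ...) {
  stopifnot(length(labels) == length(covariate))
  keep <- labels %in% .subtype_labels & !is.na(covariate)
  labels <- factor(labels[keep], levels = .subtype_labels)
  covariate <- factor(covariate[keep])
  if (nlevels(droplevels(covariate)) < 2L)
    stop("covariate has a single observed level")
  covariate <- droplevels(covariate)
  counts <- table(covariate, labels)
  ct <- contingency_table(unclass(counts), row_labels = levels(covariate),
                          col_labels = .subtype_labels)
  res <- fisher_exact_rxc(ct, ...)
  col_pct <- sweep(ct, 2L, pmax(colSums(ct), 1L), "/") * 100
  attr(ct, "col_pct") <- col_pct
  list(table = ct, p_value = res$p_value, method = res$method)
}

#' Covariate-by-subtype association report
#'
#' One exact test per covariate over a classified cohort, mirroring the
#' familiar "Table 1" layout (counts, percentage of each subtype column,
#' p-value). Unclassified patients are excluded; missing covariate values
#' are dropped row-wise per covariate. Covariates with a single observed
#' level are skipped with a warning.
#'
#' @param patients data.frame of patient covariates.
#' @param labels Subtype labels aligned to `patients` rows (or a data.frame
#'   from [classify_cohort()] sharing `patient_id`).
#' @param vars Character vector of covariate column names to test.
#' @param ... Passed to [fisher_exact_rxc()].
#' @return List with `summary` (data.frame: variable, p_value, method) and
#'   `tables` (named list of per-covariate results from
#'   [association_test()]).
#' @export
table1_report <- function(patients, labels, vars, ...) {
  if (is.data.frame(labels)) {
    stopifnot("patient_id" %in% names(labels), "patient_id" %in% names(patients))
    labels <- labels$label[match(patients$patient_id, labels$patient_id)]
  }
  stopifnot(length(labels) == nrow(patients), all(vars %in% names(patients)))
  tables <- list()
  rows <- list()
  for (v in vars) {
    res <- tryCatch(association_test(labels, patients[[v]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping covariate '", v, "': ", conditionMessage(res))
      next
    }
    tables[[v]] <- res
    rows[[v]] <- data.frame(variable = v, p_value = res$p_value,
                            method = res$method, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tables = tables)
}

#' Published association-table counts
#'
#' Loads the covariate-by-subtype contingency tables transcribed from the
#' source cohort's clinicopathological association table (shipped as
#' `extdata/table1_counts.json`), ready for [fisher_exact_rxc()].
#'
#' @param path Optional path to an alternative JSON file with the same
#'   layout.
#' @return Named list; per variable: `table` (a [contingency_table()]) and
#'   `printed_p` (the p-value string as typeset in the publication).
#' @export
table1_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_counts.json", package = "cmsihc")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw$variables, function(v) {
    m <- if (is.matrix(v$counts)) v$counts else
      matrix(unlist(v$counts), nrow = length(v$rows), byrow = TRUE)
    list(table = contingency_table(m, row_labels = v$rows,
                                   col_labels = raw$columns),
         printed_p = v$printed_p)
  })
}
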