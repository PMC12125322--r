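# File-format plumbing: schema-validated CSV tables with a version/config
# comment header, plain-text netpbm rasters (PGM for masks, PPM for RGB
# spot images), and the JSON run manifest.
#
# Netpbm text formats are written by hand because no raster-format package
# is guaranteed in the deployment environment; PGM/PPM are trivial,
# lossless and diffable.

.pkg_version <- function() {
  as.character(utils::packageVersion("cmsihc"))
}

.config_hash <- function(config) {
  # stable short hash of the serialised config (no digest dependency);
  # the output location is not part of the scientific configuration
  if (is.list(config)) config$outdir <- NULL
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

#' Write a table as CSV with a provenance comment header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config Optional config object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cmsihc %s config=%s", .pkg_version(),
                     if (is.null(config)) "-" else .config_hash(config)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_table_csv()]
#'
#' @param path Input path.
#' @return data.frame (comment headers skipped).
#' @export
read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# --- schema validation ------------------------------------------------------

.schemas <- list(
  patients = list(
    required = c("patient_id", "mmr_deficient"),
    checks = list(
      mmr_deficient = function(v) v %in% c(TRUE, FALSE),
      stage = function(v) is.na(v) | v %in% c("I", "II", "III", "IV"),
      pT = function(v) is.na(v) | v %in% 1:4,
      pN = function(v) is.na(v) | v %in% 0:2,
      pM = function(v) is.na(v) | v %in% 0:1,
      grade = function(v) is.na(v) | v %in% c("low", "high"),
      location = function(v) is.na(v) |
        v %in% c("right colon", "left colon", "rectum"),
      histology = function(v) is.na(v) | v %in% c("non-mucinous", "mucinous"),
      os_time = function(v) is.na(v) | v >= 0
    )
  ),
  spots = list(
    required = c("patient_id", "spot_index", "cdx2_intensity", "cdx2_pct",
                 "frmd6_intensity", "frmd6_pct", "htr2b_intensity",
                 "ker_intensity", "ker_pct", "zeb1_pct"),
    checks = list(
      spot_index = function(v) v %in% 1:4,
      cdx2_intensity = function(v) is.na(v) | v %in% 0:3,
      frmd6_intensity = function(v) is.na(v) | v %in% 0:3,
      htr2b_intensity = function(v) is.na(v) | v %in% 0:3,
      ker_intensity = function(v) is.na(v) | v %in% 0:3,
      cdx2_pct = function(v) is.na(v) | (v >= 0 & v <= 100),
      frmd6_pct = function(v) is.na(v) | (v >= 0 & v <= 100),
      ker_pct = function(v) is.na(v) | (v >= 0 & v <= 100),
      zeb1_pct = function(v) is.na(v) | (v >= 0 & v <= 100)
    )
  ),
  bcat = list(
    required = c("patient_id", "spot_index", "nuclear_intensity",
                 "nuclear_pct_category"),
    checks = list(
      spot_index = function(v) v %in% 1:4,
      nuclear_intensity = function(v) is.na(v) | v %in% 0:3,
      nuclear_pct_category = function(v) is.na(v) | v %in% 0:4
    )
  ),
  calls = list(
    required = c("patient_id", "label"),
    checks = list(
      label = function(v) v %in% c("CMS1-like", "CMS2-like", "CMS3-like",
                                   "CMS4-like", "unclassified")
    )
  )
)

#' Validate a table against a named schema
#'
#' Checks required columns (unknown columns are preserved untouched) and
#' per-column value ranges; failures report the offending column and row
#' indices.
#'
#' @param df data.frame.
#' @param schema One of `"patients"`, `"spots"`, `"bcat"`, `"calls"`.
#' @return `df`, invisibly, when valid; otherwise an error.
#' @export
validate_table <- function(df, schema) {
  sc <- .schemas[[match.arg(schema, names(.schemas))]]
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(names(sc$checks), names(df))) {
    ok <- sc$checks[[col]](df[[col]])
    if (!all(ok))
      stop(sprintf("column '%s': invalid value(s) at row(s) %s", col,
                   paste(head(which(!ok), 10L), collapse = ", ")))
  }
  invisible(df)
}

#' Read and validate a pipeline table
#'
#' @param path CSV path.
#' @param schema Schema name, see [validate_table()].
#' @return Validated data.frame.
#' @export
read_validated_table <- function(path, schema) {
  df <- read_table_csv(path)
  validate_table(df, schema)
  df
}

# --- netpbm rasters ---------------------------------------------------------

#' Write a binary mask as plain-text PGM (P2)
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix / `annotation_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  m <- if (is.logical(mask)) mask else mask > 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  apply(ifelse(m, 255L, 0L), 1L, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a plain-text PGM (P2) mask
#'
#' @param path PGM path.
#' @return `annotation_mask` (TRUE where the stored value exceeds half the
#'   maxval).
#' @export
read_mask_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not a plain PGM (P2) file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  .new_mask(matrix(vals > maxv / 2, h, w, byrow = TRUE))
}

#' Write an RGB spot image as plain-text PPM (P3)
#'
#' @param image `spot_image` (or h x w x 3 array, 0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_ppm <- function(image, path) {
  rgb <- if (inherits(image, "spot_image")) image$rgb else image
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", w, h), "255"), con)
  flat <- matrix(aperm(round(rgb), c(3L, 2L, 1L)), nrow = 3L * w)
  apply(flat, 2L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a plain-text PPM (P3) image
#'
#' @param path PPM path.
#' @param pixel_size,marker Metadata to attach to the `spot_image`.
#' @return A `spot_image`.
#' @export
read_image_ppm <- function(path, pixel_size = 200, marker = "CDX2") {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P3") stop("not a plain PPM (P3) file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != 3 * w * h) stop("PPM pixel count mismatch")
  rgb <- aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
  .new_spot_image(rgb, pixel_size, marker)
}

# --- run manifest -----------------------------------------------------------

#' Write the run manifest
#'
#' Records the config snapshot, the seed, the package version, output file
#' MD5 hashes and a timestamp; re-running with the same config reproduces
#' byte-identical tabular outputs.
#'
#' @param config Config object (list).
#' @param outputs Character vector of output file paths.
#' @param path Manifest output path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  manifest <- list(
    tool = "cmsihc",
    version = .pkg_version(),
    config = config,
    config_hash = .config_hash(config),
    seed = config$seed,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
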