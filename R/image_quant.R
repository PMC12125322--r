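# Classical quantification of DAB-stained spot images: Beer-Lambert stain
# separation, threshold-plus-morphology epithelium segmentation, and
# intensity / percent-positive scoring under each marker's compartment
# convention. This is a deterministic stand-in for the proprietary
# CNN-based scoring used in the source pipeline: the downstream classifier
# needs only the scores, not the network.

#' Intensity rounding rule
#'
#' Maps a continuous intensity on the 0-3 scale to the integer score used
#' by the classifier: 0-0.499 to 0, 0.5-1.499 to 1, 1.5-2.499 to 2,
#' 2.5-3 to 3.
#'
#' @param x Numeric in \[0, 3\] (vectorised).
#' @return Integer in \{0, 1, 2, 3\}; `NA` propagated.
#' @export
#' @examples
#' round_intensity(c(0.499, 0.5, 1.499, 2.5, 3))
round_intensity <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > 3)
  if (any(bad)) stop("intensity must be in [0, 3]")
  as.integer(floor(x + 0.5))
}

#' Beer-Lambert stain separation
#'
#' Converts an RGB image to optical density and decomposes every pixel onto
#' the two stain vectors by least squares, clipping negative densities to
#' zero.
#'
#' @param image A `spot_image` (or an h x w x 3 array on the 0-255 scale).
#' @param stain_vectors 3 x 2 matrix of stain OD vectors (columns
#'   hematoxylin, DAB); must be linearly independent.
#' @return List: `hematoxylin` and `dab` density matrices.
#' @export
separate_stains <- function(image, stain_vectors = default_stain_vectors()) {
  rgb <- if (inherits(image, "spot_image")) image$rgb else image
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("image must have three channels")
  M <- stain_vectors
  if (!is.matrix(M) || any(dim(M) != c(3L, 2L)))
    stop("stain_vectors must be a 3 x 2 matrix")
  cross <- sum((M[, 1] / sqrt(sum(M[, 1]^2)) -
                M[, 2] / sqrt(sum(M[, 2]^2)))^2)
  if (cross < 1e-10) stop("stain vectors are collinear")
  od <- -log(pmax(rgb, 0.5) / 255)
  odm <- matrix(od, ncol = 3L)            # pixels x channels
  pinv <- solve(crossprod(M), t(M))       # 2 x 3
  dens <- odm %*% t(pinv)                 # pixels x 2
  dens[dens < 0] <- 0
  d <- dim(rgb)[1:2]
  list(hematoxylin = matrix(dens[, 1], d[1], d[2]),
       dab = matrix(dens[, 2], d[1], d[2]))
}

# 3x3 majority filter (morphological smoothing of a binary mask) using a
# padded box sum; removes isolated noise pixels and fills pinholes.
.majority3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  s <- p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
       p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
       p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
  s >= 5L
}

#' Segment epithelium from hematoxylin density
#'
#' Epithelial regions are nuclei-dense and carry a markedly higher
#' hematoxylin optical density than surrounding stroma; a fixed threshold
#' followed by a 3 x 3 majority filter yields the epithelium mask.
#' Deterministic; may return an empty mask.
#'
#' @param image A `spot_image`.
#' @param h_threshold Hematoxylin OD threshold separating epithelium from
#'   other tissue (between the stromal and epithelial tones of the
#'   generator, default 0.6).
#' @param stain_vectors Passed to [separate_stains()].
#' @return An `annotation_mask`.
#' @export
segment_epithelium <- function(image, h_threshold = 0.6,
                               stain_vectors = default_stain_vectors()) {
  dens <- separate_stains(image, stain_vectors)
  .new_mask(.majority3(dens$hematoxylin > h_threshold))
}

#' Mean-positive-pixel intensity score
#'
#' Mean DAB optical density over masked pixels above the positivity
#' threshold, mapped through the linear 0-3 calibration. Intensity is
#' averaged over positive pixels only, keeping it independent of the
#' percent-positive score; a mask with no positive pixel scores 0.
#'
#' @param dab_map DAB density matrix from [separate_stains()].
#' @param mask Compartment `annotation_mask`.
#' @param od_per_unit OD corresponding to one intensity unit.
#' @param positivity_threshold OD above which a pixel counts as stained.
#' @return Continuous intensity in \[0, 3\]; `NA` (no-tissue) for an empty
#'   mask.
#' @export
score_intensity <- function(dab_map, mask, od_per_unit = .od_per_unit,
                            positivity_threshold = 0.15) {
  m <- as.logical(mask)
  if (!any(m)) {
    warning("empty mask: no-tissue signal")
    return(NA_real_)
  }
  v <- dab_map[m]
  v <- v[v > positivity_threshold]
  if (!length(v)) return(0)
  min(3, max(0, mean(v) / od_per_unit))
}

#' Percent of compartment area that is positively stained
#'
#' @inheritParams score_intensity
#' @return Percent in \[0, 100\]; `NA` for an empty compartment.
#' @export
percent_positive <- function(dab_map, mask, positivity_threshold = 0.15) {
  m <- as.logical(mask)
  if (!any(m)) {
    warning("empty compartment: no-tissue signal")
    return(NA_real_)
  }
  100 * mean(dab_map[m] > positivity_threshold)
}

#' Quantify one stained spot image
#'
#' Runs stain separation and epithelium segmentation, then scores the spot
#' under the marker's compartment convention: CDX2, FRMD6, KER and BCAT
#' report intensity and percent positive; HTR2B reports intensity only;
#' ZEB1 reports percent only (its presence/absence is decided downstream by
#' the 2% cut-off).
#'
#' @param image A `spot_image` with its `marker` label set.
#' @param h_threshold,od_per_unit,positivity_threshold See
#'   [segment_epithelium()] and [score_intensity()].
#' @param stain_vectors Passed to [separate_stains()].
#' @return A `quant_result`: `marker`, `continuous_intensity`,
#'   `rounded_intensity`, `percent_positive`, `area_analyzed`, `mask`.
#' @export
quantify_spot <- function(image, h_threshold = 0.6,
                          od_per_unit = .od_per_unit,
                          positivity_threshold = 0.15,
                          stain_vectors = default_stain_vectors()) {
  stopifnot(inherits(image, "spot_image"))
  marker <- toupper(image$marker)
  if (!marker %in% .markers)
    stop("unknown marker label: ", image$marker)
  dens <- separate_stains(image, stain_vectors)
  mask <- segment_epithelium(image, h_threshold, stain_vectors)
  area <- sum(mask)
  want_int <- marker != "ZEB1"
  want_pct <- marker != "HTR2B"
  ci <- if (want_int && area > 0)
    score_intensity(dens$dab, mask, od_per_unit, positivity_threshold)
    else NA_real_
  pp <- if (want_pct && area > 0)
    percent_positive(dens$dab, mask, positivity_threshold) else NA_real_
  structure(list(
    marker = marker,
    continuous_intensity = ci,
    rounded_intensity = if (is.na(ci)) NA_integer_ else round_intensity(ci),
    percent_positive = pp,
    area_analyzed = area,
    mask = mask
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "Quant [%s]: intensity %s (rounded %s), percent positive %s, area %d px\n",
    x$marker,
    ifelse(is.na(x$continuous_intensity), "-",
           sprintf("%.3f", x$continuous_intensity)),
    ifelse(is.na(x$rounded_intensity), "-",
           as.character(x$rounded_intensity)),
    ifelse(is.na(x$percent_positive), "-",
           sprintf("%.1f%%", x$percent_positive)),
    x$area_analyzed))
  invisible(x)
}
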