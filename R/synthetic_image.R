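# Synthetic TMA spot images with ground truth.
#
# A two-stain Beer-Lambert model: per-pixel optical density is
# H * v_hematoxylin + D * v_dab with fixed unit stain vectors, and
# RGB = 255 * exp(-OD). The circular tissue disc carries a light
# hematoxylin tone, epithelial blobs a dense one; a configurable fraction
# of epithelial pixels carries DAB at a density proportional to the
# requested 0-3 intensity level. The epithelium mask and the realized
# intensity/percent are returned as ground truth, so the quantification
# stage can be validated by round trip.

# OD units per intensity level on the 0-3 scale (package calibration).
.od_per_unit <- 0.5

# Ruifrok-Johnston style unit stain vectors (columns: hematoxylin, DAB).
#' Default hematoxylin/DAB stain matrix
#'
#' 3 x 2 matrix of unit optical-density vectors (columns hematoxylin, DAB)
#' used by both the image generator and [separate_stains()].
#' @return Numeric 3 x 2 matrix.
#' @export
default_stain_vectors <- function() {
  m <- cbind(h = c(0.651, 0.701, 0.290), dab = c(0.269, 0.568, 0.778))
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

#' Synthetic spot image specification
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel pitch in nm (whole-slide scans are typically
#'   around 200 nm/pixel at 20x).
#' @param tissue_radius_fraction Tissue disc radius as a fraction of the
#'   smaller image dimension.
#' @param n_blobs Number of epithelial blobs.
#' @param blob_radius_range Min/max blob radius in pixels.
#' @param dab_intensity_level Target DAB intensity on the 0-3 scale.
#' @param positive_fraction Fraction of epithelial area that is
#'   DAB-positive, in \[0, 1\].
#' @param noise_sd Gaussian RGB noise standard deviation (8-bit scale).
#' @param marker Marker label the image represents.
#' @param seed Integer seed.
#' @return List of class `image_spec`.
#' @export
image_spec <- function(width = 160L, height = 160L, pixel_size = 200,
                       tissue_radius_fraction = 0.45, n_blobs = 6L,
                       blob_radius_range = c(12, 30),
                       dab_intensity_level = 2, positive_fraction = 0.5,
                       noise_sd = 2, marker = "CDX2", seed = 1L) {
  if (dab_intensity_level < 0 || dab_intensity_level > 3)
    .stop_config("dab_intensity_level must be in [0, 3]")
  .check_prob(positive_fraction, "positive_fraction")
  if (width < 16 || height < 16) .stop_config("image too small")
  if (noise_sd < 0) .stop_config("noise_sd must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 tissue_radius_fraction = tissue_radius_fraction,
                 n_blobs = as.integer(n_blobs),
                 blob_radius_range = blob_radius_range,
                 dab_intensity_level = dab_intensity_level,
                 positive_fraction = positive_fraction,
                 noise_sd = noise_sd, marker = marker,
                 seed = as.integer(seed)),
            class = "image_spec")
}

.new_spot_image <- function(rgb, pixel_size, marker) {
  structure(list(rgb = rgb, pixel_size = pixel_size, marker = marker),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("Spot image: %d x %d px, marker %s, %g nm/pixel\n",
              d[1], d[2], x$marker, x$pixel_size))
  invisible(x)
}

.new_mask <- function(mat, label = "epithelium") {
  structure(mat, label = label, class = c("annotation_mask", class(mat)))
}

#' Generate a synthetic TMA spot image
#'
#' @param spec An [image_spec()].
#' @return List: `image` (a `spot_image`), `mask` (epithelium
#'   `annotation_mask`), `truth` (a `quant_result` holding the intended
#'   continuous intensity, its rounded value, and the realized percent
#'   positive).
#' @export
generate_spot_image <- function(spec = image_spec()) {
  stopifnot(inherits(spec, "image_spec"))
  .with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    r_disc <- spec$tissue_radius_fraction * min(h, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    disc <- (yy - cy)^2 + (xx - cx)^2 <= r_disc^2

    epi <- matrix(FALSE, h, w)
    if (spec$n_blobs > 0L) {
      for (b in seq_len(spec$n_blobs)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, 0.7 * r_disc)
        by <- cy + rad * sin(ang); bx <- cx + rad * cos(ang)
        br <- runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
        epi <- epi | ((yy - by)^2 + (xx - bx)^2 <= br^2)
      }
      epi <- epi & disc
    }
    if (!any(epi) && spec$positive_fraction > 0)
      .stop_config("zero-area epithelium with positive_fraction > 0")

    pos <- matrix(FALSE, h, w)
    n_epi <- sum(epi)
    if (n_epi > 0L && spec$positive_fraction > 0)
      pos[epi] <- runif(n_epi) < spec$positive_fraction

    hem <- ifelse(epi, 0.9, ifelse(disc, 0.35, 0.02))
    dab <- ifelse(pos, spec$dab_intensity_level * .od_per_unit, 0)

    sv <- default_stain_vectors()
    rgb <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      rgb[, , ch] <- 255 * exp(-(hem * sv[ch, 1L] + dab * sv[ch, 2L]))
    if (spec$noise_sd > 0)
      rgb <- rgb + rnorm(length(rgb), 0, spec$noise_sd)
    rgb <- round(pmin(pmax(rgb, 0), 255))

    # at intensity 0 nothing is actually stained, so the realized percent is 0
    realized_pct <- if (n_epi > 0L && spec$dab_intensity_level > 0)
      100 * sum(pos) / n_epi else 0
    truth <- structure(list(
      marker = spec$marker,
      continuous_intensity = spec$dab_intensity_level,
      rounded_intensity = round_intensity(spec$dab_intensity_level),
      percent_positive = realized_pct,
      area_analyzed = n_epi
    ), class = "quant_result")
    list(image = .new_spot_image(rgb, spec$pixel_size, spec$marker),
         mask = .new_mask(epi), truth = truth)
  })
}

#' Jitter an annotation mask
#'
#' Emulates inter-annotator variation by shifting the mask by a random
#' integer offset drawn from a rounded normal with standard deviation
#' `boundary_jitter` (re-drawn until nonzero when `boundary_jitter > 0`).
#' `boundary_jitter = 0` is the identity.
#'
#' @param mask Binary `annotation_mask` (or logical matrix).
#' @param boundary_jitter Jitter scale in pixels (>= 0).
#' @param seed Optional seed.
#' @return Jittered `annotation_mask` of the same dimensions.
#' @export
perturb_annotation <- function(mask, boundary_jitter, seed = NULL) {
  if (boundary_jitter < 0) stop("boundary_jitter must be >= 0")
  m <- mask
  if (!is.logical(m)) m <- m > 0
  if (boundary_jitter == 0) return(.new_mask(unclass(m)))
  .with_seed(seed, {
    repeat {
      dy <- as.integer(round(rnorm(1, 0, boundary_jitter)))
      dx <- as.integer(round(rnorm(1, 0, boundary_jitter)))
      if (dy != 0L || dx != 0L) break
    }
    out <- matrix(FALSE, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dy
    src_c <- seq_len(ncol(m)) - dx
    ok_r <- src_r >= 1L & src_r <= nrow(m)
    ok_c <- src_c >= 1L & src_c <= ncol(m)
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
    .new_mask(out, attr(mask, "label") %||% "epithelium")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
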