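test_that("rounding rule: interval edges, idempotence, monotone step", {
  expect_identical(round_intensity(c(0, 0.499, 0.5, 1, 1.499, 1.5, 2.499,
                                     2.5, 3)),
                   c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(round_intensity(3.01), "0, 3")
  expect_error(round_intensity(-0.1), "0, 3")
  expect_identical(round_intensity(0:3), 0:3)
  x <- seq(0, 3, by = 0.01)
  expect_true(all(diff(round_intensity(x)) >= 0))
})

test_that("stain separation: no absorbance, symmetry, collinearity guard", {
  white <- array(255, dim = c(8, 8, 3))
  d <- separate_stains(white)
  expect_lt(max(d$hematoxylin, d$dab), 1e-6)

  g <- generate_spot_image(image_spec(noise_sd = 0, seed = 12))
  sv <- default_stain_vectors()
  d1 <- separate_stains(g$image, sv)
  d2 <- separate_stains(g$image, sv[, 2:1])
  expect_equal(d1$hematoxylin, d2$dab)
  expect_equal(d1$dab, d2$hematoxylin)
  expect_error(separate_stains(g$image, cbind(sv[, 1], sv[, 1])),
               "collinear")
})

test_that("noiseless stain separation round-trips the generator densities", {
  sp <- image_spec(dab_intensity_level = 2, positive_fraction = 0.4,
                   noise_sd = 0, seed = 13)
  g <- generate_spot_image(sp)
  d <- separate_stains(g$image)
  # DAB ground truth: level * OD-per-unit on positive pixels, 0 elsewhere
  dab_pos <- d$dab[g$mask & d$dab > 0.5]
  truth <- 2 * cmsihc:::.od_per_unit
  rms <- sqrt(mean((dab_pos - truth)^2)) / truth
  expect_lt(rms, 0.01)
})

test_that("intensity scoring is calibrated, zero-safe and monotone", {
  g2 <- generate_spot_image(image_spec(dab_intensity_level = 2,
                                       positive_fraction = 0.5,
                                       noise_sd = 0, seed = 14))
  d2 <- separate_stains(g2$image)
  expect_equal(score_intensity(d2$dab, g2$mask), 2, tolerance = 0.05)

  zero <- matrix(0, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  expect_equal(score_intensity(zero, mask), 0)
  expect_warning(score_intensity(zero, matrix(FALSE, 16, 16)), "no-tissue")

  scores <- vapply(seq(0, 3, by = 0.5), function(lv) {
    g <- generate_spot_image(image_spec(dab_intensity_level = lv, seed = 15))
    q <- quantify_spot(g$image)
    q$continuous_intensity
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("percent positive: threshold extremes and generator recovery", {
  g <- generate_spot_image(image_spec(positive_fraction = 0.3, seed = 16))
  d <- separate_stains(g$image)
  expect_equal(percent_positive(d$dab, g$mask, positivity_threshold = 1e6), 0)
  expect_equal(percent_positive(d$dab, g$mask, positivity_threshold = -1), 100)
  expect_equal(percent_positive(d$dab, g$mask), g$truth$percent_positive,
               tolerance = 3)

  # invariance to integer upscaling (+-1 point)
  up <- function(m, k) m[rep(seq_len(nrow(m)), each = k),
                         rep(seq_len(ncol(m)), each = k)]
  p1 <- percent_positive(d$dab, g$mask)
  p2 <- percent_positive(up(d$dab, 2), up(unclass(g$mask), 2))
  expect_equal(p1, p2, tolerance = 1)
})

test_that("marker conventions are honored by quantify_spot", {
  mk <- function(marker) {
    g <- generate_spot_image(image_spec(marker = marker, seed = 17))
    quantify_spot(g$image)
  }
  htr2b <- mk("HTR2B")
  expect_false(is.na(htr2b$continuous_intensity))
  expect_true(is.na(htr2b$percent_positive))
  zeb1 <- mk("ZEB1")
  expect_true(is.na(zeb1$continuous_intensity))
  expect_false(is.na(zeb1$percent_positive))
  cdx2 <- mk("CDX2")
  expect_false(is.na(cdx2$continuous_intensity))
  expect_false(is.na(cdx2$percent_positive))
  bad <- generate_spot_image(image_spec(seed = 18))
  bad$image$marker <- "NOTAMARKER"
  expect_error(quantify_spot(bad$image), "unknown marker")

  g <- generate_spot_image(image_spec(dab_intensity_level = 1,
                                      positive_fraction = 0.8, noise_sd = 0,
                                      seed = 19))
  q <- quantify_spot(g$image)
  expect_equal(q$rounded_intensity, 1L)
  expect_equal(q$percent_positive, 80, tolerance = 2)
})

test_that("epithelium segmentation: empty on blank, contained in the disc, accurate", {
  blank <- cmsihc:::.new_spot_image(array(255, dim = c(32, 32, 3)), 200,
                                    "CDX2")
  expect_equal(sum(segment_epithelium(blank)), 0)

  sp <- image_spec(seed = 20)
  g <- generate_spot_image(sp)
  m <- segment_epithelium(g$image)
  disc_area <- pi * (sp$tissue_radius_fraction * min(sp$width, sp$height))^2
  expect_lte(sum(m), disc_area * 1.02)
  f1 <- f1_score(area_precision(m, g$mask), area_sensitivity(m, g$mask))
  expect_gte(f1, 0.90)
})
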