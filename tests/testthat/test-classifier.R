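test_that("ZEB1 presence uses the 2% cut-off with inclusive boundary", {
  expect_false(zeb1_presence(1.9))
  expect_true(zeb1_presence(2.0))
  expect_false(zeb1_presence(0))
  expect_error(zeb1_presence(101), "0, 100")
})

test_that("spot probability is logistic and monotone in ZEB1", {
  null_model <- classifier_model(intercept = 0)
  zero_panel <- list(cdx2_intensity = 0, cdx2_pct = 0, frmd6_intensity = 0,
                     frmd6_pct = 0, htr2b_intensity = 0, ker_intensity = 0,
                     ker_pct = 0, zeb1_pct = 0)
  expect_equal(spot_epithelial_probability(zero_panel, null_model), 0.5)

  m <- default_classifier_model()
  expect_gt(spot_epithelial_probability(epithelial_panel(), m), 0.9)
  expect_lt(spot_epithelial_probability(mesenchymal_panel(), m), 0.1)

  # flipping ZEB1 absent -> present never increases the probability when its
  # coefficient is negative
  expect_lt(m$coefficients["zeb1_present"], 0)
  for (p in list(epithelial_panel(), mesenchymal_panel())) {
    p_absent <- p; p_absent$zeb1_pct <- 0
    p_present <- p; p_present$zeb1_pct <- 50
    expect_lte(spot_epithelial_probability(p_present, m),
               spot_epithelial_probability(p_absent, m))
  }
})

test_that("spot call threshold resolves ties to epithelial", {
  expect_equal(classify_spot(0.51), "E")
  expect_equal(classify_spot(0.49), "M")
  expect_equal(classify_spot(0.50), "E")
})

test_that("majority vote follows the most-frequent rule with tie -> inconclusive", {
  expect_equal(aggregate_spot_calls(c("E", "E", "M", "E")), "CMS2/3-like")
  expect_equal(aggregate_spot_calls(c("E", "E", "M", "M")), "inconclusive")
  expect_equal(aggregate_spot_calls("M"), "CMS4-like")
  expect_equal(aggregate_spot_calls(character(0)), "missing")
  # order independence
  set.seed(42)
  for (i in 1:20) {
    calls <- sample(c("E", "M"), sample(1:4, 1), replace = TRUE)
    expect_equal(aggregate_spot_calls(calls),
                 aggregate_spot_calls(sample(calls)))
  }
})

test_that("beta-catenin positivity requires >= 2 in either score and is monotone", {
  expect_true(beta_catenin_call(2, 0))
  expect_true(beta_catenin_call(1, 3))
  expect_false(beta_catenin_call(1, 1))
  # raising either score never flips positive -> negative
  for (i in 0:3) for (p in 0:4) {
    if (beta_catenin_call(i, p)) {
      if (i < 3) expect_true(beta_catenin_call(i + 1, p))
      if (p < 4) expect_true(beta_catenin_call(i, p + 1))
    }
  }
  expect_equal(aggregate_bcat(c(TRUE, TRUE, FALSE)), "positive")
  expect_equal(aggregate_bcat(c(TRUE, FALSE)), "inconclusive")
  expect_equal(aggregate_bcat(FALSE), "negative")
})

test_that("patient classification follows the hierarchical rule", {
  m <- default_classifier_model()
  mes4 <- panels_df(rep(list(mesenchymal_panel()), 4))
  epi3_mes1 <- panels_df(c(rep(list(epithelial_panel()), 3),
                           list(mesenchymal_panel())))
  bcat_neg <- data.frame(nuclear_intensity = c(0, 1, 0),
                         nuclear_pct_category = c(1, 0, 1))
  bcat_pos <- data.frame(nuclear_intensity = c(2, 3, 2),
                         nuclear_pct_category = c(3, 4, 0))

  # MMR gate precedes the classifier even with all-mesenchymal spots
  gate <- classify_patient(TRUE, mes4, bcat_pos, m)
  expect_equal(gate$label, "CMS1-like")
  expect_equal(gate$stage_provenance, "MMR gate")

  # E-majority with negative beta-catenin -> CMS3-like
  c3 <- classify_patient(FALSE, epi3_mes1, bcat_neg, m)
  expect_equal(c3$label, "CMS3-like")
  c2 <- classify_patient(FALSE, epi3_mes1, bcat_pos, m)
  expect_equal(c2$label, "CMS2-like")

  # M-majority -> CMS4-like regardless of beta-catenin
  c4 <- classify_patient(FALSE, mes4, bcat_pos, m)
  expect_equal(c4$label, "CMS4-like")

  # ties and missing data
  tie <- classify_patient(FALSE, panels_df(c(rep(list(epithelial_panel()), 2),
                                             rep(list(mesenchymal_panel()), 2))),
                          bcat_neg, m)
  expect_equal(tie$label, "unclassified")
  expect_equal(tie$stage_provenance, "inconclusive-at-vote")
  miss <- classify_patient(FALSE, NULL, NULL, m)
  expect_equal(miss$label, "unclassified")
  expect_equal(miss$stage_provenance, "missing-data")
  bc_tie <- classify_patient(FALSE, epi3_mes1,
                             data.frame(nuclear_intensity = c(2, 0),
                                        nuclear_pct_category = c(0, 0)), m)
  expect_equal(bc_tie$stage_provenance, "inconclusive-at-bcat")
})

test_that("cohort report arithmetic and partition", {
  labels <- c(rep("CMS1-like", 76), rep("CMS2-like", 168),
              rep("CMS3-like", 185), rep("CMS4-like", 52),
              rep("unclassified", 57))
  rep <- cohort_classification_report(labels)
  expect_equal(rep$n, 538)
  expect_equal(rep$n_classified, 481)
  expect_equal(round(rep$classified_fraction, 1), 89.4)
  expect_equal(round(rep$table$pct_of_classified[1], 1), 15.8)
  expect_equal(sum(rep$table$count) + sum(labels == "unclassified"), rep$n)

  all_un <- cohort_classification_report(rep("unclassified", 10))
  expect_equal(all_un$classified_fraction, 0)
})
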