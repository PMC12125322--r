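# The exact path is checked against a direct hypergeometric enumeration on
# a 2x2 (closed form) and against stats::fisher.test (independent network
# algorithm) on random small tables.

test_that("2x2 exact p matches direct hypergeometric enumeration", {
  tab <- rbind(c(3, 1), c(1, 3))
  # direct oracle: X ~ Hypergeom(m=4, n=4, k=4) over cell (1,1)
  probs <- stats::dhyper(0:4, 4, 4, 4)
  p_obs <- stats::dhyper(3, 4, 4, 4)
  p_direct <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(p_direct, 0.4857142857, tolerance = 1e-9)
  expect_equal(fisher_exact_rxc(tab)$p_value, p_direct, tolerance = 1e-10)
  expect_equal(fisher_exact_rxc(tab)$p_value,
               stats::fisher.test(tab)$p.value, tolerance = 1e-10)
})

test_that("exact path agrees with fisher.test on random r x c tables", {
  set.seed(11)
  for (i in 1:12) {
    r <- sample(2:3, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 4), r, cc)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_rxc(tab, method = "exact")$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8,
                 info = paste(tab, collapse = ","))
  }
})

test_that("modal tables and degenerate margins give p = 1", {
  expect_equal(fisher_exact_rxc(rbind(c(10, 20), c(20, 40)))$p_value, 1)
  degen <- rbind(c(5, 7), c(0, 0))
  expect_equal(fisher_exact_rxc(degen, method = "exact")$p_value, 1)
  expect_equal(fisher_exact_rxc(degen, method = "monte_carlo", reps = 1e4,
                                seed = 1)$p_value, 1)
})

test_that("p is invariant under row and column permutations", {
  set.seed(3)
  tab <- matrix(rpois(12, 6), 3, 4)
  p0 <- fisher_exact_rxc(tab, method = "exact")$p_value
  for (i in 1:5) {
    perm <- tab[sample(3), sample(4)]
    expect_equal(fisher_exact_rxc(perm, method = "exact")$p_value, p0,
                 tolerance = 1e-12)
  }
  expect_gt(p0, 0)
  expect_lte(p0, 1)
})

test_that("Monte-Carlo path is seeded, guarded and converges to exact", {
  tab <- rbind(c(8, 3, 6), c(2, 7, 5))
  p1 <- fisher_exact_rxc(tab, method = "monte_carlo", reps = 1e4, seed = 9)
  p2 <- fisher_exact_rxc(tab, method = "monte_carlo", reps = 1e4, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  expect_error(fisher_exact_rxc(tab, method = "monte_carlo", reps = 100),
               "10\\^4")

  chk <- mc_vs_exact_check(tab, reps = 1e5, seed = 2)
  expect_true(chk$agree)
  # error shrinks with replicates (1/sqrt(reps) rate, generous factor)
  err4 <- abs(fisher_exact_rxc(tab, method = "monte_carlo", reps = 1e4,
                               seed = 5)$p_value - chk$p_exact)
  err6 <- abs(fisher_exact_rxc(tab, method = "monte_carlo", reps = 1e6,
                               seed = 5)$p_value - chk$p_exact)
  expect_lt(err6, max(err4, 10 / sqrt(1e6)))
})

test_that("enumeration guard rejects infeasibly large tables", {
  big <- matrix(200L, 4, 4)
  expect_error(fisher_exact_rxc(big, method = "exact"), "monte_carlo")
  # auto falls back to sampling
  res <- fisher_exact_rxc(big, method = "auto", reps = 1e4, seed = 1)
  expect_equal(res$method, "monte_carlo")
})

test_that("contingency table validation", {
  expect_error(contingency_table(rbind(c(1, -1), c(2, 3))), "non-negative")
  expect_error(contingency_table(matrix(1, 1, 3)), "at least 2")
  expect_error(contingency_table(matrix(0, 2, 2)), "positive")
})

test_that("association scan detects perfect association and conserves counts", {
  set.seed(21)
  labels <- sample(c("CMS1-like", "CMS2-like", "CMS3-like", "CMS4-like"),
                   120, replace = TRUE)
  perfect <- labels  # covariate identical to the subtype
  res <- association_test(labels, perfect)
  expect_lt(res$p_value, 1e-6)
  expect_equal(sum(res$table), 120)

  # unclassified patients and missing covariate values are excluded
  labels2 <- c(labels, rep("unclassified", 10))
  cov2 <- c(perfect, rep("x", 10))
  res2 <- association_test(labels2, cov2)
  expect_equal(sum(res2$table), 120)
  expect_error(association_test(labels, rep("a", 120)), "single observed level")
})

test_that("published association-table fixture loads and is consistent", {
  tc <- table1_counts()
  expect_length(tc, 9)
  expect_true(all(vapply(tc, function(v) ncol(v$table) == 4L, logical(1))))
  # age rows as typeset
  expect_equal(unname(tc$age$table[1, ]), c(38L, 93L, 74L, 28L))
  expect_equal(unname(tc$age$table[2, ]), c(38L, 75L, 111L, 24L))
})
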