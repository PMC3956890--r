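test_that("risk split is an equal-size stable partition", {
  p1 <- splitGroups(c(s1 = 0.1, s2 = 0.2, s3 = 0.3, s4 = 0.4))
  g1 <- riskGroups(p1)
  expect_equal(unname(g1), factor(c("low", "low", "high", "high"),
                                  levels = c("low", "high")))
  # odd n: low group gets the extra sample
  p2 <- splitGroups(setNames(c(5, 4, 3, 2, 1), paste0("s", 1:5)))
  g2 <- riskGroups(p2)
  expect_equal(sum(g2 == "low"), 3L)
  expect_setequal(names(g2)[g2 == "low"], c("s3", "s4", "s5"))
  # all-equal risks: split by input order
  p3 <- splitGroups(setNames(rep(1, 4), paste0("s", 1:4)))
  g3 <- riskGroups(p3)
  expect_equal(names(g3)[g3 == "low"], c("s1", "s2"))
})

test_that("log-rank test matches hand-computed and degenerate cases", {
  # identical survival in both groups
  clin <- data.frame(sample_id = paste0("s", 1:6),
                     time = rep(c(1, 2, 3), 2), event = rep(1, 6))
  part <- splitGroups(setNames(c(0, 0, 0, 1, 1, 1), paste0("s", 1:6)))
  res <- logrankTest(part, clin)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # separated event times: frozen from the O-E/variance sums per event time;
  # the high-risk half holds the early events, so HR(high vs low) > 1
  clin2 <- data.frame(sample_id = paste0("s", 1:6),
                      time = 1:6, event = rep(1, 6))
  part2 <- splitGroups(setNames(c(1, 1, 1, 0, 0, 0), paste0("s", 1:6)))
  # perfect separation: coxph warns that the coefficient may be infinite
  res2 <- suppressWarnings(logrankTest(part2, clin2))
  expect_equal(res2$statistic, 5.0517, tolerance = 1e-3)
  expect_equal(res2$p_value, 0.0246, tolerance = 1e-2)
  expect_gt(res2$hazard_ratio, 1)
  expect_true(res2$ci_low <= res2$hazard_ratio &
              res2$hazard_ratio <= res2$ci_high)
})

test_that("log-rank p-values are calibrated under label permutation", {
  set.seed(31)
  n <- 60
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     time = rexp(n, 0.2), event = rbinom(n, 1, 0.8))
  pv <- replicate(200, {
    risks <- setNames(sample(n), clin$sample_id)  # random risk ordering
    logrankTest(splitGroups(risks), clin)$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Dscore is the floored sum of -log10 p across datasets", {
  p6 <- c(3.20e-2, 5.56e-3, 9.60e-3, 5.40e-2, 1.30e-2, 2.90e-3)
  expect_equal(dscore(p6), 11.45877, tolerance = 1e-5)
  expect_equal(dscore(rep(1, 4)), 0)
  expect_equal(dscore(1e-20), 17)  # floor engaged
  # additive over datasets, monotone decreasing in each p
  expect_equal(dscore(p6), sum(vapply(p6, dscore, 0)))
  expect_gt(dscore(c(0.01, 0.5)), dscore(c(0.02, 0.5)))
})

test_that("Fisher's combined test obeys its Dscore identity", {
  expect_equal(fisherCombined(1), 1)
  expect_equal(fisherCombined(rep(1, 5)), 1)
  # n = 1: combined p equals the (floored) input
  for (p in c(0.3, 0.01, 1e-20)) {
    expect_equal(fisherCombined(p), max(p, 1e-17), tolerance = 1e-10)
  }
  p6 <- c(3.20e-2, 5.56e-3, 9.60e-3, 5.40e-2, 1.30e-2, 2.90e-3)
  expect_equal(fisherCombined(p6), 4.5269e-7, tolerance = 1e-3)
  # identity X = 2 ln(10) Dscore, for any p-vector
  set.seed(5)
  for (i in 1:10) {
    ps <- runif(sample(1:8, 1))
    x <- -2 * sum(log(pmax(ps, 1e-17)))
    expect_equal(x, 2 * log(10) * dscore(ps), tolerance = 1e-12)
    expect_equal(fisherCombined(ps),
                 pchisq(2 * log(10) * dscore(ps), 2 * length(ps),
                        lower.tail = FALSE))
  }
})

test_that("signature evaluation separates risk groups across a family", {
  fam <- generateSurvivalFamily(generatorConfig(
    nSamples = 200, nGenes = 30, nModulatedPairs = 0, nHazardGenes = 3,
    hazardBeta = 0.8, censoringRate = 0.2, nDatasets = 3, seed = 17))
  sig <- newSignature(data.frame(gene_id = fam$truth$gene,
                                 cox_beta = fam$truth$true_beta,
                                 cox_p = 0.001, stability = 1))
  ev <- evaluateSignature(sig, fam$datasets)
  expect_equal(nrow(ev$table), 3L)
  expect_true(all(ev$table$hazard_ratio > 1))
  expect_equal(ev$dscore, dscore(ev$table$logrank_p))
  expect_gt(ev$dscore, 6)
})

test_that("random-signature nulls are seeded and degenerate correctly", {
  fam <- generateSurvivalFamily(generatorConfig(
    nSamples = 120, nGenes = 12, nModulatedPairs = 0, nHazardGenes = 2,
    hazardBeta = 0.8, censoringRate = 0.2, nDatasets = 2, seed = 19))
  tr <- fam$datasets[[1]]
  expect_length(randomSignatureNull(fam$datasets, tr,
                                    rownames(tr$expr), 3, 0), 0)
  expect_error(randomSignatureNull(fam$datasets, tr, c("a", "b"), 3, 2),
               "pool")
  # k = |pool|: every draw is the same set, so the Dscores are constant
  same <- randomSignatureNull(fam$datasets, tr, rownames(tr$expr)[1:4],
                              k = 4, nReps = 3, seed = 2)
  expect_equal(var(same), 0)
  # fixed seed reproduces the whole null list
  a <- randomSignatureNull(fam$datasets, tr, rownames(tr$expr), 4,
                           nReps = 4, seed = 9)
  b <- randomSignatureNull(fam$datasets, tr, rownames(tr$expr), 4,
                           nReps = 4, seed = 9)
  expect_identical(a, b)
})

test_that("empirical p-values use the plain exceedance convention", {
  expect_equal(empiricalPvalue(18.9359, c(rep(1, 994), rep(19, 6))), 0.006)
  expect_equal(empiricalPvalue(5, c(6, 7, 8)), 1.0)
  expect_equal(empiricalPvalue(9, c(6, 7, 8)), 0.0)
  expect_error(empiricalPvalue(1, numeric()), "empty")
})
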