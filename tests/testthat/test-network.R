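test_that("buildNetwork keeps reciprocal edges and rejects duplicates", {
  net <- makeNet(c("B", "A"), c("A", "B"))
  expect_equal(length(networkNodes(net)), 2L)
  expect_equal(numEdges(net), 2L)

  empty <- buildNetwork(data.frame(modulator = character(),
                                   target = character(),
                                   cmi = numeric(), p_value = numeric()))
  expect_equal(numEdges(empty), 0L)

  net3 <- makeNet(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(sum(nodeDegrees(net3, "out")), 3L)
  expect_equal(sum(nodeDegrees(net3, "in")), sum(nodeDegrees(net3, "out")))

  expect_error(makeNet(c("A", "A"), c("B", "B")), "duplicate")
  expect_error(makeNet("A", "A"), "self-loops")
})

test_that("mainComponent takes the largest weak component, ties by id", {
  # components {a,b,c} (2 edges) and {x,y} (1 edge)
  net <- makeNet(c("a", "b", "x"), c("b", "c", "y"))
  main <- mainComponent(net)
  expect_setequal(networkNodes(main), c("a", "b", "c"))
  # direction is ignored for connectivity
  rev <- makeNet(c("b", "c", "x"), c("a", "b", "y"))
  expect_setequal(networkNodes(mainComponent(rev)), c("a", "b", "c"))
  # fully connected net is its own main component
  full <- makeNet(c("a", "b"), c("b", "a"))
  expect_setequal(networkNodes(mainComponent(full)), c("a", "b"))
  # equal-size tie: the component with the smallest gene id wins
  tie <- makeNet(c("m", "a"), c("z", "b"))
  expect_setequal(networkNodes(mainComponent(tie)), c("a", "b"))
})

test_that("degree distributions match the star-network examples", {
  star <- makeNet(rep("c0", 4), paste0("l", 1:4))
  outd <- degreeDistribution(star, "out")
  expect_equal(outd, data.frame(degree = c(0L, 4L), frequency = c(4L, 1L)))
  tot <- degreeDistribution(star, "total")
  expect_equal(tot, data.frame(degree = c(1L, 4L), frequency = c(4L, 1L)))
  expect_equal(mean(nodeDegrees(star, "total")), 8 / 5)
  empty <- buildNetwork(data.frame(modulator = character(),
                                   target = character(),
                                   cmi = numeric(), p_value = numeric()))
  expect_equal(nrow(degreeDistribution(empty, "in")), 0L)
})

test_that("power-law fits recover exact and noisy log-log lines", {
  exact <- data.frame(degree = 1:10, frequency = 1000 * (1:10)^-2)
  fit <- fitPowerLaw(exact)
  expect_equal(fit$exponent, 2.0, tolerance = 1e-10)
  expect_equal(fit$correlation, 1.0, tolerance = 1e-10)
  expect_equal(fit$r_square, 1.0, tolerance = 1e-10)

  flat <- data.frame(degree = 1:5, frequency = rep(7, 5))
  ffit <- fitPowerLaw(flat)
  expect_equal(ffit$exponent, 0)
  expect_equal(ffit$r_square, 0)

  expect_error(fitPowerLaw(data.frame(degree = 1:2, frequency = c(5, 2))),
               "at least 3")

  # scale invariance: multiplying frequencies leaves the exponent unchanged
  scaled <- exact; scaled$frequency <- scaled$frequency * 13
  expect_equal(fitPowerLaw(scaled)$exponent, fit$exponent)

  set.seed(9)
  noisy <- data.frame(degree = 1:12,
                      frequency = round(2000 * (1:12)^-2 *
                                        exp(rnorm(12, 0, 0.15))) + 1)
  nfit <- fitPowerLaw(noisy)
  expect_gte(nfit$r_square, 0.8)
  expect_lte(nfit$r_square, 1.0)
})

test_that("hub selection follows the degree-cutoff rule exactly", {
  # descending 9..0 over 10 nodes: 20% of 10 = 2 -> degrees {9, 8}
  d1 <- netWithOutDegrees(9:0)
  expect_setequal(selectHubs(d1, hubParams()), c("n01", "n02"))
  # all out-degrees 3 < minimum 4 -> empty
  d2 <- netWithOutDegrees(rep(3, 10))
  expect_length(selectHubs(d2, hubParams()), 0)
  # 9,5,5,5,1,0... : taking degree >= 5 would select 4 > 2, so cutoff 9
  d3 <- netWithOutDegrees(c(9, 5, 5, 5, 1, rep(0, 5)))
  expect_equal(selectHubs(d3, hubParams()), "n01")
  expect_error(selectHubs(buildNetwork(
    data.frame(modulator = character(), target = character(),
               cmi = numeric(), p_value = numeric()))), "empty")
})

test_that("hub selection respects size and degree bounds on random nets", {
  set.seed(21)
  for (i in 1:20) {
    deg <- sample(0:8, 12, replace = TRUE)
    net <- netWithOutDegrees(deg)
    hubs <- selectHubs(net, hubParams(hubFraction = 0.25, minOutDegree = 3))
    expect_lte(length(hubs), 0.25 * length(networkNodes(net)))
    if (length(hubs) > 0) {
      outd <- nodeDegrees(net, "out")
      expect_true(all(outd[hubs] >= 3))
      # membership is monotone in out-degree: non-hubs sit below every hub
      expect_true(all(outd[setdiff(names(outd), hubs)] < min(outd[hubs])))
    }
  }
})

test_that("hypergeometric overlap test matches exhaustive enumeration", {
  u <- letters[1:10]
  res <- overlapTest(letters[1:4], letters[c(1:3, 5, 6)], u)
  expect_equal(res$overlap, 3L)
  res2 <- overlapTest(letters[1:4], letters[1:5], u)
  expect_equal(res2$p_value, 5 / 210, tolerance = 1e-12)
  # degenerate cases
  expect_equal(overlapTest(letters[1:3], letters[5:7], u)$p_value <= 1, TRUE)
  expect_equal(overlapTest(u, u, u)$p_value, 1)
  expect_error(overlapTest(c("zz"), u[1:2], u), "subsets")
  # oracle equivalence on random small universes
  set.seed(4)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    uni <- paste0("g", seq_len(n))
    A <- sample(uni, sample(1:n, 1))
    B <- sample(uni, sample(1:n, 1))
    got <- overlapTest(A, B, uni)
    expect_equal(got$p_value,
                 oracleOverlapP(uni, B, length(A), got$overlap),
                 tolerance = 1e-10)
  }
})

test_that("networks survive a write/read round trip", {
  net <- makeNet(c("a", "b", "c"), c("b", "c", "a"),
                 cmi = c(0.1, 0.2, 0.3), p = c(0.01, 0.02, 0.03))
  ep <- withr::local_tempfile(); np <- withr::local_tempfile()
  writeNetwork(net, ep, np, hubs = "a")
  back <- readNetwork(ep)
  expect_equal(networkEdges(back), networkEdges(net))
  nd <- read.delim(np)
  expect_equal(nd$is_hub[nd$gene == "a"], 1L)
})
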