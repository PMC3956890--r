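test_that("mutual information matches hand-computed 2x2 values", {
  expect_equal(mutualInformation(rep(c(0, 1), each = 5),
                                 rep(c(0, 1), each = 5)), 1.0)
  expect_equal(mutualInformation(c(0, 0, 1, 1, 0, 0, 1, 1),
                                 c(0, 1, 0, 1, 0, 1, 0, 1)), 0.0)
  # joint counts [[4,1],[1,4]]
  x <- rep(c(0, 0, 1, 1), c(4, 1, 1, 4))
  y <- rep(c(0, 1, 0, 1), c(4, 1, 1, 4))
  expect_equal(mutualInformation(x, y), 0.2780719, tolerance = 1e-6)
  expect_error(mutualInformation(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("plug-in MI equals the entropy-identity oracle on all 2x2 tables", {
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      cnt <- c(a, b, cc, d)
      x <- rep(c(0, 0, 1, 1), cnt)
      y <- rep(c(0, 1, 0, 1), cnt)
      expect_equal(mutualInformation(x, y), oracleMI(cnt),
                   tolerance = 1e-12)
    }
  }
  # symmetry and bounds on random vectors
  set.seed(11)
  for (i in 1:50) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.3)
    m <- mutualInformation(x, y)
    expect_equal(m, mutualInformation(y, x))
    expect_gte(m, 0)
    expect_lte(m, 1 + 1e-12)
  }
})

test_that("stratified MI restricts to the right floor-sized stratum", {
  # n = 20, bottom 7: target equals phenotype exactly there, balanced
  b <- 1:20
  a <- integer(20); p <- integer(20)
  a[1:7] <- c(0, 1, 0, 1, 0, 1, 0); p[1:7] <- a[1:7]   # perfect coupling
  a[8:20] <- rep(c(0, 1), length.out = 13)
  p[8:20] <- rep(c(1, 0), length.out = 13)
  expect_equal(stratifiedMI(a, p, b, side = "low"),
               oracleMI(c(4, 0, 0, 3)))
  # n = 10, fraction 0.35 -> stratum of floor(3.5) = 3
  cs <- cmiScore(rep(c(0, 1), 5), rep(c(0, 1), 5), 1:10)
  expect_equal(cs$n_stratum, 3L)
  expect_error(stratifiedMI(c(0, 1, 0), c(0, 1, 1), c(1, 2, 3)),
               "stratum size")
})

test_that("cmi is |I_high - I_low| and invariant to monotone b transforms", {
  set.seed(3)
  a <- rbinom(60, 1, 0.5); p <- rbinom(60, 1, 0.5); b <- rnorm(60)
  cs <- cmiScore(a, p, b)
  expect_equal(cs$cmi, abs(cs$mi_high - cs$mi_low))
  for (f in list(function(x) 2 * x + 7, exp, function(x) x^3)) {
    expect_equal(cmiScore(a, p, f(b))$cmi, cs$cmi)
  }
  # strata with identical joint counts give zero score
  a2 <- rep(c(0, 1, 0, 1), 15); p2 <- rep(c(0, 0, 1, 1), 15)
  expect_equal(cmiScore(a2, p2, seq_len(60),
                        cmiParams(stratumFraction = 0.4))$cmi, 0)
})

test_that("permutation p-values follow the add-one rank convention", {
  # strongly gated planted triple: observed score tops every null draw
  cfg <- generatorConfig(nSamples = 200, nGenes = 10, nModulatedPairs = 1,
                         gateStrength = 1, seed = 5)
  d <- generateDependencyDataset(cfg)
  abin <- suppressWarnings(binarizeExpression(d$expr))[d$truth$target[1], ]
  bval <- d$expr[d$truth$modulator[1], ]
  set.seed(1)
  res <- permutationPvalue(abin, d$status, bval,
                           cmiParams(nPermutations = 100))
  expect_equal(res$p_value, 1 / 100)
  # p is capped at 1 and never 0
  set.seed(2)
  a0 <- rbinom(100, 1, 0.5); p0 <- rbinom(100, 1, 0.5)
  r0 <- permutationPvalue(a0, p0, rnorm(100),
                          cmiParams(nPermutations = 50))
  expect_gt(r0$p_value, 0)
  expect_lte(r0$p_value, 1)
})

test_that("screenPairs tests both directions and is seed-reproducible", {
  expect_equal(nrow(screenPairs(matrix(rnorm(40), 4, 10,
                                       dimnames = list(letters[1:4], NULL)),
                                rbinom(10, 1, 0.5),
                                data.frame(gene_a = character(),
                                           gene_b = character()))), 0L)
  cfg <- generatorConfig(nSamples = 200, nGenes = 20, nModulatedPairs = 3,
                         gateStrength = 1, seed = 8)
  d <- generateDependencyDataset(cfg)
  prm <- cmiParams(nPermutations = 100, seed = 42)
  hits1 <- screenPairs(d$expr, d$status, d$candidates, prm)
  hits2 <- screenPairs(d$expr, d$status, d$candidates, prm)
  expect_identical(hits1, hits2)
  planted <- paste(d$truth$modulator, d$truth$target)
  expect_gte(sum(paste(hits1$modulator, hits1$target) %in% planted), 2)
  # genes absent from the matrix are skipped, not fatal
  cand <- rbind(d$candidates,
                data.frame(gene_a = "missing1", gene_b = "missing2"))
  expect_message(screenPairs(d$expr, d$status, cand, prm), "skipped")
})
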