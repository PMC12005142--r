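test_that("config validation rejects out-of-range parameters", {
  expect_error(simulationConfig(drift = c(1, 0.1, 0.1)), "drift")
  expect_error(simulationConfig(mafFloor = 0.5), "mafFloor")
  expect_error(simulationConfig(errorRate = 0.3), "errorRate")
  expect_error(simulationConfig(sweep = list(pop = 1, start = 0, end = 10,
                                             delta = 0.5)), "interval")
  expect_error(simulationConfig(sweep = list(pop = 1, start = 1, end = 10,
                                             delta = 0)), "delta")
  expect_error(
    simulationConfig(nInd = c(2, 2, 2),
                     admixture = matrix(0.6, 6, 3)), "sum to 1")
})

test_that("zero drift copies the ancestral frequencies exactly", {
  cfg <- simulationConfig(nSites = 200, chromLength = 1e5,
                          nInd = c(3, 3), drift = c(0, 0), seed = 3)
  fr <- simulateFrequencies(cfg)
  expect_equal(fr$popFreqs[1, ], fr$ancestral)
  expect_equal(fr$popFreqs[2, ], fr$ancestral)
})

test_that("Balding-Nichols drift matches its Beta variance", {
  cfg <- simulationConfig(nSites = 50000, chromLength = 1e7,
                          nInd = c(3, 3), drift = c(0.05, 0.05), seed = 11)
  fr <- simulateFrequencies(cfg)
  for (i in 1:2) {
    p <- fr$ancestral
    m <- mean((fr$popFreqs[i, ] - p)^2 / (p * (1 - p)))
    expect_gt(m, 0.04)
    expect_lt(m, 0.06)
  }
})

test_that("frequency moments converge to the drift coefficient", {
  drift <- c(0.02, 0.10)
  cfg <- simulationConfig(nSites = 30000, chromLength = 1e7,
                          nInd = c(3, 3), drift = drift, seed = 5)
  fr <- simulateFrequencies(cfg)
  for (i in 1:2) {
    p <- fr$ancestral
    r <- (fr$popFreqs[i, ] - p)^2 / (p * (1 - p))
    se <- sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - drift[i]), 3 * se)
  }
})

test_that("the whole generator is deterministic under a fixed seed", {
  cfg <- simulationConfig(nSites = 300, chromLength = 1e6,
                          nInd = c(4, 4, 4), seed = 42)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$pileup, d2$pileup)
  expect_identical(d1$truth$genotypes, d2$truth$genotypes)
})

test_that("sweep displacement follows p' = p + delta (1 - p)", {
  pf <- matrix(c(0.5, 0.3, 0.2), 1)
  pos <- c(100, 200, 5000)
  sw <- function(delta) implantSweep(pf, pos, list(pop = 1, start = 1,
                                                   end = 1000,
                                                   delta = delta))
  expect_equal(implantSweep(pf, pos, list(pop = 1, start = 1, end = 1000,
                                          delta = 1e-12)),
               pf, tolerance = 1e-9)
  expect_equal(sw(1)[1, 1:2], c(1, 1))       # fixation inside the interval
  expect_equal(sw(0.8)[1, 1], 0.5 + 0.8 * 0.5)  # 0.9
  expect_equal(sw(0.8)[1, 3], 0.2)           # outside: unchanged
})

test_that("read depths are Poisson with the configured mean", {
  cfg <- simulationConfig(nSites = 10000, chromLength = 1e7,
                          nInd = c(33), drift = 0.05, meanDepth = 2,
                          seed = 9)
  d <- simulateDataset(cfg)
  meanDepth <- nrow(d$pileup) / (10000 * 33)
  expect_gt(meanDepth, 1.9)
  expect_lt(meanDepth, 2.1)
})

test_that("zero depth yields an empty pileup, zero error only true alleles", {
  cfg <- simulationConfig(nSites = 50, chromLength = 1e4, nInd = c(3),
                          drift = 0.1, meanDepth = 0, seed = 2)
  expect_equal(nrow(simulateDataset(cfg)$pileup), 0)
  g <- matrix(2L, 2, 4)  # all homozygous minor
  sites <- data.frame(chrom = "1", pos = c(10, 20, 30, 40),
                      major = "A", minor = "C")
  pu <- simulateReads(g, sites, meanDepth = 5, errorRate = 0, seed = 1)
  expect_true(all(pu$base == "C"))
})

test_that("admixed genotypes follow the individual allele frequency law", {
  # Q row (1, 0): plain binomial at the first population's frequency
  pf <- matrix(c(0, 1), 2, 2000)  # pop1 fixed major, pop2 fixed minor
  Q <- rbind(c(1, 0), c(0.5, 0.5))
  g <- simulateGenotypes(pf, nInd = c(1, 1), Q = Q, seed = 4)
  expect_true(all(g[1, ] == 0))
  # h = 0.5: heterozygote probability 1/2
  pHet <- mean(g[2, ] == 1)
  expect_lt(abs(pHet - 0.5), 3 * sqrt(0.25 / 2000))
  expect_error(simulateGenotypes(pf, nInd = c(1, 1),
                                 Q = rbind(c(0.7, 0.2), c(0.5, 0.5))),
               "sum to 1")
  expect_identical(g, simulateGenotypes(pf, nInd = c(1, 1), Q = Q,
                                        seed = 4))
})

test_that("Hudson FST from true genotypes on a null simulation is near c", {
  cfg <- simulationConfig(nSites = 30000, chromLength = 1e7,
                          nInd = c(15, 15), drift = c(0.05, 0.05),
                          mafFloor = 0.05, seed = 21)
  d <- simulateDataset(cfg)
  g <- d$truth$genotypes
  fst <- hudsonFstFromGenotypes(g[1:15, ], g[16:30, ])
  # ratio-of-averages estimand (c1 + c2) / 2 = 0.05; generous 3-SE band
  expect_lt(abs(fst - 0.05), 0.008)
})

test_that("maximal frequency divergence localizes at the sweep interval", {
  cfg <- simulationConfig(nSites = 5000, chromLength = 1e6,
                          nInd = c(5, 5, 5), drift = c(0.02, 0.02, 0.02),
                          sweep = list(pop = 1, start = 400001,
                                       end = 500000, delta = 0.8),
                          seed = 8)
  fr <- simulateFrequencies(cfg)
  pf <- implantSweep(fr$popFreqs, fr$positions, cfg$sweep)
  div <- abs(pf[1, ] - (pf[2, ] + pf[3, ]) / 2)
  inSweep <- fr$positions >= 400001 & fr$positions <= 500000
  expect_gt(mean(div[inSweep]), mean(div[!inSweep]) + 0.3)
  sm <- stats::filter(div, rep(1 / 51, 51))
  expect_true(which.max(ifelse(is.na(sm), 0, sm)) %in% which(inSweep))
})
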