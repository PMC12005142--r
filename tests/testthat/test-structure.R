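test_that("K = 1 reduces to the HWE likelihood at the MAF estimates", {
  sim <- simToGL(nSites = 100, chromLength = 1e5, nInd = 12,
                 drift = 0.05, meanDepth = 3, seed = 101)
  m <- admixtureEM(sim$gl, K = 1, maxIter = 300, nRestarts = 1, seed = 1)
  expect_equal(as.vector(admixtureQ(m)), rep(1, 12))
  maf <- estimateMafEM(sim$gl, tol = 1e-9, maxIter = 500)
  informative <- !is.na(maf$maf) & maf$maf > 0.01 & maf$maf < 0.99
  expect_equal(admixtureF(m)[1, informative], maf$maf[informative],
               tolerance = 1e-2)
  expect_equal(tail(loglikTrace(m), 1), sum(maf$loglik, na.rm = TRUE),
               tolerance = 1e-3)
})

test_that("admixture EM recovers Q for two diverged populations", {
  set.seed(103)
  cfg <- simulationConfig(nSites = 2000, chromLength = 1e6,
                          nInd = c(10, 10), drift = c(0.3, 0.3),
                          mafFloor = 0.05, seed = 107)
  fr <- simulateFrequencies(cfg)
  g <- simulateGenotypes(fr$popFreqs, cfg$nInd, seed = 109)
  gl <- makeGL(lapply(seq_len(2000), function(s) onehotGL(g[, s])),
               pos = fr$positions)
  trueQ <- cbind(rep(c(1, 0), c(10, 10)), rep(c(0, 1), c(10, 10)))
  m <- admixtureEM(gl, K = 2, maxIter = 200, nRestarts = 2, seed = 5)
  m <- alignLabels(m, trueQ)
  expect_lt(mean(abs(admixtureQ(m) - trueQ)), 0.05)
  ll <- loglikTrace(m)
  expect_true(all(diff(ll) >= -1e-6 * (1 + abs(ll[1]))))
})

test_that("the best-likelihood restart is the one returned", {
  sim <- simToGL(nSites = 150, chromLength = 1e5, nInd = c(5, 5),
                 drift = c(0.2, 0.2), meanDepth = 4, seed = 113)
  # restart 1 of a multi-restart run is identical to a single-restart run
  # with the same master seed, so best-of-3 can never fall below it
  single <- admixtureEM(sim$gl, K = 2, maxIter = 60, nRestarts = 1,
                        seed = 9)
  best <- admixtureEM(sim$gl, K = 2, maxIter = 60, nRestarts = 3, seed = 9)
  expect_gte(tail(loglikTrace(best), 1), tail(loglikTrace(single), 1))
  expect_true(best@restart %in% 1:3)
  if (best@restart == 1L)
    expect_equal(loglikTrace(best), loglikTrace(single))
  # determinism of the whole selection
  best2 <- admixtureEM(sim$gl, K = 2, maxIter = 60, nRestarts = 3, seed = 9)
  expect_identical(admixtureQ(best), admixtureQ(best2))
})

test_that("label alignment resolves permutations deterministically", {
  Q <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  F <- matrix(runif(2 * 4), 2, 4)
  m <- new("AncestryModel", Q = Q, F = F, loglik = -1, nIter = 1L,
           restart = 1L)
  expect_equal(admixtureQ(alignLabels(m, Q)), Q)          # identity
  swapped <- new("AncestryModel", Q = Q[, 2:1], F = F[2:1, ],
                 loglik = -1, nIter = 1L, restart = 1L)
  expect_equal(admixtureQ(alignLabels(swapped, Q)), Q)    # swap undone
  expect_equal(admixtureF(alignLabels(swapped, Q)), F)
  m1 <- new("AncestryModel", Q = matrix(1, 3, 1), F = matrix(0.5, 1, 4),
            loglik = -1, nIter = 1L, restart = 1L)
  expect_equal(admixtureQ(alignLabels(m1, matrix(1, 3, 1))),
               matrix(1, 3, 1))                           # K = 1 no-op
})

test_that("mean ancestry is reported in percentages summing to 100", {
  m <- new("AncestryModel", Q = matrix(c(0.941, 0.038, 0.021), 1),
           F = matrix(0.5, 3, 2), loglik = -1, nIter = 1L, restart = 1L)
  rep1 <- meanAncestryReport(m, "focal")
  expect_equal(as.vector(rep1), c(94.1, 3.8, 2.1))
  # identical individuals: the report equals their shared Q
  Q <- matrix(rep(c(0.6, 0.3, 0.1), each = 4), 4, 3)
  m2 <- new("AncestryModel", Q = Q, F = matrix(0.5, 3, 2), loglik = -1,
            nIter = 1L, restart = 1L)
  rep2 <- meanAncestryReport(m2, rep(c("a", "b"), 2))
  expect_equal(unname(rep2), rbind(c(60, 30, 10), c(60, 30, 10)))
  expect_true(all(abs(rowSums(rep2) - 100) < 0.1))
  # mirrored groups produce a symmetric table
  Qm <- rbind(matrix(rep(c(0.8, 0.2), each = 3), 3, 2),
              matrix(rep(c(0.2, 0.8), each = 3), 3, 2))
  m3 <- new("AncestryModel", Q = Qm, F = matrix(0.5, 2, 2), loglik = -1,
            nIter = 1L, restart = 1L)
  rep3 <- meanAncestryReport(m3, rep(c("a", "b"), each = 3))
  expect_equal(unname(rep3), rbind(c(80, 20), c(20, 80)))
  expect_error(meanAncestryReport(m3, "a"), "label")
})

test_that("PCA covariance on certain genotypes equals the dosage formula", {
  set.seed(127)
  g <- matrix(rbinom(10 * 400, 2, runif(400, 0.1, 0.9)), 10, 400,
              byrow = FALSE)
  keep <- colSums(g) > 0 & colSums(g) < 20
  g <- g[, keep]
  gl <- makeGL(lapply(seq_len(ncol(g)), function(s) onehotGL(g[, s])))
  maf <- colMeans(g) / 2
  res <- pcaCovariance(gl, maf = maf, nIterIndf = 0)
  X <- t((t(g) - 2 * maf) / sqrt(2 * maf * (1 - maf)))
  expect_equal(pcaCov(res), tcrossprod(X) / ncol(g), tolerance = 1e-8)
})

test_that("PCA eigenstructure is consistent and permutation-equivariant", {
  sim <- simToGL(nSites = 500, chromLength = 1e6, nInd = c(6, 6),
                 drift = c(0.1, 0.1), meanDepth = 2, seed = 131)
  glF <- filterMaf(sim$gl)
  res <- pcaCovariance(glF, K = 2)
  e <- pcaEigen(res)
  expect_equal(sum(e$varFrac), 1, tolerance = 1e-8)
  expect_equal(sum(diag(pcaCov(res))), sum(e$values), tolerance = 1e-8)
  # permuting individuals permutes the covariance consistently
  perm <- c(3, 1, 2, 4, 5, 6, 12, 7, 8, 9, 10, 11)
  maf <- estimateMafEM(glF)$maf
  resP <- pcaCovariance(glF[, perm], maf = maf, K = 2)
  expect_equal(pcaCov(resP), pcaCov(res)[perm, perm], tolerance = 1e-8)
  # monomorphic site rejection
  expect_error(pcaCovariance(glF, maf = rep(0, nSites(glF))),
               "monomorphic")
})

test_that("three simulated populations separate in the top two PCs", {
  sim <- simToGL(nSites = 3000, chromLength = 5e6, nInd = c(33, 15, 15),
                 drift = c(0.1, 0.1, 0.1), meanDepth = 2,
                 errorRate = 0.01, seed = 137)
  glF <- filterMaf(sim$gl)
  res <- pcaCovariance(glF, K = 3)
  pcs <- pcaEigen(res)$vectors[, 1:2]
  cl <- cutree(hclust(dist(pcs), method = "complete"), k = 3)
  pop <- sim$d$truth$pop
  # complete linkage purity: each cluster maps to exactly one population
  tab <- table(cl, pop)
  expect_equal(sum(apply(tab, 1, max)), length(pop))
})
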