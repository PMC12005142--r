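# point-mass SAF helper used by the component checks
pointSaf <- function(n, j, sites = 1) {
  m <- matrix(0, sites, 2 * n + 1)
  m[, j + 1] <- 1
  gl <- makeGL(rep(list(matrix(1, n, 3)), sites),
               pos = seq_len(sites) * 100L)
  new("SafLikelihoods", sites = glSites(gl), saf = m, nInd = as.integer(n))
}

uniformSFS <- function(n1, n2) {
  k <- (2 * n1 + 1) * (2 * n2 + 1)
  new("JointSFS", eta = matrix(1 / k, 2 * n1 + 1, 2 * n2 + 1),
      loglik = 0, nIter = 1L, nSites = 1L)
}

test_that("site components match closed forms at certain counts", {
  # certain fixed difference: a = d = 1, site FST = 1
  comp <- fstComponents(pointSaf(3, 6), pointSaf(4, 0), uniformSFS(3, 4))
  expect_equal(comp$a, 1)
  expect_equal(comp$d, 1)
  # certain equal counts p1 = p2 = 0.5 with n1 = n2 = 2
  comp2 <- fstComponents(pointSaf(2, 2), pointSaf(2, 2), uniformSFS(2, 2))
  expect_equal(comp2$a, -2 * (0.25 / 3), tolerance = 1e-12)
  expect_equal(comp2$d, 0.5, tolerance = 1e-12)
})

test_that("components equal the brute-force posterior expectation", {
  set.seed(73)
  for (rep in 1:5) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    L1 <- runif(2 * n1 + 1); L1 <- L1 / max(L1)
    L2 <- runif(2 * n2 + 1); L2 <- L2 / max(L2)
    eta <- matrix(rgamma((2 * n1 + 1) * (2 * n2 + 1), 1),
                  2 * n1 + 1, 2 * n2 + 1)
    eta <- eta / sum(eta)
    s1 <- pointSaf(n1, 0); s1@saf[1, ] <- L1
    s2 <- pointSaf(n2, 0); s2@saf[1, ] <- L2
    sfs <- new("JointSFS", eta = eta, loglik = 0, nIter = 1L,
               nSites = 1L)
    got <- fstComponents(s1, s2, sfs)
    want <- oracleFstComponents(L1, L2, eta, n1, n2)
    expect_equal(c(got$a, got$d), unname(want), tolerance = 1e-10)
    expect_lte(got$a, got$d + 1e-12)
  }
})

test_that("window FST is a ratio of sums, not a mean of ratios", {
  expect_equal(windowFst(data.frame(a = c(1, 2), d = c(1, 2))), 1)
  expect_equal(windowFst(data.frame(a = c(0.5, 0), d = c(1, 1))), 0.25)
  expect_true(is.na(windowFst(data.frame(a = 0, d = 0))))
  # explicitly different from the mean of per-site ratios
  comp <- data.frame(a = c(0.9, 0.1), d = c(1, 10))
  expect_equal(windowFst(comp), 1 / 11)
  expect_false(isTRUE(all.equal(windowFst(comp),
                                mean(comp$a / comp$d))))
})

test_that("branch lengths and PBS follow the log transform", {
  expect_equal(branchLength(0), 0)
  expect_equal(branchLength(0.5), log(2))
  expect_equal(branchLength(-0.01), 0)  # clamped
  expect_equal(branchLength(1), Inf)
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.1, 0.1, 0.1), -log(1 - 0.1) / 2, tolerance = 1e-9)
  expect_equal(pbs(0.1, 0.1, 0.1), 0.052680, tolerance = 1e-5)
  # the trio of genome-wide FST values from the worked example
  expect_equal(pbs(0.044, 0.040, 0.016), 0.03484499, tolerance = 1e-6)
})

test_that("PBS is symmetric in the reference pair and not in the focal", {
  set.seed(79)
  for (rep in 1:20) {
    f <- runif(3, 0, 0.3)
    expect_equal(pbs(f[1], f[2], f[3]), pbs(f[2], f[1], f[3]))
    T <- -log(1 - f)
    expect_equal(pbs(f[1], f[3], f[2]),
                 (T[1] + T[3] - T[2]) / 2, tolerance = 1e-12)
  }
})

test_that("sliding windows cover each site ceiling(W/step) times", {
  comp <- data.frame(chrom = "1", pos = 55000L, a = 0.5, d = 1)
  w <- slidingScan(comp, comp, comp, window = 50000, step = 10000,
                   minSites = 1)
  hit <- w[w$nSites > 0, ]
  expect_equal(hit$start, seq(10001, 50001, by = 10000))
  # W = step: non-overlapping tiling, each site in exactly one window
  w2 <- slidingScan(comp, comp, comp, window = 10000, step = 10000,
                    minSites = 1)
  expect_equal(sum(w2$nSites), 1)
  # empty input produces no windows
  empty <- comp[0, ]
  expect_equal(nrow(slidingScan(empty, empty, empty)), 0)
})

test_that("window statistics agree with brute-force recomputation", {
  set.seed(83)
  pos <- sort(sample.int(2e5, 400))
  mkComp <- function() data.frame(chrom = "1", pos = pos,
                                  a = runif(400, -0.05, 0.3),
                                  d = runif(400, 0.2, 1))
  c12 <- mkComp(); c13 <- mkComp(); c23 <- mkComp()
  w <- slidingScan(c12, c13, c23, window = 50000, step = 10000,
                   minSites = 5)
  for (r in sample(nrow(w), 10)) {
    inWin <- pos >= w$start[r] & pos < w$end[r]
    expect_equal(w$nSites[r], sum(inWin))
    if (w$nSites[r] >= 5) {
      f12 <- sum(c12$a[inWin]) / sum(c12$d[inWin])
      f13 <- sum(c13$a[inWin]) / sum(c13$d[inWin])
      f23 <- sum(c23$a[inWin]) / sum(c23$d[inWin])
      expect_equal(w$fstIJ[r], f12, tolerance = 1e-12)
      expect_equal(w$pbs[r], pbs(f12, f13, f23), tolerance = 1e-12)
    } else {
      expect_true(is.na(w$pbs[r]))
    }
  }
})

test_that("the tail above the quantile threshold has the expected size", {
  set.seed(89)
  n <- 5000
  w <- data.frame(chrom = "1", start = seq_len(n), end = seq_len(n) + 1,
                  nSites = 20, pbs = rnorm(n))
  thr <- quantile(w$pbs, 0.999, type = 1, names = FALSE)
  nTop <- sum(w$pbs > thr)
  expect_true(nTop %in% c(floor(0.001 * n), floor(0.001 * n) + 1))
})

test_that("peak calling clusters top windows and enforces the minimum", {
  mkWin <- function(starts, pbsVals, chrom = "1")
    data.frame(chrom = chrom, start = starts, end = starts + 50000,
               nSites = 30, pbs = pbsVals)
  # background of 4000 quiet windows (all tied at 0; strict threshold)
  bg <- mkWin(seq(1, by = 10000, length.out = 4000), rep(0, 4000))
  # 10 contiguous hot windows at 10 Mb, 3 at 20 Mb
  hot1 <- mkWin(seq(10e6, by = 10000, length.out = 10), rep(0.5, 10))
  hot2 <- mkWin(seq(20e6, by = 10000, length.out = 3), rep(0.4, 3))
  peaks <- callPeaks(rbind(bg, hot1, hot2), topFraction = 0.005,
                     minWindows = 6, mergeDistance = 1e6)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$nTopWindows, 10)
  expect_equal(peaks$start, 10e6)
  # two clusters of 7, 2 Mb apart: two peaks ordered by best PBS
  hotA <- mkWin(seq(10e6, by = 10000, length.out = 7), rep(0.5, 7))
  hotB <- mkWin(seq(12.5e6, by = 10000, length.out = 7), rep(0.6, 7))
  peaks2 <- callPeaks(rbind(bg, hotA, hotB), topFraction = 0.005,
                      minWindows = 6, mergeDistance = 1e6)
  expect_equal(nrow(peaks2), 2)
  expect_equal(peaks2$start, c(12.5e6, 10e6))
  expect_true(all(diff(peaks2$pbs) <= 0))
  # nothing above threshold: empty result (tiny window pool warns)
  expect_warning(none <- callPeaks(bg[1:100, ], topFraction = 1e-9,
                                   minWindows = 1), "topFraction")
  expect_equal(nrow(none), 0)
})

test_that("mean window PBS on a symmetric null matches the drift level", {
  sim <- simToGL(nSites = 4000, chromLength = 4e6, nInd = c(8, 8, 8),
                 drift = c(0.05, 0.05, 0.05), meanDepth = 2,
                 errorRate = 0.01, seed = 97)
  pop <- sim$d$truth$pop
  saf <- lapply(1:3, function(p) safLikelihoods(sim$gl[, pop == p]))
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  comp <- lapply(prs, function(pr) {
    s <- estimateSFS(saf[[pr[1]]], saf[[pr[2]]], maxIter = 100)
    fstComponents(saf[[pr[1]]], saf[[pr[2]]], s)
  })
  w <- slidingScan(comp[[1]], comp[[2]], comp[[3]], 50000, 10000, 10)
  cEst <- mean(c(windowFst(comp[[1]]), windowFst(comp[[2]]),
                 windowFst(comp[[3]])))
  meanPbs <- mean(w$pbs, na.rm = TRUE)
  expected <- -log(1 - cEst) / 2
  se <- sd(w$pbs, na.rm = TRUE) / sqrt(sum(!is.na(w$pbs)) / 5)
  expect_lt(abs(meanPbs - expected), max(3 * se, 0.01))
})
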