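# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use brute-force enumeration or direct formula
# evaluation, never the package's own computational path.

# Build a GenotypeLikelihoods object from a plain list of per-site
# N x 3 likelihood matrices (max-rescaled internally).
makeGL <- function(triples, chrom = "1", pos = NULL,
                   major = "A", minor = "C") {
  if (is.matrix(triples)) triples <- list(triples)
  S <- length(triples)
  N <- nrow(triples[[1]])
  if (is.null(pos)) pos <- seq_len(S) * 100L
  gl <- array(0, dim = c(S, N, 3))
  for (s in seq_len(S)) {
    m <- triples[[s]]
    gl[s, , ] <- m / apply(m, 1, max)
  }
  sites <- data.frame(chrom = chrom, pos = pos,
                      major = major, minor = minor,
                      stringsAsFactors = FALSE)
  new("GenotypeLikelihoods", sites = pbscan:::.sitesGRanges(sites),
      gl = gl, samples = sprintf("i%02d", seq_len(N)))
}

# One-hot GL matrix (N x 3) from a genotype vector.
onehotGL <- function(g) {
  m <- matrix(0, length(g), 3)
  m[cbind(seq_along(g), g + 1L)] <- 1
  m
}

# Oracle: genotype likelihood triple from raw reads by direct product
# evaluation, independent of computeGL's grouped log-space path.
oracleGLTriple <- function(bases, quals, major, minor) {
  eps <- 10^(-quals / 10)
  L <- sapply(0:2, function(g) {
    e <- 1
    for (r in seq_along(bases)) {
      eMaj <- if (bases[r] == major) 1 - eps[r] else eps[r] / 3
      eMin <- if (bases[r] == minor) 1 - eps[r] else eps[r] / 3
      e <- e * ((1 - g / 2) * eMaj + (g / 2) * eMin)
    }
    e
  })
  L / max(L)
}

# Oracle: SAF vector by exhaustive enumeration of genotype
# configurations, with binomial within-individual weights.
oracleSAF <- function(glMat) {
  N <- nrow(glMat)
  M <- 2L * N
  cfgs <- as.matrix(expand.grid(rep(list(0:2), N)))
  q <- numeric(M + 1)
  for (r in seq_len(nrow(cfgs))) {
    g <- cfgs[r, ]
    wt <- prod(glMat[cbind(seq_len(N), g + 1L)] * choose(2, g))
    j <- sum(g)
    q[j + 1] <- q[j + 1] + wt
  }
  L <- q / choose(M, 0:M)
  L / max(L)
}

# Oracle: one-sided heterozygote-excess exact p-value by direct
# enumeration with choose(), counting allele arrangements.
oracleHetP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n1 <- min(2 * naa + nAa, 2 * nAA + nAa)
  if (n1 == 0) return(1)
  hVals <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  ways <- sapply(hVals, function(h) {
    nHomMinor <- (n1 - h) / 2
    nHomMajor <- n - h - nHomMinor
    choose(n, h) * choose(n - h, nHomMinor) * 2^h
  })
  pmf <- ways / sum(ways)
  sum(pmf[hVals >= nAa])
}

# Oracle: two-sided Fisher p-value by hypergeometric enumeration with
# the minimum-likelihood rule (tables no more probable than observed).
oracleFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pmf <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# Oracle: posterior-expected FST components by explicit double loop
# over the joint count grid.
oracleFstComponents <- function(L1, L2, eta, n1, n2) {
  a <- d <- w <- 0
  for (j in 0:(2 * n1)) {
    for (k in 0:(2 * n2)) {
      p1 <- j / (2 * n1); p2 <- k / (2 * n2)
      Nv <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
        p2 * (1 - p2) / (2 * n2 - 1)
      Dv <- p1 * (1 - p2) + p2 * (1 - p1)
      post <- eta[j + 1, k + 1] * L1[j + 1] * L2[k + 1]
      a <- a + post * Nv
      d <- d + post * Dv
      w <- w + post
    }
  }
  c(a = a / w, d = d / w)
}

# Hudson ratio-of-averages FST from true genotype matrices
# (individuals x sites), used to check the simulator's drift scale.
hudsonFstFromGenotypes <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Simulate a small dataset and return its computed GL table plus truth.
simToGL <- function(..., seed = 1) {
  cfg <- simulationConfig(..., seed = seed)
  d <- simulateDataset(cfg)
  gl <- computeGL(d$pileup, d$sites, nInd = sum(cfg$nInd))
  list(gl = gl, d = d, cfg = cfg)
}
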