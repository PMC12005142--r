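#' Configuration for the synthetic low-coverage three-population design
#'
#' Builds and validates the parameter set for the Balding-Nichols generator.
#' Defaults emulate a low-coverage study design: a focal population of 33
#' diploid individuals at about 2x mean depth plus two related reference
#' populations, biallelic SNPs with genome-wide pairwise differentiation on
#' the order of FST 0.01-0.05, and (optionally) an admixed ancestry fraction
#' and a localized region of exaggerated focal-population divergence.
#'
#' The default drift coefficients (0.068, 0.020, 0.012) were chosen so that
#' the three pairwise FST values expected under the model,
#' (c_i + c_j) / 2, reproduce the 0.016-0.044 genome-wide scale typical of
#' closely related South American populations.
#'
#' @param nSites Number of biallelic SNP sites.
#' @param chromLength Chromosome length in bp; positions are drawn uniformly
#'   without replacement on `[1, chromLength]` and sorted (1-based).
#' @param nInd Integer vector of per-population diploid sample sizes; the
#'   first population is the focal one.
#' @param drift Per-population drift coefficients c in `[0, 1)`;
#'   `c = 0` means no drift from the ancestral frequency.
#' @param meanDepth Expected reads per individual per site (Poisson mean).
#' @param errorRate Per-base sequencing error probability in `[0, 0.25)`.
#' @param mafFloor Minimum ancestral allele frequency; ancestral frequencies
#'   are uniform on `[mafFloor, 1 - mafFloor]`. Must be `< 0.5`.
#' @param sweep Optional selection sweep: a list with elements `pop` (focal
#'   population index), `start` and `end` (bp, interval within
#'   `[1, chromLength]`), `delta` (frequency displacement in `(0, 1]`) and
#'   optionally `towards` (`"minor"`, the default, or `"major"`).
#' @param admixture Optional true admixture matrix Q (individuals x
#'   populations, rows summing to 1) replacing the block-diagonal
#'   "every individual belongs to one population" default.
#' @param chrom Chromosome label used in all output.
#' @param seed Integer seed; every downstream simulation call is
#'   deterministic given the config.
#'
#' @return A validated list of class `"simConfig"`.
#' @examples
#' cfg <- simulationConfig(nSites = 100, nInd = c(5, 5, 5), seed = 1)
#' @export
simulationConfig <- function(nSites = 10000L,
                             chromLength = 1e7,
                             nInd = c(33L, 15L, 15L),
                             drift = c(0.068, 0.020, 0.012),
                             meanDepth = 2,
                             errorRate = 0.01,
                             mafFloor = 0.05,
                             sweep = NULL,
                             admixture = NULL,
                             chrom = "1",
                             seed = 1L) {
  stopifnot(nSites >= 1, chromLength >= nSites, length(nInd) >= 1,
            all(nInd >= 1), length(drift) == length(nInd))
  if (any(drift < 0 | drift >= 1))
    stop("drift coefficients must lie in [0, 1)")
  if (meanDepth < 0) stop("meanDepth must be non-negative")
  if (errorRate < 0 || errorRate >= 0.25)
    stop("errorRate must lie in [0, 0.25)")
  if (mafFloor < 0 || mafFloor >= 0.5)
    stop("mafFloor must lie in [0, 0.5)")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep),
              all(c("pop", "start", "end", "delta") %in% names(sweep)))
    if (sweep$pop < 1 || sweep$pop > length(nInd))
      stop("sweep population index out of range")
    if (sweep$start < 1 || sweep$end > chromLength ||
        sweep$start > sweep$end)
      stop("sweep interval must lie within [1, chromLength]")
    if (sweep$delta <= 0 || sweep$delta > 1)
      stop("sweep delta must lie in (0, 1]")
    if (is.null(sweep$towards)) sweep$towards <- "minor"
    stopifnot(sweep$towards %in% c("minor", "major"))
  }
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (ncol(admixture) != length(nInd))
      stop("admixture Q must have one column per population")
    if (nrow(admixture) != sum(nInd))
      stop("admixture Q must have one row per individual")
    if (any(abs(rowSums(admixture) - 1) > 1e-9))
      stop("rows of the admixture Q must sum to 1 (within 1e-9)")
  }
  structure(list(nSites = as.integer(nSites), chromLength = chromLength,
                 nInd = as.integer(nInd), drift = drift,
                 meanDepth = meanDepth, errorRate = errorRate,
                 mafFloor = mafFloor, sweep = sweep, admixture = admixture,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "simConfig")
}

#' Draw ancestral and population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies p are uniform on `[mafFloor, 1 - mafFloor]`. For
#' population i with drift c > 0, the population frequency is Beta
#' distributed with mean p and variance c p (1 - p):
#' `p_i ~ Beta(p (1 - c) / c, (1 - p)(1 - c) / c)`. With c = 0 the
#' population frequency equals the ancestral frequency exactly. Frequencies
#' refer to a designated allele per site; the minor allele is the one whose
#' ancestral frequency is below 0.5 (ties broken so that the
#' lexicographically smaller base is the major allele).
#'
#' @param config A [simulationConfig()].
#' @return A list with `positions` (sorted bp), `alleles` (data.frame of
#'   `major`/`minor` bases), `ancestral` (ancestral minor-allele
#'   frequencies), and `popFreqs` (populations x sites matrix of
#'   minor-allele frequencies).
#' @export
simulateFrequencies <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(childSeed(config$seed, 1L))
  S <- config$nSites
  positions <- sort(sample.int(config$chromLength, S))
  # two distinct bases per site; p tracks the frequency of allele 'a1'
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, S, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "",
               USE.NAMES = FALSE)
  p <- runif(S, config$mafFloor, 1 - config$mafFloor)
  nPop <- length(config$nInd)
  pf <- matrix(0, nPop, S)
  for (i in seq_len(nPop)) {
    ci <- config$drift[i]
    if (ci == 0) {
      pf[i, ] <- p
    } else {
      pf[i, ] <- rbeta(S, p * (1 - ci) / ci, (1 - p) * (1 - ci) / ci)
    }
  }
  # minor = allele with ancestral frequency < 0.5; on a tie the
  # lexicographically smaller base becomes the major allele
  a1minor <- p < 0.5 | (p == 0.5 & a1 > a2)
  major <- ifelse(a1minor, a2, a1)
  minor <- ifelse(a1minor, a1, a2)
  ancestral <- ifelse(a1minor, p, 1 - p)
  pfMinor <- pf
  pfMinor[, !a1minor] <- 1 - pf[, !a1minor, drop = FALSE]
  list(positions = positions,
       alleles = data.frame(major = major, minor = minor,
                            stringsAsFactors = FALSE),
       ancestral = ancestral,
       popFreqs = pfMinor)
}

#' Implant a selection sweep into population allele frequencies
#'
#' Displaces the focal population's minor-allele frequency at every site in
#' the sweep interval toward fixation: `p' = p + delta * (1 - p)` when the
#' sweep favors the minor allele, or `p' = p * (1 - delta)` when it favors
#' the major allele. All other sites and populations are unchanged.
#'
#' @param popFreqs Populations x sites matrix of minor-allele frequencies.
#' @param positions Site positions (bp), same length as `ncol(popFreqs)`.
#' @param sweep Sweep description as in [simulationConfig()].
#' @return The modified `popFreqs` matrix.
#' @examples
#' implantSweep(matrix(0.5, 1, 1), 50,
#'              list(pop = 1, start = 1, end = 100, delta = 0.8))
#' @export
implantSweep <- function(popFreqs, positions, sweep) {
  stopifnot(length(positions) == ncol(popFreqs))
  inSweep <- positions >= sweep$start & positions <= sweep$end
  p <- popFreqs[sweep$pop, inSweep]
  towards <- if (is.null(sweep$towards)) "minor" else sweep$towards
  popFreqs[sweep$pop, inSweep] <-
    if (towards == "minor") p + sweep$delta * (1 - p)
    else p * (1 - sweep$delta)
  popFreqs
}

#' Draw genotypes, honoring admixture when configured
#'
#' Without admixture each individual belongs to one population and its
#' minor-allele count is `Binomial(2, p_pop,site)`. With a true admixture
#' matrix Q, the individual allele frequency is `h_is = sum_k Q_ik F_ks`
#' and the genotype is `Binomial(2, h_is)`.
#'
#' @param popFreqs Populations x sites minor-allele frequency matrix.
#' @param nInd Per-population sample sizes.
#' @param Q Optional individuals x populations admixture matrix (rows
#'   summing to 1 within 1e-9).
#' @param seed Integer seed.
#' @return Integer matrix individuals x sites of minor-allele counts
#'   in \{0, 1, 2\}, individuals ordered by population.
#' @export
simulateGenotypes <- function(popFreqs, nInd, Q = NULL, seed = 1L) {
  S <- ncol(popFreqs)
  N <- sum(nInd)
  set.seed(seed)
  if (is.null(Q)) {
    pop <- rep(seq_along(nInd), nInd)
    h <- popFreqs[pop, , drop = FALSE]
  } else {
    Q <- as.matrix(Q)
    if (any(abs(rowSums(Q) - 1) > 1e-9))
      stop("rows of Q must sum to 1 (within 1e-9)")
    if (nrow(Q) != N) stop("Q must have one row per individual")
    h <- Q %*% popFreqs
  }
  g <- matrix(rbinom(N * S, 2L, as.vector(h)), N, S)
  storage.mode(g) <- "integer"
  g
}

#' Simulate low-coverage reads as a pileup table
#'
#' Per individual per site the read depth is Poisson(meanDepth). Each read
#' samples one of the individual's two allele copies (minor with probability
#' g/2); the observed base equals the sampled allele with probability
#' 1 - errorRate, otherwise one of the other three bases uniformly. Strand
#' is Bernoulli(0.5) and every base carries the fixed Phred quality
#' `round(-10 log10 errorRate)` so that the likelihood model's per-base
#' error probability matches the generator exactly.
#'
#' @param genotypes Individuals x sites integer matrix of minor-allele
#'   counts.
#' @param sites Data frame with `chrom`, `pos`, `major`, `minor`.
#' @param meanDepth Poisson mean depth.
#' @param errorRate Per-base error probability.
#' @param seed Integer seed.
#' @return A pileup `data.frame` with columns `chrom`, `pos`, `indiv`
#'   (1-based individual index), `base`, `qual` (Phred), `strand`
#'   (`"+"`/`"-"`), sorted by position then individual.
#' @export
simulateReads <- function(genotypes, sites, meanDepth, errorRate,
                          seed = 1L) {
  stopifnot(nrow(sites) == ncol(genotypes))
  set.seed(seed)
  N <- nrow(genotypes); S <- ncol(genotypes)
  depth <- matrix(rpois(N * S, meanDepth), N, S)
  tot <- sum(depth)
  if (tot == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      indiv = integer(), base = character(),
                      qual = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  siteIdx <- rep(rep(seq_len(S), each = N), as.vector(depth))
  indIdx <- rep(rep(seq_len(N), S), as.vector(depth))
  g <- genotypes[cbind(indIdx, siteIdx)]
  isMinor <- runif(tot) < g / 2
  trueBase <- ifelse(isMinor, sites$minor[siteIdx], sites$major[siteIdx])
  err <- runif(tot) < errorRate
  obs <- trueBase
  if (any(err)) {
    bases <- c("A", "C", "G", "T")
    # uniform over the three other bases
    shift <- sample.int(3L, sum(err), replace = TRUE)
    cur <- match(trueBase[err], bases)
    obs[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  # error-free reads get the conventional maximum Phred score
  qual <- if (errorRate > 0)
    min(93L, as.integer(round(-10 * log10(errorRate)))) else 93L
  out <- data.frame(chrom = sites$chrom[siteIdx],
                    pos = sites$pos[siteIdx],
                    indiv = indIdx,
                    base = obs,
                    qual = qual,
                    strand = ifelse(runif(tot) < 0.5, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(out$pos, out$indiv), , drop = FALSE]
}

#' Simulate a complete low-coverage dataset with its truth
#'
#' Runs the full generator: ancestral and population frequencies under the
#' Balding-Nichols model, optional sweep implantation, genotypes (optionally
#' admixed), and Poisson-depth reads with sequencing errors. The returned
#' truth channel carries everything parameter-recovery tests need.
#'
#' @param config A [simulationConfig()].
#' @return A list with `sites` (data.frame `chrom`, `pos`, `major`,
#'   `minor`), `pileup` (see [simulateReads()]), and `truth` (list:
#'   `ancestral`, `popFreqs`, `genotypes`, `Q`, `pop` individual
#'   population index, `sweep` the sweep description or `NULL`).
#' @examples
#' d <- simulateDataset(simulationConfig(nSites = 50, nInd = c(4, 4, 4),
#'                                       chromLength = 1e5, seed = 7))
#' head(d$pileup)
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  fr <- simulateFrequencies(config)
  pf <- fr$popFreqs
  if (!is.null(config$sweep))
    pf <- implantSweep(pf, fr$positions, config$sweep)
  Q <- config$admixture
  genotypes <- simulateGenotypes(pf, config$nInd, Q = Q,
                                 seed = childSeed(config$seed, 2L))
  sites <- data.frame(chrom = config$chrom, pos = fr$positions,
                      major = fr$alleles$major, minor = fr$alleles$minor,
                      stringsAsFactors = FALSE)
  pileup <- simulateReads(genotypes, sites, config$meanDepth,
                          config$errorRate,
                          seed = childSeed(config$seed, 3L))
  if (is.null(Q)) {
    Q <- matrix(0, sum(config$nInd), length(config$nInd))
    Q[cbind(seq_len(nrow(Q)), rep(seq_along(config$nInd), config$nInd))] <- 1
  }
  list(sites = sites, pileup = pileup,
       truth = list(ancestral = fr$ancestral, popFreqs = pf,
                    genotypes = genotypes, Q = Q,
                    pop = rep(seq_along(config$nInd), config$nInd),
                    sweep = config$sweep))
}
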