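#' Compute genotype likelihoods from a pileup
#'
#' Implements the standard independent-error allele-sampling model for
#' diploid genotype likelihoods at a biallelic site. Reads with base quality
#' below `minBaseQuality` or carrying a base other than the site's major or
#' minor allele are discarded. For the surviving reads of one individual,
#' the unnormalized likelihood of carrying g copies of the minor allele is
#'
#' \deqn{L(g) = \prod_{reads} \left[(1 - g/2)\, e(b \mid major) +
#'   (g/2)\, e(b \mid minor)\right]}
#'
#' with \eqn{e(b \mid a) = 1 - \epsilon} if \eqn{b = a} and
#' \eqn{\epsilon / 3} otherwise, where \eqn{\epsilon} is the per-base error
#' probability implied by the read's Phred quality
#' (\eqn{\epsilon = 10^{-q/10}}). Each triple is rescaled so its maximum is
#' 1; an individual with no surviving reads gets the uninformative triple
#' (1, 1, 1).
#'
#' If the pileup carries a `mapq` column, reads with `mapq < minMapQuality`
#' are discarded first.
#'
#' @param pileup Pileup `data.frame` with columns `chrom`, `pos`, `indiv`,
#'   `base`, `qual`, and optionally `strand` and `mapq`
#'   (see [simulateReads()]).
#' @param sites Data frame with columns `chrom`, `pos`, `major`, `minor`
#'   declaring the biallelic sites and allele labels, sorted by position
#'   within chromosome.
#' @param nInd Number of individuals (defaults to `max(pileup$indiv)`).
#' @param samples Optional character vector of sample names.
#' @param minBaseQuality Minimum Phred base quality (default 20).
#' @param minMapQuality Minimum mapping quality, applied only when the
#'   pileup has a `mapq` column (default 30).
#' @return A [GenotypeLikelihoods-class] object.
#' @examples
#' sites <- data.frame(chrom = "1", pos = 100, major = "A", minor = "C")
#' pu <- data.frame(chrom = "1", pos = 100, indiv = 1, base = "A",
#'                  qual = 20, strand = "+")
#' glArray(computeGL(pu, sites, nInd = 1))
#' @export
computeGL <- function(pileup, sites, nInd = NULL, samples = NULL,
                      minBaseQuality = 20, minMapQuality = 30) {
  if (is.null(nInd))
    nInd <- if (nrow(pileup)) max(pileup$indiv) else 1L
  nInd <- as.integer(nInd)
  if (nrow(pileup) && max(pileup$indiv) > nInd)
    stop("pileup references individual index beyond nInd")
  if (is.null(samples)) samples <- sprintf("ind%02d", seq_len(nInd))
  S <- nrow(sites)
  key <- paste(sites$chrom, sites$pos, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated sites")
  ll <- array(0, dim = c(S, nInd, 3L))
  if (nrow(pileup)) {
    pu <- pileup
    if (!is.null(pu$mapq)) pu <- pu[pu$mapq >= minMapQuality, , drop = FALSE]
    pu <- pu[pu$qual >= minBaseQuality, , drop = FALSE]
    sIdx <- match(paste(pu$chrom, pu$pos, sep = "\r"), key)
    keep <- !is.na(sIdx)
    pu <- pu[keep, , drop = FALSE]; sIdx <- sIdx[keep]
    isMajor <- pu$base == sites$major[sIdx]
    isMinor <- pu$base == sites$minor[sIdx]
    keep <- isMajor | isMinor
    pu <- pu[keep, , drop = FALSE]; sIdx <- sIdx[keep]
    isMajor <- isMajor[keep]
    if (nrow(pu)) {
      eps <- 10^(-pu$qual / 10)
      eMaj <- ifelse(isMajor, 1 - eps, eps / 3)
      eMin <- ifelse(isMajor, eps / 3, 1 - eps)
      cell <- (pu$indiv - 1L) * S + sIdx  # column-major index into S x N
      for (g in 0:2) {
        perRead <- log((1 - g / 2) * eMaj + (g / 2) * eMin)
        acc <- rowsum(perRead, cell)
        idx <- as.integer(rownames(acc))
        ll[idx + (g * S * nInd)] <- acc[, 1]
      }
    }
  }
  mx <- pmax(ll[, , 1], ll[, , 2], ll[, , 3])
  gl <- exp(ll - as.vector(mx))
  dim(gl) <- c(S, nInd, 3L)
  new("GenotypeLikelihoods", sites = .sitesGRanges(sites), gl = gl,
      samples = samples)
}

#' Estimate per-site minor allele frequencies by EM
#'
#' Maximum-likelihood minor-allele frequency under Hardy-Weinberg
#' proportions, computed per site from genotype likelihoods by EM. With
#' genotype weights \eqn{w_{ig} \propto GL_{ig}\,\mathrm{Binom}(g; 2, f)}
#' the update is \eqn{f' = \frac{1}{2N} \sum_i \sum_g g\, w_{ig}}. EM starts
#' at f = 0.1 and stops when `|f' - f| < tol` or after `maxIter`
#' iterations. Sites at which every individual is uninformative (all
#' triples (1, 1, 1)) get `NA`.
#'
#' @param gl A [GenotypeLikelihoods-class] object.
#' @param tol Convergence tolerance on the frequency (default 1e-6).
#' @param maxIter Maximum EM iterations (default 100).
#' @return A `data.frame` with one row per site: `chrom`, `pos`, `maf`,
#'   `nIter`, `loglik` (final per-site log-likelihood).
#' @export
estimateMafEM <- function(gl, tol = 1e-6, maxIter = 100L) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  G0 <- gl@gl[, , 1, drop = FALSE]; dim(G0) <- dim(gl@gl)[1:2]
  G1 <- gl@gl[, , 2, drop = FALSE]; dim(G1) <- dim(gl@gl)[1:2]
  G2 <- gl@gl[, , 3, drop = FALSE]; dim(G2) <- dim(gl@gl)[1:2]
  S <- nrow(G0); N <- ncol(G0)
  informative <- rowSums(G0 == 1 & G1 == 1 & G2 == 1) < N
  f <- rep(0.1, S)
  nIter <- rep(0L, S)
  active <- informative
  it <- 0L
  while (any(active) && it < maxIter) {
    it <- it + 1L
    fa <- f
    w0 <- G0 * (1 - fa)^2
    w1 <- G1 * 2 * fa * (1 - fa)
    w2 <- G2 * fa^2
    denom <- w0 + w1 + w2
    fNew <- rowSums((w1 + 2 * w2) / denom) / (2 * N)
    moved <- abs(fNew - fa) >= tol & active
    f[active] <- fNew[active]
    nIter[active] <- it
    active <- moved
  }
  w0 <- G0 * (1 - f)^2; w1 <- G1 * 2 * f * (1 - f); w2 <- G2 * f^2
  loglik <- rowSums(log(w0 + w1 + w2))
  f[!informative] <- NA_real_
  loglik[!informative] <- NA_real_
  sf <- .sitesFrame(gl@sites)
  data.frame(chrom = sf$chrom, pos = sf$pos, maf = f, nIter = nIter,
             loglik = loglik, stringsAsFactors = FALSE)
}

#' Filter sites by estimated minor allele frequency
#'
#' Keeps sites whose estimated MAF is strictly greater than the threshold.
#' Sites with a missing MAF (fully uninformative) are always removed.
#'
#' @param gl A [GenotypeLikelihoods-class] object.
#' @param maf Numeric vector of per-site MAF estimates, or the `data.frame`
#'   returned by [estimateMafEM()]. If `NULL`, MAFs are estimated first.
#' @param threshold MAF threshold; the comparison is strict (`maf >
#'   threshold`). Default 0.05.
#' @return The filtered [GenotypeLikelihoods-class] object.
#' @export
filterMaf <- function(gl, maf = NULL, threshold = 0.05) {
  if (is.null(maf)) maf <- estimateMafEM(gl)
  if (is.data.frame(maf)) maf <- maf$maf
  stopifnot(length(maf) == nSites(gl))
  gl[!is.na(maf) & maf > threshold, ]
}
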