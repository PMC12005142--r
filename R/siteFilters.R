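#' Minimum-individuals coverage filter
#'
#' A site passes when at least `k` individuals are covered by at least `u`
#' reads (both comparisons inclusive). Defaults follow common low-coverage
#' practice: at least 10 individuals with at least 1 read.
#'
#' @param depths Integer vector of per-individual read depths at one site.
#' @param k Minimum number of adequately covered individuals (default 10).
#' @param u Minimum per-individual depth (default 1).
#' @return Logical: does the site pass?
#' @examples
#' coverageFilter(c(2, 0, 1, 1), k = 3, u = 1)
#' @export
coverageFilter <- function(depths, k = 10L, u = 1L) {
  sum(depths >= u) >= k
}

#' Exact test for excess heterozygosity
#'
#' One-sided exact Hardy-Weinberg test against an excess of heterozygotes,
#' using the Levene-Haldane conditional distribution of the heterozygote
#' count given the sample size and minor-allele count. The p-value is the
#' probability, under Hardy-Weinberg equilibrium, of a heterozygote count
#' greater than or equal to the observed one. Small p-values indicate
#' heterozygote excess (the signature of paralogous mis-mapping); sites are
#' conventionally removed below 1e-6.
#'
#' @param nAA,nAa,naa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return The one-sided p-value.
#' @examples
#' excessHetTest(50, 0, 0)  # 1: no heterozygotes at all
#' excessHetTest(0, 20, 0)  # all heterozygous: extreme excess
#' @export
excessHetTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype required")
  n1 <- min(2 * naa + nAa, 2 * nAA + nAa)  # rarer-allele count
  if (n1 == 0) return(1)
  hVals <- seq.int(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logPmf <- hVals * log(2) + lfactorial(n) -
    lfactorial((n1 - hVals) / 2) - lfactorial(hVals) -
    lfactorial((2 * n - n1 - hVals) / 2)
  pmf <- exp(logPmf - max(logPmf))
  pmf <- pmf / sum(pmf)
  sum(pmf[hVals >= nAa])
}

#' Exact test for strand bias
#'
#' Two-sided Fisher exact test on the 2x2 table of allele (major/minor) by
#' strand (forward/reverse) read counts, with the conventional
#' minimum-likelihood two-sided rule. Sites with alleles concentrated on
#' opposite strands are sequencing artifacts; sites are conventionally
#' removed below 1e-4.
#'
#' @param tab 2x2 matrix of non-negative counts: rows alleles
#'   (major, minor), columns strands (forward, reverse).
#' @return The two-sided p-value.
#' @examples
#' strandBiasTest(matrix(c(5, 5, 5, 5), 2))
#' @export
strandBiasTest <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Apply all site filters to a pileup and its genotype likelihoods
#'
#' Runs the three snpCleaner-style predicates per site: minimum-individuals
#' coverage, exact excess-heterozygosity and strand bias. Genotype counts
#' for the heterozygosity test come from hard calls: an individual is
#' called when its posterior genotype probability, under a Hardy-Weinberg
#' prior at the site's EM-estimated minor-allele frequency, reaches
#' `callThreshold`; uncalled individuals are excluded. Strand tables count
#' quality-passing major/minor reads by strand. The filters are
#' independent predicates; a site passes overall when every enabled filter
#' passes.
#'
#' @param pileup Pileup `data.frame` (see [simulateReads()]).
#' @param gl A [GenotypeLikelihoods-class] object for the same sites.
#' @param maf Optional per-site MAF estimates ([estimateMafEM()] output or
#'   numeric vector); estimated when `NULL`.
#' @param k,u Coverage filter thresholds (see [coverageFilter()]); set
#'   `k = 0` to disable.
#' @param hetP Heterozygosity-excess p-value threshold (default 1e-6;
#'   `NA` disables).
#' @param strandP Strand-bias p-value threshold (default 1e-4; `NA`
#'   disables).
#' @param minBaseQuality Minimum base quality for reads entering the
#'   strand table (default 20).
#' @param callThreshold Posterior needed for a hard genotype call
#'   (default 0.95).
#' @return A `data.frame` with one row per site: `chrom`, `pos`,
#'   `nCovered`, `hetP`, `strandP`, per-filter pass flags and `pass`
#'   (their conjunction).
#' @export
applySiteFilters <- function(pileup, gl, maf = NULL, k = 10L, u = 1L,
                             hetP = 1e-6, strandP = 1e-4,
                             minBaseQuality = 20, callThreshold = 0.95) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  sf <- .sitesFrame(gl@sites)
  S <- nrow(sf); N <- nSamples(gl)
  key <- paste(sf$chrom, sf$pos, sep = "\r")
  sIdx <- match(paste(pileup$chrom, pileup$pos, sep = "\r"), key)
  ok <- !is.na(sIdx)
  pu <- pileup[ok, , drop = FALSE]; sIdx <- sIdx[ok]

  # coverage: depth per (site, individual) from all reads
  depthTab <- table(factor(sIdx, levels = seq_len(S)),
                    factor(pu$indiv, levels = seq_len(N)))
  nCovered <- rowSums(depthTab >= u)

  # heterozygosity: hard calls under the site's MAF-HWE prior
  if (is.null(maf)) maf <- estimateMafEM(gl)
  if (is.data.frame(maf)) maf <- maf$maf
  f <- ifelse(is.na(maf), 0, maf)
  w0 <- gl@gl[, , 1] * (1 - f)^2
  w1 <- gl@gl[, , 2] * 2 * f * (1 - f)
  w2 <- gl@gl[, , 3] * f^2
  tot <- w0 + w1 + w2
  p0 <- w0 / tot; p1 <- w1 / tot; p2 <- w2 / tot
  called0 <- p0 >= callThreshold
  called1 <- p1 >= callThreshold
  called2 <- p2 >= callThreshold
  cnt <- cbind(AA = rowSums(called0), Aa = rowSums(called1),
               aa = rowSums(called2))
  hetPval <- vapply(seq_len(S), function(s)
    if (sum(cnt[s, ]) == 0) 1 else
      excessHetTest(cnt[s, 1], cnt[s, 2], cnt[s, 3]), 0)

  # strand bias: quality-passing major/minor reads by strand
  strandPval <- rep(1, S)
  if (!is.null(pu$strand) && nrow(pu)) {
    puq <- pu[pu$qual >= minBaseQuality, , drop = FALSE]
    sI <- sIdx[pu$qual >= minBaseQuality]
    isMajor <- puq$base == sf$major[sI]
    isMinor <- puq$base == sf$minor[sI]
    keep <- isMajor | isMinor
    puq <- puq[keep, , drop = FALSE]; sI <- sI[keep]
    isMajor <- isMajor[keep]
    if (nrow(puq)) {
      fwd <- puq$strand == "+"
      counts <- rowsum(cbind(isMajor & fwd, isMajor & !fwd,
                             !isMajor & fwd, !isMajor & !fwd) + 0, sI)
      rows <- as.integer(rownames(counts))
      strandPval[rows] <- vapply(seq_along(rows), function(r)
        strandBiasTest(matrix(counts[r, ], 2, byrow = TRUE)), 0)
    }
  }

  passCov <- if (k > 0) nCovered >= k else rep(TRUE, S)
  passHet <- if (!is.na(hetP)) hetPval >= hetP else rep(TRUE, S)
  passStrand <- if (!is.na(strandP)) strandPval >= strandP
                else rep(TRUE, S)
  data.frame(chrom = sf$chrom, pos = sf$pos, nCovered = nCovered,
             hetP = hetPval, strandP = strandPval,
             passCoverage = passCov, passHet = passHet,
             passStrand = passStrand,
             pass = passCov & passHet & passStrand,
             stringsAsFactors = FALSE)
}
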