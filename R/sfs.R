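#' Sample allele frequency likelihoods from genotype likelihoods
#'
#' For each site, computes the likelihood L(j) that j of the population's
#' 2N sampled chromosomes carry the minor allele, by a dynamic program over
#' individuals:
#' \deqn{q_0 = \delta_{j=0}; \quad
#'   q_i(j) = \sum_{g \in \{0,1,2\}} q_{i-1}(j-g)\, GL_i(g) \binom{2}{g};
#'   \quad L(j) = q_N(j) / \binom{2N}{j}.}
#' Rows are max-rescaled after the division; relative likelihoods within a
#' site are exact. Rows are renormalized after every individual to prevent
#' underflow at large N.
#'
#' @param gl A [GenotypeLikelihoods-class] object for one population.
#' @return A [SafLikelihoods-class] object with a
#'   `sites x (2N + 1)` matrix.
#' @examples
#' sites <- data.frame(chrom = "1", pos = 1, major = "A", minor = "C")
#' g <- new("GenotypeLikelihoods", sites = pbscan:::.sitesGRanges(sites),
#'          gl = array(c(1, 0, 0), c(1, 1, 3)), samples = "i1")
#' safMatrix(safLikelihoods(g))
#' @export
safLikelihoods <- function(gl) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  S <- nSites(gl); N <- nSamples(gl)
  M <- 2L * N
  q <- matrix(0, S, M + 1L)
  q[, 1] <- 1
  for (i in seq_len(N)) {
    g0 <- gl@gl[, i, 1]; g1 <- gl@gl[, i, 2]; g2 <- gl@gl[, i, 3]
    upTo <- 2L * i
    cols <- seq_len(upTo + 1L)
    qNew <- q[, cols, drop = FALSE] * g0
    qNew[, -1] <- qNew[, -1] + q[, cols[-(upTo + 1L)], drop = FALSE] *
      (2 * g1)
    qNew[, -(1:2)] <- qNew[, -(1:2)] +
      q[, cols[seq_len(upTo - 1L)], drop = FALSE] * g2
    q[, cols] <- qNew / apply(qNew, 1, max)
  }
  L <- q / matrix(choose(M, 0:M), S, M + 1L, byrow = TRUE)
  L <- L / apply(L, 1, max)
  new("SafLikelihoods", sites = gl@sites, saf = L, nInd = as.integer(N))
}

#' Estimate a 1D or 2D site frequency spectrum by EM
#'
#' Maximum-likelihood estimate of the distribution of sample allele counts
#' across sites, from SAF likelihoods of one population (1D) or two
#' populations (2D). Starting from a uniform spectrum, each iteration
#' computes the per-site posterior over count bins,
#' \eqn{P_s(j, k) \propto \eta(j, k)\, L_{1s}(j)\, L_{2s}(k)},
#' and sets the new spectrum to the mean posterior over sites. Iteration
#' stops when `max |delta eta| < tol` or after `maxIter` iterations; the
#' log-likelihood (up to the constant absorbed by SAF rescaling) never
#' decreases.
#'
#' Sites whose SAF products are identically zero carry no information under
#' any spectrum and are excluded with a warning.
#'
#' @param saf1 A [SafLikelihoods-class] object.
#' @param saf2 Optional second population's [SafLikelihoods-class] (same
#'   sites); when supplied, a 2D spectrum is estimated.
#' @param tol Convergence tolerance on `max |delta eta|` (default 1e-8).
#' @param maxIter Maximum EM iterations (default 500).
#' @return A [JointSFS-class] object.
#' @export
estimateSFS <- function(saf1, saf2 = NULL, tol = 1e-8, maxIter = 500L) {
  stopifnot(is(saf1, "SafLikelihoods"))
  L1 <- saf1@saf
  S <- nrow(L1)
  if (S < 1) stop("at least one site required")
  if (is.null(saf2)) {
    K1 <- ncol(L1)
    drop <- rowSums(L1) == 0
    if (any(drop)) {
      warning(sum(drop), " site(s) with all-zero SAF excluded")
      L1 <- L1[!drop, , drop = FALSE]
    }
    S <- nrow(L1)
    eta <- rep(1 / K1, K1)
    ll <- numeric(0)
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      denom <- as.vector(L1 %*% eta)
      ll <- c(ll, sum(log(denom)))
      etaNew <- eta * colMeans(L1 / denom)
      etaNew <- etaNew / sum(etaNew)
      delta <- max(abs(etaNew - eta))
      eta <- etaNew
      if (delta < tol) break
    }
    return(new("JointSFS", eta = matrix(eta, ncol = 1L), loglik = ll,
               nIter = it, nSites = as.integer(S)))
  }
  stopifnot(is(saf2, "SafLikelihoods"), nrow(saf2@saf) == S)
  L2 <- saf2@saf
  drop <- rowSums(L1) == 0 | rowSums(L2) == 0
  if (any(drop)) {
    warning(sum(drop), " site(s) with all-zero SAF excluded")
    L1 <- L1[!drop, , drop = FALSE]
    L2 <- L2[!drop, , drop = FALSE]
  }
  S <- nrow(L1)
  K1 <- ncol(L1); K2 <- ncol(L2)
  eta <- matrix(1 / (K1 * K2), K1, K2)
  ll <- numeric(0)
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # denom_s = sum_jk eta_jk L1_sj L2_sk computed without per-site loops
    A <- L1 %*% eta             # S x K2
    denom <- rowSums(A * L2)
    ll <- c(ll, sum(log(denom)))
    # eta'_jk = eta_jk * (1/S) sum_s L1_sj L2_sk / denom_s
    etaNew <- eta * (crossprod(L1 / denom, L2) / S)
    etaNew <- etaNew / sum(etaNew)
    delta <- max(abs(etaNew - eta))
    eta <- etaNew
    if (delta < tol) break
  }
  new("JointSFS", eta = eta, loglik = ll, nIter = it,
      nSites = as.integer(S))
}
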