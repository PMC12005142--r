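#' Admixture proportions from genotype likelihoods by EM
#'
#' Fits the K-component admixture model directly on genotype likelihoods.
#' With per-individual mixing proportions Q (rows on the simplex) and
#' component minor-allele frequencies F, the individual allele frequency is
#' \eqn{h_{is} = \sum_k Q_{ik} F_{ks}} and the likelihood is
#' \deqn{\prod_i \prod_s \sum_{g} GL_{isg}\, \mathrm{Binom}(g; 2, h_{is}).}
#' Parameters are updated with the standard multiplicative EM for this
#' model (expected allele-copy assignments to components), which never
#' decreases the log-likelihood. Frequencies are clamped to
#' `[1e-6, 1 - 1e-6]` to avoid absorbing states and Q rows are
#' renormalized each step. The fit is repeated from `nRestarts` random
#' initializations and the restart with the best final log-likelihood is
#' returned.
#'
#' @param gl A [GenotypeLikelihoods-class] object (MAF-filtered sites).
#' @param K Number of ancestry components.
#' @param maxIter Maximum EM iterations per restart (default 1000).
#' @param tol Convergence tolerance on the log-likelihood increase
#'   (default 1e-6).
#' @param nRestarts Number of random restarts (default 3).
#' @param seed Integer seed controlling the restarts.
#' @return An [AncestryModel-class] object carrying the best restart's Q,
#'   F, full log-likelihood trace, iteration count and restart index.
#' @export
admixtureEM <- function(gl, K, maxIter = 1000L, tol = 1e-6,
                        nRestarts = 3L, seed = 1L) {
  stopifnot(is(gl, "GenotypeLikelihoods"), K >= 1)
  N <- nSamples(gl); S <- nSites(gl)
  if (K > N) stop("K must not exceed the number of individuals")
  G0 <- t(gl@gl[, , 1]); G1 <- t(gl@gl[, , 2]); G2 <- t(gl@gl[, , 3])
  dim(G0) <- dim(G1) <- dim(G2) <- c(N, S)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(childSeed(seed, 100L + r))
    Q <- matrix(rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    F <- matrix(runif(K * S, 0.05, 0.95), K, S)
    ll <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      H <- Q %*% F
      H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
      w0 <- G0 * (1 - H)^2
      w1 <- G1 * 2 * H * (1 - H)
      w2 <- G2 * H^2
      denom <- w0 + w1 + w2
      ll <- c(ll, sum(log(denom)))
      e <- (w1 + 2 * w2) / denom      # expected minor-allele dosage
      minorTot <- e / H               # N x S
      majorTot <- (2 - e) / (1 - H)
      Fnew <- F; Qnew <- Q
      colMinor <- matrix(0, K, S)
      colMajor <- matrix(0, K, S)
      for (k in seq_len(K)) {
        mk <- (Q[, k] * t(F[k, ] * t(minorTot)))   # e * Q_ik F_ks / h
        jk <- (Q[, k] * t((1 - F[k, ]) * t(majorTot)))
        colMinor[k, ] <- colSums(mk)
        colMajor[k, ] <- colSums(jk)
        Qnew[, k] <- rowSums(mk) + rowSums(jk)
      }
      Fnew <- colMinor / (colMinor + colMajor)
      Fnew <- pmin(pmax(Fnew, 1e-6), 1 - 1e-6)
      Qnew <- Qnew / rowSums(Qnew)
      Q <- Qnew; F <- Fnew
      converged <- it > 1 && (ll[it] - ll[it - 1]) < tol
      if (converged || it >= maxIter) break
    }
    if (!all(is.finite(ll))) next  # degenerate restart excluded
    if (is.null(best) || tail(ll, 1) > tail(best$ll, 1))
      best <- list(Q = Q, F = F, ll = ll, it = it, r = r)
  }
  if (is.null(best)) stop("no restart produced a finite log-likelihood")
  new("AncestryModel", Q = best$Q, F = best$F, loglik = best$ll,
      nIter = as.integer(best$it), restart = as.integer(best$r))
}

#' Resolve component label switching against a reference
#'
#' Admixture components are identifiable only up to permutation. This
#' re-orders the model's components by the permutation of columns that
#' maximizes `sum(Q[, perm] * referenceQ)` (exhaustive over the K!
#' permutations; deterministic).
#'
#' @param model An [AncestryModel-class].
#' @param referenceQ Reference Q matrix, same dimensions as the model's.
#' @return The model with permuted components.
#' @export
alignLabels <- function(model, referenceQ) {
  K <- ncol(model@Q)
  stopifnot(ncol(referenceQ) == K, nrow(referenceQ) == nrow(model@Q))
  perms <- .permutations(K)
  score <- vapply(perms, function(p)
    sum(model@Q[, p, drop = FALSE] * referenceQ), 0)
  p <- perms[[which.max(score)]]
  new("AncestryModel", Q = model@Q[, p, drop = FALSE],
      F = model@F[p, , drop = FALSE], loglik = model@loglik,
      nIter = model@nIter, restart = model@restart)
}

.permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- .permutations(K - 1L)
  out <- list()
  for (p in sub)
    for (pos in 0:(K - 1L))
      out[[length(out) + 1L]] <- append(p, K, after = pos)
  out
}

#' Mean ancestry per population, as percentages
#'
#' Averages the (label-aligned) admixture proportions within declared
#' populations and reports them as percentages; each row sums to 100
#' within rounding.
#'
#' @param model An aligned [AncestryModel-class].
#' @param populations Character or factor of population labels, one per
#'   individual.
#' @return A matrix populations x components of mean percentages.
#' @examples
#' m <- new("AncestryModel", Q = matrix(c(0.941, 0.038, 0.021), 1),
#'          F = matrix(0.5, 3, 1), loglik = 0, nIter = 1L, restart = 1L)
#' meanAncestryReport(m, "pop1")
#' @export
meanAncestryReport <- function(model, populations) {
  if (length(populations) != nrow(model@Q))
    stop("one population label per individual required")
  pops <- as.factor(populations)
  out <- 100 * rowsum(model@Q, pops) / as.vector(table(pops))
  colnames(out) <- paste0("C", seq_len(ncol(out)))
  out
}

#' Genotype covariance from genotype likelihoods, for PCA
#'
#' Estimates the individuals x individuals covariance of standardized
#' genotype dosages directly from genotype likelihoods, iteratively
#' refining per-individual allele frequencies from the top principal
#' components. Iteration 0 uses the site MAF as every individual's
#' frequency; each cycle (i) computes posterior expected dosages
#' \eqn{e_{is} = \sum_g g\, P(g \mid GL_{is}, h_{is})} under a
#' Hardy-Weinberg prior at `h`, (ii) standardizes by the global MAF,
#' \eqn{x_{is} = (e_{is} - 2 f_s) / \sqrt{2 f_s (1 - f_s)}}, (iii) forms
#' `C = x xT / S`, and (iv) rebuilds individual frequencies from the
#' projection of the dosage matrix onto the top `K - 1` eigenvectors.
#' After `nIterIndf` refinement cycles the final covariance is
#' eigendecomposed.
#'
#' @param gl A [GenotypeLikelihoods-class] with MAF-filtered sites (an
#'   error is raised if a monomorphic-estimated site reaches this point).
#' @param maf Per-site MAF estimates (vector or [estimateMafEM()] output);
#'   estimated when `NULL`.
#' @param K Number of ancestral groups assumed; `K - 1` principal
#'   components drive the frequency refinement (default 3).
#' @param nIterIndf Number of individual-allele-frequency refinement
#'   cycles (default 2; 0 reproduces covariance at the global MAF).
#' @return A [CovarianceResult-class] object.
#' @export
pcaCovariance <- function(gl, maf = NULL, K = 3L, nIterIndf = 2L) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  if (is.null(maf)) maf <- estimateMafEM(gl)
  if (is.data.frame(maf)) maf <- maf$maf
  S <- nSites(gl); N <- nSamples(gl)
  stopifnot(length(maf) == S)
  if (anyNA(maf) || any(maf <= 0 | maf >= 1))
    stop("monomorphic or missing-MAF site reached PCA; filter sites first")
  G0 <- t(gl@gl[, , 1]); G1 <- t(gl@gl[, , 2]); G2 <- t(gl@gl[, , 3])
  dim(G0) <- dim(G1) <- dim(G2) <- c(N, S)
  f <- matrix(maf, N, S, byrow = TRUE)
  sdv <- sqrt(2 * maf * (1 - maf))
  H <- f
  C <- NULL
  for (cycle in 0:nIterIndf) {
    w0 <- G0 * (1 - H)^2
    w1 <- G1 * 2 * H * (1 - H)
    w2 <- G2 * H^2
    e <- (w1 + 2 * w2) / (w0 + w1 + w2)
    X <- t((t(e) - 2 * maf) / sdv)
    C <- tcrossprod(X) / S
    C <- (C + t(C)) / 2
    if (cycle < nIterIndf) {
      nPC <- max(1L, min(K - 1L, N - 1L))
      V <- eigen(C, symmetric = TRUE)$vectors[, seq_len(nPC), drop = FALSE]
      Xhat <- V %*% crossprod(V, X)
      H <- t((t(Xhat) * sdv + 2 * maf) / 2)
      H <- pmin(pmax(H, 1e-4), 1 - 1e-4)
    }
  }
  ev <- eigen(C, symmetric = TRUE)
  o <- order(ev$values, decreasing = TRUE)
  vals <- ev$values[o]
  new("CovarianceResult", cov = C, values = vals,
      vectors = ev$vectors[, o, drop = FALSE],
      varFrac = vals / sum(vals))
}
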