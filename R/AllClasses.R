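#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GenotypeLikelihoods: genotype likelihoods at biallelic sites
#'
#' The central exchange object of the pipeline: per-site, per-individual
#' genotype likelihoods for the three genotypes g in \{0, 1, 2\} copies of
#' the minor allele. Likelihood triples are max-rescaled (Beagle convention):
#' each triple is divided by its maximum, so every stored value lies in
#' \[0, 1\] and the maximum of each triple is exactly 1. An individual with
#' no usable reads at a site carries the uninformative triple (1, 1, 1).
#'
#' @slot sites A [GenomicRanges::GRanges] of width-1 SNP positions with
#'   metadata columns `major` and `minor` (single bases, `major != minor`).
#'   Sites are sorted by (chromosome, position).
#' @slot gl Numeric array `sites x individuals x 3`; `gl[s, i, g + 1]` is the
#'   rescaled likelihood of genotype `g` minor-allele copies.
#' @slot samples Character vector of individual identifiers.
#'
#' @seealso [computeGL()], [estimateMafEM()], [readBeagle()], [safLikelihoods()]
#' @export
setClass("GenotypeLikelihoods",
  representation(
    sites = "GRanges",
    gl = "array",
    samples = "character"
  )
)

setValidity("GenotypeLikelihoods", function(object) {
  msg <- character()
  d <- dim(object@gl)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'gl' must be a sites x individuals x 3 array")
  else {
    if (d[1] != length(object@sites))
      msg <- c(msg, "dim(gl)[1] must equal length(sites)")
    if (d[2] != length(object@samples))
      msg <- c(msg, "dim(gl)[2] must equal length(samples)")
    if (d[1] > 0 && d[2] > 0) {
      if (anyNA(object@gl) || min(object@gl) < 0 || max(object@gl) > 1)
        msg <- c(msg, "all likelihoods must lie in [0, 1]")
      else {
        mx <- apply(object@gl, c(1, 2), max)
        if (any(abs(mx - 1) > 1e-9))
          msg <- c(msg, "every likelihood triple must have maximum 1")
      }
    }
  }
  mc <- S4Vectors::mcols(object@sites)
  if (!all(c("major", "minor") %in% colnames(mc)))
    msg <- c(msg, "'sites' needs metadata columns 'major' and 'minor'")
  else if (length(object@sites) > 0 && any(mc$major == mc$minor))
    msg <- c(msg, "major and minor alleles must differ at every site")
  if (length(msg)) msg else TRUE
})

#' SafLikelihoods: sample allele frequency likelihoods for one population
#'
#' Per-site likelihood vectors L(j), j = 0..2N, of observing j minor-allele
#' copies among the 2N sampled chromosomes of one population, computed from
#' genotype likelihoods by a dynamic program over individuals. Rows are
#' max-rescaled; relative likelihoods within a site are exact.
#'
#' @slot sites A [GenomicRanges::GRanges] of SNP positions (as in
#'   [GenotypeLikelihoods-class]).
#' @slot saf Numeric matrix `sites x (2N + 1)`; row maxima are 1.
#' @slot nInd Integer, the number of diploid individuals N.
#'
#' @seealso [safLikelihoods()], [estimateSFS()], [fstComponents()]
#' @export
setClass("SafLikelihoods",
  representation(sites = "GRanges", saf = "matrix", nInd = "integer")
)

setValidity("SafLikelihoods", function(object) {
  msg <- character()
  if (ncol(object@saf) != 2L * object@nInd + 1L)
    msg <- c(msg, "'saf' must have 2 * nInd + 1 columns")
  if (nrow(object@saf) != length(object@sites))
    msg <- c(msg, "nrow(saf) must equal length(sites)")
  if (nrow(object@saf) > 0) {
    if (min(object@saf) < 0 || max(object@saf) > 1)
      msg <- c(msg, "SAF values must lie in [0, 1]")
    else if (any(abs(apply(object@saf, 1, max) - 1) > 1e-9))
      msg <- c(msg, "every SAF row must have maximum 1")
  }
  if (length(msg)) msg else TRUE
})

#' JointSFS: a site frequency spectrum estimated by EM
#'
#' One-dimensional (vector over 0..2N minor-allele counts) or
#' two-dimensional (matrix over pairs of counts in two populations)
#' probability distribution of sample allele counts across sites, estimated
#' by expectation-maximization from SAF likelihoods. Used as the prior for
#' posterior-expected FST components.
#'
#' @slot eta Numeric matrix of spectrum probabilities, `(2N1+1) x (2N2+1)`
#'   for a 2D spectrum or `(2N+1) x 1` for a 1D spectrum; entries are
#'   non-negative and sum to 1.
#' @slot loglik Numeric vector: the log-likelihood trace across EM
#'   iterations (up to the constant absorbed by SAF max-rescaling).
#' @slot nIter Integer, EM iterations performed.
#' @slot nSites Integer, number of sites used.
#'
#' @seealso [estimateSFS()], [fstComponents()]
#' @export
setClass("JointSFS",
  representation(eta = "matrix", loglik = "numeric", nIter = "integer",
                 nSites = "integer")
)

setValidity("JointSFS", function(object) {
  msg <- character()
  if (any(object@eta < 0))
    msg <- c(msg, "spectrum entries must be non-negative")
  if (abs(sum(object@eta) - 1) > 1e-9)
    msg <- c(msg, "spectrum must sum to 1 (within 1e-9)")
  if (length(object@loglik) > 1 &&
      any(diff(object@loglik) < -1e-8 * (1 + abs(object@loglik[1]))))
    msg <- c(msg, "EM log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' AncestryModel: admixture proportions and component frequencies
#'
#' The result of genotype-likelihood admixture inference: per-individual
#' mixture proportions Q over K ancestry components and per-component
#' allele frequencies F, fitted by EM under the likelihood
#' prod_i prod_s sum_g GL_isg * Binom(g; 2, h_is) with h = Q F.
#'
#' @slot Q Numeric matrix `individuals x K`; rows on the simplex.
#' @slot F Numeric matrix `K x sites` of component minor-allele frequencies.
#' @slot loglik Numeric vector: log-likelihood trace of the selected restart.
#' @slot nIter Integer, iterations used by the selected restart.
#' @slot restart Integer, index of the restart with the best final
#'   log-likelihood.
#'
#' @seealso [admixtureEM()], [alignLabels()], [meanAncestryReport()]
#' @export
setClass("AncestryModel",
  representation(Q = "matrix", F = "matrix", loglik = "numeric",
                 nIter = "integer", restart = "integer")
)

setValidity("AncestryModel", function(object) {
  msg <- character()
  if (ncol(object@Q) != nrow(object@F))
    msg <- c(msg, "ncol(Q) must equal nrow(F)")
  if (nrow(object@Q) > 0 && any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "rows of Q must sum to 1 (within 1e-9)")
  if (length(object@F) > 0 && (min(object@F) < 0 || max(object@F) > 1))
    msg <- c(msg, "component frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CovarianceResult: genotype covariance and its eigendecomposition
#'
#' Individual-by-individual covariance of standardized expected genotype
#' dosages computed from genotype likelihoods, with iteratively refined
#' individual allele frequencies, plus its eigendecomposition for principal
#' component analysis.
#'
#' @slot cov Numeric symmetric matrix `individuals x individuals`.
#' @slot values Numeric vector of eigenvalues, sorted decreasing.
#' @slot vectors Numeric matrix of eigenvectors (columns), same order.
#' @slot varFrac Numeric vector: fraction of total variance per component.
#'
#' @seealso [pcaCovariance()]
#' @export
setClass("CovarianceResult",
  representation(cov = "matrix", values = "numeric", vectors = "matrix",
                 varFrac = "numeric")
)

setValidity("CovarianceResult", function(object) {
  msg <- character()
  if (nrow(object@cov) != ncol(object@cov) ||
      max(abs(object@cov - t(object@cov))) > 1e-10)
    msg <- c(msg, "covariance must be symmetric (within 1e-10)")
  if (is.unsorted(rev(object@values)))
    msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeLikelihoods", function(object) {
  cat("GenotypeLikelihoods:", length(object@sites), "sites x",
      length(object@samples), "individuals\n")
  if (length(object@sites)) {
    chr <- as.character(GenomicRanges::seqnames(object@sites))
    cat("  chromosomes:", paste(unique(chr), collapse = ", "), "\n")
    miss <- mean(object@gl[, , 1] == 1 & object@gl[, , 2] == 1 &
                 object@gl[, , 3] == 1)
    cat(sprintf("  uninformative triples: %.1f%%\n", 100 * miss))
  }
})

setMethod("show", "SafLikelihoods", function(object) {
  cat("SafLikelihoods:", nrow(object@saf), "sites,", object@nInd,
      "diploid individuals (alleles 0..", 2 * object@nInd, ")\n", sep = " ")
})

setMethod("show", "JointSFS", function(object) {
  if (ncol(object@eta) == 1L)
    cat("JointSFS (1D):", nrow(object@eta) - 1L, "max count,")
  else
    cat("JointSFS (2D):", nrow(object@eta), "x", ncol(object@eta), "bins,")
  cat(" estimated from", object@nSites, "sites in", object@nIter,
      "EM iterations\n")
  cat("  final log-likelihood:", format(tail(object@loglik, 1)), "\n")
})

setMethod("show", "AncestryModel", function(object) {
  cat("AncestryModel: K =", ncol(object@Q), ",", nrow(object@Q),
      "individuals,", ncol(object@F), "sites\n")
  cat("  restart", object@restart, "selected;", object@nIter,
      "iterations; log-likelihood", format(tail(object@loglik, 1)), "\n")
})

setMethod("show", "CovarianceResult", function(object) {
  cat("CovarianceResult:", nrow(object@cov), "individuals\n")
  k <- min(3L, length(object@varFrac))
  cat("  top variance fractions:",
      paste(sprintf("%.3f", object@varFrac[seq_len(k)]), collapse = ", "),
      "\n")
})

#' @describeIn GenotypeLikelihoods-class Number of sites.
#' @param x,object A `GenotypeLikelihoods` object.
#' @export
nSites <- function(x) length(x@sites)

#' @describeIn GenotypeLikelihoods-class Number of individuals.
#' @export
nSamples <- function(x) length(x@samples)

#' @describeIn GenotypeLikelihoods-class Site positions as a `GRanges` with
#'   `major`/`minor` metadata columns.
#' @export
glSites <- function(x) x@sites

#' @describeIn GenotypeLikelihoods-class The likelihood array
#'   (`sites x individuals x 3`).
#' @export
glArray <- function(x) x@gl

#' @describeIn GenotypeLikelihoods-class Sample identifiers.
#' @export
glSamples <- function(x) x@samples

#' Subset a GenotypeLikelihoods object by site and/or individual
#'
#' @param x A [GenotypeLikelihoods-class] object.
#' @param i Site index (logical or integer).
#' @param j Individual index (logical or integer).
#' @param ... Ignored.
#' @param drop Ignored; subsetting never drops dimensions.
#' @return A `GenotypeLikelihoods` object.
#' @export
setMethod("[", "GenotypeLikelihoods", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@sites)
  if (missing(j)) j <- seq_along(x@samples)
  new("GenotypeLikelihoods",
      sites = x@sites[i],
      gl = x@gl[i, j, , drop = FALSE],
      samples = x@samples[j])
})

#' Subset a SafLikelihoods object by site
#'
#' @param x A [SafLikelihoods-class] object.
#' @param i Site index (logical or integer).
#' @param j,... Ignored.
#' @param drop Ignored; subsetting never drops dimensions.
#' @return A `SafLikelihoods` object.
#' @export
setMethod("[", "SafLikelihoods", function(x, i, j, ..., drop = FALSE) {
  new("SafLikelihoods", sites = x@sites[i],
      saf = x@saf[i, , drop = FALSE], nInd = x@nInd)
})

#' Accessors for SAF, SFS, ancestry and covariance objects
#'
#' Small accessor functions returning slot contents: `safMatrix()` the
#' per-site SAF likelihood matrix, `sfsMatrix()` the estimated spectrum,
#' `admixtureQ()`/`admixtureF()` the fitted admixture parameters,
#' `loglikTrace()` the EM log-likelihood trace of an estimate, and
#' `pcaEigen()` the eigendecomposition of a covariance result.
#'
#' @param x A [SafLikelihoods-class], [JointSFS-class],
#'   [AncestryModel-class] or [CovarianceResult-class] object as appropriate.
#' @return The slot contents (matrix, numeric vector, or list).
#' @name accessors
NULL

#' @rdname accessors
#' @export
safMatrix <- function(x) x@saf

#' @rdname accessors
#' @export
sfsMatrix <- function(x) {
  if (ncol(x@eta) == 1L) drop(x@eta) else x@eta
}

#' @rdname accessors
#' @export
admixtureQ <- function(x) x@Q

#' @rdname accessors
#' @export
admixtureF <- function(x) x@F

#' @rdname accessors
#' @export
loglikTrace <- function(x) x@loglik

#' @rdname accessors
#' @export
pcaCov <- function(x) x@cov

#' @rdname accessors
#' @export
pcaEigen <- function(x) {
  list(values = x@values, vectors = x@vectors, varFrac = x@varFrac)
}
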