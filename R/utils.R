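#' @importFrom utils head tail write.table read.table
#' @importFrom stats runif rbeta rbinom rpois rgamma quantile fisher.test
#'   dbinom setNames
NULL

#' Derive a per-stage child seed from a master seed
#'
#' A fixed affine map keeps every pipeline stage independently reproducible
#' from one master seed while keeping the result a valid 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param stage Stage index (small positive integer).
#' @return An integer seed.
#' @export
childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %%
               2147483647)
}

# internal: sites data.frame -> GRanges with major/minor mcols
.sitesGRanges <- function(sites) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(sites$chrom),
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
  S4Vectors::mcols(gr)$major <- as.character(sites$major)
  S4Vectors::mcols(gr)$minor <- as.character(sites$minor)
  gr
}

# internal: GRanges -> plain sites data.frame
.sitesFrame <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             major = S4Vectors::mcols(gr)$major,
             minor = S4Vectors::mcols(gr)$minor,
             stringsAsFactors = FALSE)
}
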