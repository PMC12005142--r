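#' Read and write Beagle genotype likelihood files
#'
#' The Beagle GL format is a tab-separated table with a header row and
#' columns `marker` (`"chrom_pos"`), `allele1`, `allele2` (bases coded
#' A, C, G, T as 0, 1, 2, 3), followed by three columns per individual
#' holding the max-rescaled likelihoods of 0, 1 and 2 copies of the second
#' (minor) allele. `writeBeagle()` and `readBeagle()` round-trip a
#' [GenotypeLikelihoods-class] object within 1e-6 relative accuracy;
#' fully uninformative individuals are encoded and recovered as (1, 1, 1).
#'
#' Chromosome labels containing underscores are supported: the position is
#' taken from the text after the last underscore of the marker id.
#'
#' @param gl A [GenotypeLikelihoods-class] object.
#' @param path File path.
#' @return `readBeagle()` returns a [GenotypeLikelihoods-class] object;
#'   `writeBeagle()` returns `path` invisibly.
#' @export
writeBeagle <- function(gl, path) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  sf <- .sitesFrame(gl@sites)
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  N <- nSamples(gl)
  glm <- matrix(aperm(gl@gl, c(1, 3, 2)), nrow = nSites(gl))
  out <- data.table::data.table(
    marker = paste(sf$chrom, sf$pos, sep = "_"),
    allele1 = code[sf$major], allele2 = code[sf$minor])
  glDT <- data.table::as.data.table(glm)
  names(glDT) <- paste0(rep(gl@samples, each = 3L),
                        c("", ".1", ".2")[rep(1:3, N)])
  data.table::fwrite(cbind(out, glDT), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname writeBeagle
#' @param samples Optional sample names for `readBeagle()`; defaults to the
#'   header's first column of each individual triple.
#' @export
readBeagle <- function(path, samples = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if ((ncol(dt) - 3L) %% 3L != 0L || ncol(dt) < 6L)
    stop("malformed Beagle file: ", ncol(dt),
         " columns; expected 3 + 3 per individual")
  N <- (ncol(dt) - 3L) %/% 3L
  marker <- dt[[1]]
  us <- regexpr("_[^_]*$", marker)
  if (any(us < 0)) stop("malformed marker id at line ",
                        which(us < 0)[1] + 1L)
  chrom <- substr(marker, 1L, us - 1L)
  pos <- as.integer(substring(marker, us + 1L))
  decode <- c(`0` = "A", `1` = "C", `2` = "G", `3` = "T")
  glm <- as.matrix(dt[, -(1:3)])
  if (anyNA(glm)) stop("malformed likelihood value at line ",
                       which(rowSums(is.na(glm)) > 0)[1] + 1L)
  gl <- array(glm, dim = c(nrow(dt), 3L, N))
  gl <- aperm(gl, c(1, 3, 2))
  # re-normalize to a max of exactly 1 (text formatting may perturb it)
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  gl <- gl / as.vector(mx)
  dim(gl) <- c(nrow(dt), N, 3L)
  if (is.null(samples)) {
    samples <- names(dt)[seq(4L, by = 3L, length.out = N)]
    samples <- sub("\\.[12]$", "", samples)
  }
  sites <- data.frame(chrom = chrom, pos = pos,
                      major = decode[as.character(dt[[2]])],
                      minor = decode[as.character(dt[[3]])],
                      stringsAsFactors = FALSE)
  new("GenotypeLikelihoods", sites = .sitesGRanges(sites), gl = gl,
      samples = samples)
}

#' Read and write VCF 4.2 files carrying genotype likelihoods
#'
#' `writeVcfGL()` writes one biallelic SNP record per site with the
#' major allele as REF, the minor allele as ALT and a `GL` FORMAT field of
#' log10-scaled likelihood triples in the conventional (hom-REF, het,
#' hom-ALT) order, which matches the package's minor-allele-copy
#' orientation. `readVcfGL()` parses such a file back (via
#' \pkg{VariantAnnotation} when available, else a built-in reader) and
#' rejects records that are not biallelic SNPs.
#'
#' @param gl A [GenotypeLikelihoods-class] object.
#' @param path File path.
#' @return `readVcfGL()` returns a [GenotypeLikelihoods-class] object;
#'   `writeVcfGL()` returns `path` invisibly.
#' @export
writeVcfGL <- function(gl, path) {
  stopifnot(is(gl, "GenotypeLikelihoods"))
  sf <- .sitesFrame(gl@sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pbscan",
    paste0("##FORMAT=<ID=GL,Number=G,Type=Float,",
           "Description=\"Genotype likelihood, log10-scaled\">"),
    paste0(sprintf("##contig=<ID=%s>", unique(sf$chrom)), collapse = "\n"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gl@samples), collapse = "\t")), con)
  lg <- log10(pmax(gl@gl, 1e-300))
  fmt <- matrix("", nSites(gl), nSamples(gl))
  for (i in seq_len(nSamples(gl)))
    fmt[, i] <- sprintf("%.6g,%.6g,%.6g", lg[, i, 1], lg[, i, 2],
                        lg[, i, 3])
  body <- cbind(sf$chrom, sf$pos, paste(sf$chrom, sf$pos, sep = "_"),
                sf$major, sf$minor, ".", "PASS", ".", "GL", fmt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeVcfGL
#' @export
readVcfGL <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- suppressWarnings(VariantAnnotation::readVcf(path))
    rr <- SummarizedExperiment::rowRanges(v)
    ref <- as.character(rr$REF)
    altL <- rr$ALT
    if (any(lengths(altL) != 1L))
      stop("non-biallelic record at site ",
           which(lengths(altL) != 1L)[1])
    alt <- as.character(unlist(altL))
    if (any(nchar(ref) != 1L | nchar(alt) != 1L))
      stop("non-SNP record rejected")
    glRaw <- VariantAnnotation::geno(v)$GL
    S <- nrow(glRaw); N <- ncol(glRaw)
    gl <- array(0, dim = c(S, N, 3L))
    for (i in seq_len(N)) {
      m <- matrix(unlist(glRaw[, i]), nrow = S, byrow = TRUE)
      gl[, i, ] <- m
    }
    sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                        pos = GenomicRanges::start(rr),
                        major = ref, minor = alt, stringsAsFactors = FALSE)
    samples <- colnames(glRaw)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("malformed VCF: no #CHROM header")
    samples <- strsplit(lines[hdr], "\t")[[1]][-(1:9)]
    body <- lines[-seq_len(hdr)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 9L + length(samples))
    if (length(bad)) stop("malformed VCF record at line ", hdr + bad[1])
    m <- do.call(rbind, fields)
    if (any(grepl(",", m[, 5], fixed = TRUE)) ||
        any(nchar(m[, 4]) != 1L | nchar(m[, 5]) != 1L))
      stop("non-biallelic record rejected")
    S <- nrow(m); N <- length(samples)
    gl <- array(0, dim = c(S, N, 3L))
    glIdx <- match("GL", strsplit(m[1, 9], ":", fixed = TRUE)[[1]])
    if (is.na(glIdx)) stop("VCF has no GL FORMAT field")
    for (i in seq_len(N)) {
      cellGL <- vapply(strsplit(m[, 9L + i], ":", fixed = TRUE),
                       `[`, "", glIdx)
      gl[, i, ] <- matrix(as.numeric(unlist(
        strsplit(cellGL, ",", fixed = TRUE))), nrow = S, byrow = TRUE)
    }
    sites <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                        major = m[, 4], minor = m[, 5],
                        stringsAsFactors = FALSE)
  }
  gl <- 10^gl
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  gl <- gl / as.vector(mx)
  dim(gl) <- c(nrow(sites), length(samples), 3L)
  new("GenotypeLikelihoods", sites = .sitesGRanges(sites), gl = gl,
      samples = samples)
}
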