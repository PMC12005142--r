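#' Run the full low-coverage population-genetics pipeline
#'
#' Orchestrates the stages end to end: simulate (or ingest) genotype
#' likelihood data, apply site filters, estimate minor-allele frequencies
#' and filter on them, compute SAF likelihoods and pairwise 2D spectra,
#' run the sliding-window FST/PBS scan with peak calling, and fit the
#' admixture model and PCA covariance. Every stage receives a child seed
#' derived from the master seed by a fixed map, so stages are individually
#' reproducible and a rerun with the same configuration is byte-identical.
#'
#' The configuration is a nested list (or path to a YAML file with the
#' same structure) with blocks:
#' \describe{
#'   \item{`simulate`}{arguments for [simulationConfig()]; alternatively
#'     `input: <path.beagle>` plus `populations` to ingest data.}
#'   \item{`filters`}{`k`, `u`, `hetP`, `strandP` for
#'     [applySiteFilters()].}
#'   \item{`maf`}{`threshold` for [filterMaf()].}
#'   \item{`sfs`}{`tol`, `maxIter` for [estimateSFS()].}
#'   \item{`scan`}{`window`, `step`, `minSites`, `topFraction`,
#'     `minWindows`, `mergeDistance`.}
#'   \item{`structure`}{`K`, `maxIter`, `tol`, `nRestarts`; `run: false`
#'     skips the stage.}
#'   \item{`seed`}{master integer seed.}
#' }
#' Unknown top-level keys are rejected before any stage runs. A resolved
#' copy of the configuration is written next to the outputs, and all stage
#' outputs are persisted as tab-separated text.
#'
#' @param config Nested list or path to a YAML file.
#' @param outDir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with the per-stage results: `data`, `filterReport`,
#'   `maf`, `gl` (filtered), `sfs` (per pair), `windows`, `peaks`,
#'   `admixture`, `pca`, and `genomeFst`/`genomePbs` summaries.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "filters", "maf", "sfs", "scan", "structure",
             "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(outDir, "resolved-config.yaml"))
  }
  persist <- function(df, name) {
    if (!is.null(outDir))
      utils::write.table(df, file.path(outDir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## stage 1: data
  simBlock <- config$simulate
  if (!is.null(simBlock$input)) {
    gl <- readBeagle(simBlock$input)
    pop <- simBlock$populations
    if (is.null(pop)) stop("ingested data needs a 'populations' vector")
    pop <- rep(seq_along(pop), pop)
    pileup <- NULL
    truth <- NULL
  } else {
    simArgs <- simBlock[setdiff(names(simBlock), "input")]
    simArgs$seed <- childSeed(seed, 11L)
    if (!is.null(simArgs$sweep)) simArgs$sweep <- as.list(simArgs$sweep)
    scfg <- do.call(simulationConfig, simArgs)
    d <- simulateDataset(scfg)
    gl <- computeGL(d$pileup, d$sites, nInd = sum(scfg$nInd))
    pop <- d$truth$pop
    pileup <- d$pileup
    truth <- d$truth
    persist(d$sites, "sites.tsv")
    persist(data.frame(indiv = seq_along(pop), pop = pop,
                       d$truth$Q), "truth-q.tsv")
  }

  ## stage 2: site filters
  report <- NULL
  if (!is.null(pileup)) {
    report <- applySiteFilters(pileup, gl,
                               k = cfg("filters", "k", 10L),
                               u = cfg("filters", "u", 1L),
                               hetP = cfg("filters", "hetP", 1e-6),
                               strandP = cfg("filters", "strandP", 1e-4))
    persist(report, "site-filters.tsv")
    gl <- gl[report$pass, ]
  }

  ## stage 3: minor allele frequencies
  maf <- estimateMafEM(gl)
  persist(maf, "maf.tsv")
  glF <- filterMaf(gl, maf, threshold = cfg("maf", "threshold", 0.05))
  if (!is.null(outDir))
    writeBeagle(glF, file.path(outDir, "genolike.beagle"))

  ## stage 4: SAF and pairwise 2D spectra
  pops <- sort(unique(pop))
  if (length(pops) < 3)
    stop("the PBS scan needs three populations")
  saf <- lapply(pops, function(p) safLikelihoods(glF[, pop == p]))
  tolSfs <- cfg("sfs", "tol", 1e-8)
  maxIterSfs <- cfg("sfs", "maxIter", 500L)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sfsList <- lapply(pairs, function(pr)
    estimateSFS(saf[[pr[1]]], saf[[pr[2]]], tol = tolSfs,
                maxIter = maxIterSfs))
  names(sfsList) <- vapply(pairs, paste, "", collapse = "-")
  if (!is.null(outDir))
    for (nm in names(sfsList))
      utils::write.table(sfsList[[nm]]@eta,
                         file.path(outDir, paste0("sfs-", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)

  ## stage 5: FST / PBS scan
  comp <- lapply(seq_along(pairs), function(i)
    fstComponents(saf[[pairs[[i]][1]]], saf[[pairs[[i]][2]]],
                  sfsList[[i]]))
  genomeFst <- vapply(comp, windowFst, 0)
  names(genomeFst) <- names(sfsList)
  genomePbs <- pbs(genomeFst[1], genomeFst[2], genomeFst[3])
  windows <- slidingScan(comp[[1]], comp[[2]], comp[[3]],
                         window = cfg("scan", "window", 50000L),
                         step = cfg("scan", "step", 10000L),
                         minSites = cfg("scan", "minSites", 10L))
  peaks <- callPeaks(windows,
                     topFraction = cfg("scan", "topFraction", 0.001),
                     minWindows = cfg("scan", "minWindows", 6L),
                     mergeDistance = cfg("scan", "mergeDistance", 1e6))
  persist(windows, "windows.tsv")
  persist(peaks, "peaks.tsv")
  if (!is.null(outDir) && nrow(peaks))
    utils::write.table(
      data.frame(peaks$chrom, peaks$start - 1L,
                 peaks$start - 1L + cfg("scan", "window", 50000L)),
      file.path(outDir, "peaks.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)

  ## stage 6: structure
  admix <- NULL; pca <- NULL
  if (!identical(cfg("structure", "run", TRUE), FALSE)) {
    admix <- admixtureEM(glF, K = cfg("structure", "K", 3L),
                         maxIter = cfg("structure", "maxIter", 1000L),
                         tol = cfg("structure", "tol", 1e-6),
                         nRestarts = cfg("structure", "nRestarts", 3L),
                         seed = childSeed(seed, 12L))
    pca <- pcaCovariance(glF, maf = NULL,
                         K = cfg("structure", "K", 3L))
    persist(data.frame(indiv = glF@samples, pop = pop,
                       admixtureQ(admix)), "admixture-q.tsv")
    persist(as.data.frame(pcaEigen(pca)$vectors[, 1:3]), "pca.tsv")
  }

  invisible(list(data = list(pileup = pileup, truth = truth, pop = pop),
                 filterReport = report, maf = maf, gl = glF,
                 sfs = sfsList, genomeFst = genomeFst,
                 genomePbs = unname(genomePbs), windows = windows,
                 peaks = peaks, admixture = admix, pca = pca))
}
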