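#' Per-site FST components as posterior expectations
#'
#' Computes the per-site numerator and denominator of the Hudson/Bhatia
#' ratio-of-sums FST estimator as posterior expectations over the joint
#' sample allele counts (j, k), with the 2D spectrum as prior. With
#' \eqn{p_1 = j / 2n_1} and \eqn{p_2 = k / 2n_2}:
#' \deqn{N(j,k) = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{2n_1 - 1}
#'   - \frac{p_2(1-p_2)}{2n_2 - 1}, \qquad
#'   D(j,k) = p_1(1 - p_2) + p_2(1 - p_1)}
#' and the per-site components are a = E\[N\], d = E\[D\] under
#' \eqn{P(j,k) \propto \eta(j,k) L_1(j) L_2(k)}. Window and genome-wide
#' FST are then the ratio of sums of these components
#' (see [windowFst()]).
#'
#' @param saf1,saf2 [SafLikelihoods-class] objects for the two populations
#'   (same sites).
#' @param sfs A [JointSFS-class] 2D spectrum for the pair (from
#'   [estimateSFS()]).
#' @return A `data.frame` with `chrom`, `pos`, `a`, `d` per site. Sites
#'   with an identically zero posterior get `NA` components.
#' @export
fstComponents <- function(saf1, saf2, sfs) {
  stopifnot(is(saf1, "SafLikelihoods"), is(saf2, "SafLikelihoods"),
            is(sfs, "JointSFS"))
  n1 <- saf1@nInd; n2 <- saf2@nInd
  if (n1 < 1 || n2 < 1) stop("populations must have at least 1 individual")
  eta <- sfs@eta
  stopifnot(nrow(eta) == 2L * n1 + 1L, ncol(eta) == 2L * n2 + 1L)
  p1 <- (0:(2 * n1)) / (2 * n1)
  p2 <- (0:(2 * n2)) / (2 * n2)
  P1 <- matrix(p1, length(p1), length(p2))
  P2 <- matrix(p2, length(p1), length(p2), byrow = TRUE)
  Nmat <- (P1 - P2)^2 - P1 * (1 - P1) / (2 * n1 - 1) -
    P2 * (1 - P2) / (2 * n2 - 1)
  Dmat <- P1 * (1 - P2) + P2 * (1 - P1)
  L1 <- saf1@saf; L2 <- saf2@saf
  norm <- rowSums((L1 %*% eta) * L2)
  a <- rowSums((L1 %*% (eta * Nmat)) * L2) / norm
  d <- rowSums((L1 %*% (eta * Dmat)) * L2) / norm
  bad <- !is.finite(norm) | norm == 0
  a[bad] <- NA_real_; d[bad] <- NA_real_
  sf <- .sitesFrame(saf1@sites)
  data.frame(chrom = sf$chrom, pos = sf$pos, a = a, d = d,
             stringsAsFactors = FALSE)
}

#' Window (or genome-wide) FST as a ratio of sums
#'
#' `sum(a) / sum(d)` over the supplied per-site components -- the
#' ratio-of-sums estimator, which is not the mean of per-site ratios.
#'
#' @param components Data frame with columns `a` and `d` (from
#'   [fstComponents()]); `NA` rows are dropped.
#' @return The FST estimate, or `NA` when the denominator sum is 0.
#' @examples
#' windowFst(data.frame(a = c(0.5, 0), d = c(1, 1)))  # 0.25
#' @export
windowFst <- function(components) {
  a <- components$a; d <- components$d
  ok <- !is.na(a) & !is.na(d)
  sd <- sum(d[ok])
  if (sd == 0) return(NA_real_)
  sum(a[ok]) / sd
}

#' Branch length from FST
#'
#' The log transform `T = -log(1 - FST)` mapping an FST value to an
#' additive branch length. Negative FST estimates are clamped to 0 before
#' the transform; FST = 1 maps to `Inf`.
#'
#' @param fst Numeric vector of FST values.
#' @return Branch lengths, same length.
#' @examples
#' branchLength(c(0, 0.5, -0.01))
#' @export
branchLength <- function(fst) {
  -log(1 - pmax(fst, 0))
}

#' Population branch statistic
#'
#' For focal population i and reference populations j, k:
#' \deqn{PBS_i = (T_{ij} + T_{ik} - T_{jk}) / 2, \qquad
#'   T = -\log(1 - F_{ST}).}
#' Large values indicate allele-frequency divergence specific to the focal
#' population, the signature of recent positive selection. The statistic
#' may be negative; any missing input yields a missing output.
#'
#' @param fstIJ,fstIK FST between the focal population and each reference.
#' @param fstJK FST between the two reference populations.
#' @return The PBS value(s); vectorized.
#' @examples
#' pbs(0.044, 0.040, 0.016)
#' @export
pbs <- function(fstIJ, fstIK, fstJK) {
  (branchLength(fstIJ) + branchLength(fstIK) - branchLength(fstJK)) / 2
}

#' Sliding-window FST and PBS scan
#'
#' Computes window FST for the three population pairs and the focal
#' population's PBS in sliding windows. Windows are half-open intervals
#' `[start, start + window)` with 1-based starts at 1, 1 + step, ... per
#' chromosome, so every site contributes to `ceiling(window / step)`
#' overlapping windows. Windows with fewer than `minSites` sites (in any
#' pair's component table) get `NA` statistics and are excluded from
#' percentile ranking downstream.
#'
#' @param compIJ,compIK,compJK Per-site component tables from
#'   [fstComponents()] for pairs (focal, ref1), (focal, ref2),
#'   (ref1, ref2); all three must cover the same sites in the same order.
#' @param window Window width in bp (default 50000).
#' @param step Slide in bp (default 10000). A width that is not a multiple
#'   of the step is allowed (with a warning).
#' @param minSites Minimum sites per window (default 10).
#' @return A `data.frame` of windows: `chrom`, `start`, `end` (exclusive),
#'   `nSites`, `fstIJ`, `fstIK`, `fstJK`, `pbs`, sorted by chromosome and
#'   start.
#' @export
slidingScan <- function(compIJ, compIK, compJK, window = 50000L,
                        step = 10000L, minSites = 10L) {
  stopifnot(nrow(compIJ) == nrow(compIK), nrow(compIJ) == nrow(compJK),
            all(compIJ$pos == compIK$pos), all(compIJ$pos == compJK$pos))
  if (window %% step != 0)
    warning("window is not a multiple of step")
  out <- list()
  for (chr in unique(compIJ$chrom)) {
    rows <- compIJ$chrom == chr
    pos <- compIJ$pos[rows]
    o <- order(pos)
    pos <- pos[o]
    comp <- lapply(list(compIJ, compIK, compJK), function(x) {
      y <- x[rows, , drop = FALSE][o, , drop = FALSE]
      y$a[is.na(y$d)] <- 0; y$d[is.na(y$d)] <- 0
      y
    })
    naSite <- is.na(compIJ$d[rows][o]) | is.na(compIK$d[rows][o]) |
      is.na(compJK$d[rows][o])
    starts <- seq.int(1L, max(pos), by = step)
    # per-window sums via cumulative sums over position-sorted sites
    cums <- lapply(comp, function(y)
      list(a = cumsum(y$a), d = cumsum(y$d)))
    cn <- cumsum(!naSite)
    lo <- findInterval(starts - 1L, pos)        # sites strictly before start
    hi <- findInterval(starts + window - 1L, pos)  # sites < start + window
    sumRange <- function(cs) {
      c(0, cs)[hi + 1L] - c(0, cs)[lo + 1L]
    }
    nSites <- sumRange(cn)
    fst <- lapply(cums, function(cc) {
      sa <- sumRange(cc$a); sd <- sumRange(cc$d)
      ifelse(sd > 0, sa / sd, NA_real_)
    })
    valid <- nSites >= minSites
    f1 <- ifelse(valid, fst[[1]], NA_real_)
    f2 <- ifelse(valid, fst[[2]], NA_real_)
    f3 <- ifelse(valid, fst[[3]], NA_real_)
    out[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = starts + window, nSites = nSites,
                             fstIJ = f1, fstIK = f2, fstJK = f3,
                             pbs = pbs(f1, f2, f3),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), nSites = numeric(),
                      fstIJ = numeric(), fstIK = numeric(),
                      fstJK = numeric(), pbs = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call selection peaks from a PBS window scan
#'
#' Implements the outlier peak-calling rule: windows with PBS strictly
#' above the empirical `1 - topFraction` quantile (order-statistic
#' quantile; ties at the threshold are all included because the comparison
#' is strict) form the top set. Top windows are clustered greedily: the
#' highest-PBS unassigned top window seeds a peak and absorbs every
#' unassigned top window on the same chromosome whose center lies within
#' `mergeDistance` of its own. Clusters with at least `minWindows` top
#' windows are reported, sorted by their best window's PBS.
#'
#' @param windows Window table from [slidingScan()].
#' @param topFraction Tail fraction defining top windows (default 0.001).
#' @param minWindows Minimum top windows for a reported peak (default 6).
#' @param mergeDistance Center-to-center absorption distance in bp
#'   (default 1e6).
#' @return A `data.frame` of peaks: `chrom`, `start` (best window's
#'   start), `pbs` (best window's PBS), `nTopWindows`.
#' @export
callPeaks <- function(windows, topFraction = 0.001, minWindows = 6L,
                      mergeDistance = 1e6) {
  w <- windows[!is.na(windows$pbs), , drop = FALSE]
  if (nrow(w) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      pbs = numeric(), nTopWindows = integer(),
                      stringsAsFactors = FALSE))
  if (nrow(w) < 1 / topFraction)
    warning("fewer than 1/topFraction windows; ",
            "threshold is still the empirical quantile")
  thr <- stats::quantile(w$pbs, 1 - topFraction, type = 1, names = FALSE)
  top <- w[w$pbs > thr, , drop = FALSE]
  if (nrow(top) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      pbs = numeric(), nTopWindows = integer(),
                      stringsAsFactors = FALSE))
  top <- top[order(-top$pbs), , drop = FALSE]
  center <- (top$start + top$end) / 2
  assigned <- rep(FALSE, nrow(top))
  peaks <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1]  # highest remaining PBS
    inPeak <- !assigned & top$chrom == top$chrom[seed] &
      abs(center - center[seed]) <= mergeDistance
    assigned[inPeak] <- TRUE
    peaks[[length(peaks) + 1L]] <-
      data.frame(chrom = top$chrom[seed], start = top$start[seed],
                 pbs = top$pbs[seed], nTopWindows = sum(inPeak),
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, peaks)
  res <- res[res$nTopWindows >= minWindows, , drop = FALSE]
  res <- res[order(-res$pbs), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Manhattan-style plot of a PBS scan
#'
#' Plots window PBS against position with a dashed line at the empirical
#' top-fraction threshold.
#'
#' @param windows Window table from [slidingScan()].
#' @param topFraction Tail fraction for the threshold line (default 0.001).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the threshold drawn.
#' @export
plotScan <- function(windows, topFraction = 0.001, ...) {
  w <- windows[!is.na(windows$pbs), , drop = FALSE]
  chrs <- unique(w$chrom)
  offset <- setNames(cumsum(c(0, head(tapply(w$end, w$chrom, max)[chrs],
                                      -1))), chrs)
  x <- w$start + offset[w$chrom]
  graphics::plot(x, w$pbs, pch = 16, cex = 0.4,
                 col = (match(w$chrom, chrs) %% 2) + 1,
                 xlab = "position (bp)", ylab = "PBS", ...)
  thr <- stats::quantile(w$pbs, 1 - topFraction, type = 1, names = FALSE)
  graphics::abline(h = thr, lty = 2)
  invisible(thr)
}
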