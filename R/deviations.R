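# Motif accessibility deviations: observed vs library-size-normalized
# expected fragment counts per motif and sample, Z-scored against background
# peak sets matched on GC content and mean accessibility.

#' Observed and expected motif accessibility
#'
#' `observed(motif, sample)` sums fragment counts over motif-bearing peaks.
#' `expected(motif, sample)` distributes the motif's grand total over samples
#' proportionally to library size:
#' `expected = (sum_s observed(motif, s) / sum_s lib_s) * lib_sample`.
#' The raw deviation is `(observed - expected) / expected`; a motif/sample
#' cell with zero expected count is NA (flagged in the result). By
#' construction the library-size-weighted mean deviation across samples is
#' exactly 0 for every motif, and deviations are exactly invariant to
#' uniform sequencing-depth rescaling (all counts and library sizes times a
#' constant). Rescaling a single sample is only approximately neutral: the
#' pooled expectation itself shifts, by an amount that vanishes as the other
#' samples dominate the pool.
#'
#' @param counts Peak x sample count matrix.
#' @param hits A [MotifHitMatrix] (or a peak x motif logical matrix) on the
#'   same peaks.
#' @param librarySizes Per-sample totals (default `colSums(counts)`).
#' @return list(observed, expected, deviations) of motif x sample matrices.
#' @export
motifObservedExpected <- function(counts, hits,
                                  librarySizes = colSums(counts)) {
  occ <- if (is(hits, "MotifHitMatrix")) occupancy(hits) else hits
  if (nrow(occ) != nrow(counts))
    stop("hits and counts cover different numbers of peaks")
  if (!is.null(rownames(occ)) && !is.null(rownames(counts)) &&
      !identical(rownames(occ), rownames(counts)))
    stop("hits and counts must be on the same peaks, in the same order")
  obs <- t(occ) %*% counts
  frac <- rowSums(obs) / sum(librarySizes)
  expd <- outer(frac, librarySizes)
  dimnames(expd) <- dimnames(obs)
  dev <- (obs - expd) / expd
  dev[expd == 0] <- NA_real_
  list(observed = as.matrix(obs), expected = expd,
       deviations = as.matrix(dev))
}

#' Sample GC- and accessibility-matched background peak sets
#'
#' Peaks are binned on a 2-D grid of (GC content, mean normalized
#' accessibility), `nBins` quantile bins per axis. For each background
#' iteration every peak is replaced by a peak drawn (with replacement) from
#' its own bin; an empty bin falls back to the nearest non-empty bin with a
#' warning. Set `matched = FALSE` for unmatched uniform sampling over all
#' peaks. The sampling is seeded and reproducible.
#'
#' @param counts Peak x sample count matrix.
#' @param sequences Peak sequences (named character or `DNAStringSet`) for
#'   GC content; ignored when `matched = FALSE`.
#' @param nIterations Number of background sets (>= 2; default 50).
#' @param nBins Quantile bins per axis (default 10).
#' @param seed RNG seed (default 0).
#' @param matched Match on (GC, accessibility) bins (default TRUE).
#' @return Integer matrix, peaks x iterations, of sampled peak indices.
#' @export
sampleBackgroundSets <- function(counts, sequences = NULL, nIterations = 50L,
                                 nBins = 10L, seed = 0L, matched = TRUE) {
  if (nIterations < 2)
    stop("at least 2 background iterations are required for a sd")
  n <- nrow(counts)
  if (matched) {
    if (is.null(sequences))
      stop("sequences are required for GC-matched sampling")
    if (is(sequences, "DNAStringSet"))
      sequences <- stats::setNames(as.character(sequences), names(sequences))
    if (length(sequences) != n)
      stop("sequences and counts cover different numbers of peaks")
    baseCodes <- vapply(c("A", "C", "G", "T"), utf8ToInt, integer(1))
    gc <- vapply(sequences, function(s) {
      v <- utf8ToInt(toupper(s))
      acgt <- sum(v %in% baseCodes)
      if (!acgt) return(0.5)
      sum(v %in% baseCodes[c("C", "G")]) / acgt
    }, numeric(1))
    acc <- rowMeans(sweep(counts, 2, colSums(counts), "/"))
    qbin <- function(x) {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
      if (length(br) < 2) return(rep(1L, length(x)))
      as.integer(cut(x, br, include.lowest = TRUE))
    }
    bin <- paste(qbin(gc), qbin(acc))
  } else {
    bin <- rep("all", n)
  }
  byBin <- split(seq_len(n), bin)
  withSeed(seed, {
    vapply(seq_len(nIterations), function(i) {
      out <- integer(n)
      for (b in names(byBin)) {
        idx <- byBin[[b]]
        out[idx] <- idx[sample.int(length(idx), length(idx),
                                   replace = TRUE)]
      }
      out
    }, integer(n))
  })
}

#' Motif deviation Z-scores against sampled backgrounds
#'
#' For each motif and sample the Z-score is
#' `z = (dev - mean(dev_bg)) / sd(dev_bg)` where the background deviations
#' re-run [motifObservedExpected()] with each background peak set standing in
#' for the motif's peaks (counts re-indexed by the sampled peak mapping). A
#' background sd of zero (e.g. a motif present in every peak) yields NA,
#' flagged. Z-scores are invariant to the order of background iterations.
#'
#' @param counts Peak x sample count matrix.
#' @param hits A [MotifHitMatrix] or logical occupancy matrix.
#' @param backgrounds Peak-index matrix from [sampleBackgroundSets()].
#' @param librarySizes Per-sample totals (default `colSums(counts)`).
#' @return A [MotifDeviations] with assays `deviations` and `z`.
#' @export
deviationZscores <- function(counts, hits, backgrounds,
                             librarySizes = colSums(counts)) {
  if (ncol(backgrounds) < 2) stop("need >= 2 background iterations")
  occ <- if (is(hits, "MotifHitMatrix")) occupancy(hits) else hits
  fg <- motifObservedExpected(counts, occ, librarySizes)
  dev <- fg$deviations
  nIter <- ncol(backgrounds)
  bgSum <- array(0, dim(dev))
  bgSumSq <- array(0, dim(dev))
  for (i in seq_len(nIter)) {
    b <- backgrounds[, i]
    bgDev <- motifObservedExpected(counts[b, , drop = FALSE],
                                   unname(occ), librarySizes)$deviations
    bgSum <- bgSum + bgDev
    bgSumSq <- bgSumSq + bgDev^2
  }
  bgMean <- bgSum / nIter
  bgSd <- sqrt(pmax(bgSumSq / nIter - bgMean^2, 0) * nIter / (nIter - 1))
  z <- (dev - bgMean) / bgSd
  z[bgSd == 0] <- NA_real_
  se <- SummarizedExperiment(
    assays = list(deviations = dev, z = z),
    metadata = list(n_iterations = nIter,
                    sd_zero = which(bgSd == 0, arr.ind = TRUE)))
  new("MotifDeviations", se)
}

#' Differential motif deviations between sample groups
#'
#' Two groups: Welch t-test on the deviation Z-scores; more than two: one-way
#' ANOVA. BH FDR across motifs; significance at `fdr < fdrThreshold`
#' (default 0.01). Identical group vectors (zero variance, equal means)
#' report p = 1.
#'
#' @param deviations A [MotifDeviations] (or a motif x sample z matrix).
#' @param groups Factor of sample group labels (>= 2 groups, >= 2 samples
#'   each).
#' @param fdrThreshold Significance threshold on BH FDR (default 0.01).
#' @return data.frame (motif, p_value, fdr, significant, group means).
#' @export
differentialDeviations <- function(deviations, groups, fdrThreshold = 0.01) {
  z <- if (is(deviations, "MotifDeviations")) deviationZ(deviations)
  else deviations
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(table(groups))[table(groups) < 2], collapse = ", "))
  testOne <- function(y) {
    ok <- is.finite(y)
    if (any(tapply(ok, groups, sum) < 2)) return(NA_real_)
    y <- y[ok]; g <- droplevels(groups[ok])
    if (nlevels(g) < 2) return(NA_real_)
    vars <- tapply(y, g, stats::var)
    if (all(vars == 0)) {
      mns <- tapply(y, g, mean)
      return(if (max(mns) - min(mns) == 0) 1 else 0)
    }
    if (nlevels(g) == 2)
      stats::t.test(y ~ g)$p.value
    else
      summary(stats::aov(y ~ g))[[1]][["Pr(>F)"]][1]
  }
  p <- apply(z, 1, testOne)
  mns <- t(apply(z, 1, function(y) tapply(y, groups, mean, na.rm = TRUE)))
  colnames(mns) <- paste0("mean_", levels(groups))
  out <- data.frame(motif = rownames(z), p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$fdr) & out$fdr < fdrThreshold
  cbind(out, mns)
}
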