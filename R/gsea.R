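# Peak-level GSEA. Gene sets are lifted to peak sets through the peak-to-gene
# map; the ranked universe is the accessome ordered by a differential
# statistic (log2 fold change of a chosen contrast); enrichment uses the
# classic weighted Kolmogorov-Smirnov running sum; significance comes from a
# permutation null built by shuffling membership labels over the ranked list
# (peak permutation), with sign-split NES normalization and the +1-corrected
# permutation p-value.

#' Lift a gene set to its associated peak set
#'
#' All peaks associated with any member gene (set semantics: a peak shared by
#' two member genes appears once).
#'
#' @param geneSet A [GeneSet] (or character vector of gene ids).
#' @param peakGeneMap Output of [associatePeaksToGenes()].
#' @param name Name for the resulting set (default: the gene set's).
#' @return A [PeakSet] (possibly empty).
#' @export
peaksForGeneSet <- function(geneSet, peakGeneMap, name = NULL) {
  genes <- if (is(geneSet, "GeneSet")) memberIds(geneSet)
  else as.character(geneSet)
  if (is.null(name))
    name <- if (is(geneSet, "GeneSet")) setName(geneSet) else "gene_set_peaks"
  PeakSet(name,
          unique(peakGeneMap$peak_id[peakGeneMap$gene_id %in% genes]),
          provenance = sprintf("peaks associated with %d genes (+/-10 kb map)",
                               length(unique(genes))))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list keeping a running sum: member peaks step up by
#' `|stat|^w / sum(|stat|^w over members)`, non-members step down by
#' `1 / (N - m)`. The enrichment score is the extremum of the running sum
#' (signed; ties broken toward the positive extremum). `w = 0` reduces to the
#' unweighted "running tally" form.
#'
#' @param rankedStats Named numeric vector of per-peak statistics, sorted in
#'   decreasing order (re-sorted internally if needed; ties keep input
#'   order).
#' @param memberIds Character vector (or [PeakSet]) of member peak ids; must
#'   be a subset of `names(rankedStats)`.
#' @param weightExponent Weight exponent `w` (default 1).
#' @return list(es, running) with the full running-sum profile.
#' @export
enrichmentScore <- function(rankedStats, memberIds, weightExponent = 1) {
  if (is(memberIds, "PeakSet")) memberIds <- memberIds(memberIds)
  if (is.unsorted(-rankedStats))   # stable: ties keep input order
    rankedStats <- rankedStats[order(rankedStats, decreasing = TRUE)]
  N <- length(rankedStats)
  isMember <- names(rankedStats) %in% memberIds
  m <- sum(isMember)
  if (m == 0L) stop("no member peaks in the ranked universe")
  if (m == N) return(list(es = 1, running = cumsum(
    abs(rankedStats)^weightExponent / sum(abs(rankedStats)^weightExponent))))
  w <- abs(rankedStats)^weightExponent
  wm <- sum(w[isMember])
  if (wm == 0)
    stop("all member weights are zero with weightExponent > 0")
  steps <- ifelse(isMember, w / wm, -1 / (N - m))
  running <- cumsum(steps)
  hi <- max(running)
  lo <- min(running)
  es <- if (hi >= -lo) hi else lo
  list(es = es, running = running)
}

# Enrichment score from member positions only: O(m) per evaluation, used for
# permutations. `pos` are sorted 1-based ranks of members; `w` their weights.
esFromPositions <- function(pos, w, N) {
  m <- length(pos)
  if (m == N) return(1)
  gain <- cumsum(w) / sum(w)
  down <- 1 / (N - m)
  atMember <- gain - down * (pos - seq_len(m))       # just after each member
  beforeMember <- c(0, gain[-m]) - down * (pos - seq_len(m))  # just before
  hi <- max(atMember)
  lo <- min(beforeMember, 0)
  if (hi >= -lo) hi else lo
}

#' Peak-level GSEA with permutation NES
#'
#' For each set: the enrichment score over the ranked accessome, a
#' permutation null obtained by placing the same number of member labels at
#' random ranks (`nPerm` draws), the normalized enrichment score
#' `nes = es / mean(|es_perm|)` over same-sign permutations, the
#' +1-corrected permutation p-value
#' `p = (1 + #{same-sign perms at least as extreme}) / (1 + #same-sign)`,
#' and BH FDR across all scored sets. Sets with fewer than `minSize` member
#' peaks in the universe (or more than `maxSize`) are skipped.
#'
#' @param rankedStats Named numeric vector (peak -> statistic); sorted
#'   internally in decreasing order.
#' @param peakSets Named list of [PeakSet]s (or id vectors).
#' @param nPerm Number of permutations (default 10,000; < 100 warns).
#' @param minSize,maxSize Size bounds on member peaks present in the ranking.
#' @param weightExponent Weight exponent (default 1; recorded in output).
#' @param seed RNG seed for the permutation stream (default 0).
#' @return data.frame (set, size, es, nes, p_value, fdr, weight_exponent);
#'   skipped sets appear with NA scores.
#' @export
runGsea <- function(rankedStats, peakSets, nPerm = 10000L, minSize = 5L,
                    maxSize = Inf, weightExponent = 1, seed = 0L) {
  if (nPerm < 100) warning("nPerm < 100: permutation p-values are unstable")
  rankedStats <- rankedStats[order(rankedStats, decreasing = TRUE)]
  N <- length(rankedStats)
  w <- abs(rankedStats)^weightExponent
  ids <- names(rankedStats)
  withSeed(seed, {
    rows <- lapply(names(peakSets), function(nm) {
      memb <- peakSets[[nm]]
      if (is(memb, "PeakSet")) memb <- memberIds(memb)
      pos <- sort(which(ids %in% memb))
      m <- length(pos)
      if (m < minSize || m > maxSize)
        return(data.frame(set = nm, size = m, es = NA_real_, nes = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
      es <- esFromPositions(pos, w[pos], N)
      perm <- vapply(seq_len(nPerm), function(i) {
        p <- sort(sample.int(N, m))
        esFromPositions(p, w[p], N)
      }, numeric(1))
      same <- perm[sign(perm) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      data.frame(set = nm, size = m, es = es, nes = nes, p_value = p,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  scored <- !is.na(out$p_value)
  out$fdr[scored] <- stats::p.adjust(out$p_value[scored], method = "BH")
  out$weight_exponent <- weightExponent
  out
}

# Evaluate an expression under a locally-set, restorable RNG state with
# explicit generator kinds so seeded results are identical across platforms.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  eval.parent(substitute(expr))
}
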