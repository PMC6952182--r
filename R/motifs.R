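# PWM scanning with exact score thresholds, hypergeometric motif enrichment,
# and the iterative motif-to-TF assignment used to build a minimally
# redundant motif catalog.
#
# Scores are log2 odds (bits) of the PWM against background nucleotide
# frequencies, discretized on a fixed lattice (default 1e-3 bits per step).
# The threshold for a match-probability cutoff p is found by exact dynamic
# programming over the lattice score distribution under the background
# model; scanning scores windows on the same lattice, so threshold and scan
# are exactly consistent and the only approximation is the lattice
# granularity itself.

scoreLattice <- function(pwm, background, granularity) {
  bg <- background[c("A", "C", "G", "T")]
  if (any(bg <= 0) || abs(sum(bg) - 1) > 1e-6)
    stop("background frequencies must be positive and sum to 1")
  bits <- log2(pwm@matrix / bg)
  round(bits / granularity)  # integer lattice units
}

#' Exact PWM score threshold for a match-probability cutoff
#'
#' The match score of a sequence window is
#' `sum over positions of log2(p_pwm(base, pos) / p_bg(base))`. Under the
#' background model the exact distribution of this score (on the
#' discretization lattice) is computed by dynamic programming
#' (position-by-position convolution), and the threshold is the smallest
#' lattice score `s` with `P_bg(score >= s) <= pCutoff`. A degenerate motif
#' whose maximal score is still too probable (e.g. a uniform PWM on a
#' uniform background) gets threshold `+Inf` with a warning: no window can
#' match.
#'
#' @param pwm A [PWMotif].
#' @param background Named frequencies for A/C/G/T (positive, summing to 1).
#' @param pCutoff Match probability cutoff (default 5e-5).
#' @param granularity Lattice step in bits (default 1e-3); the only source
#'   of threshold tolerance.
#' @return Score threshold in bits (lattice-aligned), or `+Inf`.
#' @export
pwmThreshold <- function(pwm, background = c(A = 0.25, C = 0.25, G = 0.25,
                                             T = 0.25),
                         pCutoff = 5e-5, granularity = 1e-3) {
  if (!isTRUE(pCutoff > 0 && pCutoff < 1))
    stop("pCutoff must lie in (0, 1)")
  u <- scoreLattice(pwm, background, granularity)
  bg <- background[c("A", "C", "G", "T")]
  # DP over the lattice: dist[k] = P(score so far == (k + offset - 1))
  lo <- sum(apply(u, 2, min))
  hi <- sum(apply(u, 2, max))
  dist <- numeric(hi - lo + 1)
  dist[1] <- 1
  width <- 1L
  for (j in seq_len(ncol(u))) {
    uj <- u[, j] - min(u[, j])
    newWidth <- width + max(uj)
    nd <- numeric(newWidth)
    for (b in 1:4) {
      idx <- seq_len(width) + uj[b]
      nd[idx] <- nd[idx] + dist[seq_len(width)] * bg[b]
    }
    dist[seq_len(newWidth)] <- nd
    width <- newWidth
  }
  dist <- dist[seq_len(width)]           # scores lo..hi in lattice units
  tail <- rev(cumsum(rev(dist)))
  # smallest *achievable* score whose upper tail passes the cutoff (between
  # achievable scores the tail is constant, so this is the canonical choice
  # and the match decision is identical)
  ok <- which(tail <= pCutoff & dist > 0)
  if (!length(ok)) {
    warning("motif '", pwm@id,
            "': no score threshold achieves the cutoff; returning +Inf")
    return(Inf)
  }
  (lo + ok[1] - 1) * granularity
}

revcompLattice <- function(u) {
  # complement rows (A<->T, C<->G) and reverse columns
  u[c(4, 3, 2, 1), rev(seq_len(ncol(u))), drop = FALSE]
}

encodeSeq <- function(s, peak) {
  v <- utf8ToInt(toupper(s))
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 1L
  code[v == utf8ToInt("C")] <- 2L
  code[v == utf8ToInt("G")] <- 3L
  code[v == utf8ToInt("T")] <- 4L
  code[v == utf8ToInt("N")] <- 5L
  if (any(code == 0L))
    stop("invalid character(s) in sequence for peak '", peak, "'")
  code
}

scanOneStrand <- function(code, u5) {
  L <- ncol(u5)
  W <- length(code) - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (j in seq_len(L)) sc <- sc + u5[code[seq_len(W) + j - 1L], j]
  sc
}

#' Scan peak sequences for PWM matches at an exact p-value cutoff
#'
#' Both strands are scanned; a window whose lattice score reaches the
#' motif's [pwmThreshold()] is a hit, and peak-level occupancy is "any hit
#' in the peak". Ambiguous bases (N) score zero log-odds (background-like)
#' and so cannot create a match on their own. The background defaults to
#' nucleotide frequencies computed from the full scanned sequence set --
#' by contract, the accessome sequences.
#'
#' @param sequences Named character vector or `DNAStringSet` of peak
#'   sequences (names = peak ids).
#' @param pwms Named list of [PWMotif]s.
#' @param background Optional named A/C/G/T frequencies; computed from
#'   `sequences` when NULL.
#' @param pCutoff Match probability cutoff (default 5e-5).
#' @param granularity Score lattice step in bits.
#' @return A [MotifHitMatrix].
#' @export
scanSequences <- function(sequences, pwms, background = NULL,
                          pCutoff = 5e-5, granularity = 1e-3) {
  if (is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    stop("sequences must be named by peak id")
  if (is.null(background)) background <- backgroundFrequencies(sequences)
  codes <- mapply(encodeSeq, sequences, names(sequences), SIMPLIFY = FALSE)
  ids <- vapply(pwms, function(p) p@id, character(1))
  occ <- matrix(FALSE, length(sequences), length(pwms),
                dimnames = list(names(sequences), ids))
  hits <- list()
  thresholds <- stats::setNames(numeric(length(pwms)), ids)
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    u <- scoreLattice(pwm, background, granularity)
    u <- rbind(u, N = 0L)           # row 5: ambiguous base scores 0
    thr <- pwmThreshold(pwm, background, pCutoff, granularity)
    thresholds[k] <- thr
    if (!is.finite(thr)) next
    thrU <- round(thr / granularity)
    uR <- rbind(revcompLattice(u[1:4, , drop = FALSE]), N = 0L)
    for (i in seq_along(codes)) {
      fwd <- scanOneStrand(codes[[i]], u)
      rev <- scanOneStrand(codes[[i]], uR)
      fh <- which(fwd >= thrU)
      rh <- which(rev >= thrU)
      if (length(fh) || length(rh)) {
        occ[i, k] <- TRUE
        hits[[length(hits) + 1L]] <- data.frame(
          peak = names(codes)[i], motif = pwm@id,
          position = c(fh, rh),
          strand = rep(c("+", "-"), c(length(fh), length(rh))),
          score = c(fwd[fh], rev[rh]) * granularity,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
  else data.frame(peak = character(), motif = character(),
                  position = integer(), strand = character(),
                  score = numeric(), stringsAsFactors = FALSE)
  new("MotifHitMatrix", occupancy = occ, hits = hits,
      thresholds = thresholds, background = background)
}

#' Background nucleotide frequencies of a sequence set
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @return Named A/C/G/T frequencies (N bases excluded).
#' @export
backgroundFrequencies <- function(sequences) {
  if (is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  all <- paste(sequences, collapse = "")
  v <- utf8ToInt(toupper(all))
  counts <- c(A = sum(v == utf8ToInt("A")), C = sum(v == utf8ToInt("C")),
              G = sum(v == utf8ToInt("G")), T = sum(v == utf8ToInt("T")))
  counts / sum(counts)
}

#' Hypergeometric motif enrichment of a peak set against the accessome
#'
#' For each motif: `a` = set peaks containing the motif, `m` = accessome
#' peaks containing it, `n` = set size, `N` = accessome size;
#' `p = P(X >= a)` with `X ~ Hypergeometric(N, m, n)` (one-tailed), and the
#' odds ratio compares the in-set odds of containing the motif with the
#' accessome-wide odds: `OR = [a / (n - a)] / [m / (N - m)]`. Zero cells get
#' the Haldane 0.5 continuity correction (flagged). A relative-risk variant
#' `(a/n) / (m/N)` is available via `effect = "rr"`. BH FDR across motifs.
#'
#' @param hits A [MotifHitMatrix] covering the accessome.
#' @param peakSet A [PeakSet] (or peak id vector), subset of the accessome.
#' @param effect `"or"` (odds ratio, default) or `"rr"` (relative risk).
#' @return data.frame (motif, a, set_size, m, universe, p_value, odds_ratio,
#'   log2_or, corrected, flagged, fdr, effect).
#' @export
motifEnrichment <- function(hits, peakSet, effect = c("or", "rr")) {
  effect <- match.arg(effect)
  occ <- occupancy(hits)
  setIds <- if (is(peakSet, "PeakSet")) memberIds(peakSet)
  else as.character(peakSet)
  if (!all(setIds %in% rownames(occ)))
    stop("peak set contains ids absent from the scanned accessome")
  N <- nrow(occ)
  n <- length(setIds)
  inSet <- rownames(occ) %in% setIds
  rows <- lapply(colnames(occ), function(mo) {
    m <- sum(occ[, mo])
    a <- sum(occ[inSet, mo])
    flagged <- FALSE
    if (m == 0) {
      p <- 1
      flagged <- TRUE
    } else {
      p <- stats::phyper(a - 1, m, N - m, n, lower.tail = FALSE)
    }
    corrected <- FALSE
    if (effect == "or") {
      if (a == 0 || a == n || m == 0 || m == N) {
        orv <- ((a + 0.5) / (n - a + 0.5)) / ((m + 0.5) / (N - m + 0.5))
        corrected <- TRUE
      } else {
        orv <- (a / (n - a)) / (m / (N - m))
      }
    } else {
      orv <- if (m == 0) NA_real_ else (a / n) / (m / N)
    }
    data.frame(motif = mo, a = a, set_size = n, m = m, universe = N,
               p_value = p, odds_ratio = orv, log2_or = log2(orv),
               corrected = corrected, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$effect <- effect
  out
}

#' Iteratively assign candidate motifs to transcription factors
#'
#' Resolves a many-to-many motif/TF candidate catalog into a one-TF-per-motif
#' assignment while minimizing redundancy. At stage `k = 1, 2, ...`:
#' repeatedly (i) drop candidate associations pointing at TFs that already
#' have at least one assigned motif, then (ii) assign every motif whose
#' remaining association count is between 1 and `k` (at `k = 1` this means
#' exactly one remaining TF; for `k > 1`, a motif still facing several
#' motif-less TFs goes to the one with the fewest remaining candidate
#' motifs, lexicographic tie-break). Each stage iterates to a fixed point
#' before `k` increments; the procedure stops when every TF with any
#' candidate motif has an assigned motif, or no further progress is
#' possible. Termination is guaranteed: every pass either assigns a motif
#' (strictly fewer unassigned TF targets) or increments `k` up to the
#' maximum association count.
#'
#' @param catalog data.frame with columns `motif` and `tf` (candidate
#'   associations).
#' @return list(assignment = data.frame(motif, tf, stage),
#'   unassigned_tfs = character).
#' @export
assignMotifsToTfs <- function(catalog) {
  if (!nrow(catalog))
    return(list(assignment = data.frame(motif = character(),
                                        tf = character(), stage = integer(),
                                        stringsAsFactors = FALSE),
                unassigned_tfs = character()))
  cand <- unique(catalog[, c("motif", "tf")])
  cand$motif <- as.character(cand$motif)
  cand$tf <- as.character(cand$tf)
  allTfs <- sort(unique(cand$tf))
  assigned <- data.frame(motif = character(), tf = character(),
                         stage = integer(), stringsAsFactors = FALSE)
  k <- 1L
  maxK <- max(table(cand$motif))
  repeat {
    progress <- TRUE
    while (progress) {
      progress <- FALSE
      assignedTfs <- unique(assigned$tf)
      # (i) drop associations to TFs that already have a motif
      live <- cand[!(cand$tf %in% assignedTfs) &
                     !(cand$motif %in% assigned$motif), , drop = FALSE]
      if (!nrow(live)) break
      counts <- table(live$motif)
      ready <- names(counts)[counts <= k]
      if (!length(ready)) break
      # motifs resolved in the same pass are assigned simultaneously: two
      # motifs each left with only TF X both become motifs of X
      tfLoad <- table(live$tf)  # candidate motifs per unassigned TF
      for (mo in sort(ready)) {
        tfs <- live$tf[live$motif == mo]
        pick <- tfs[order(tfLoad[tfs], tfs)][1]   # rarest-first, then name
        assigned <- rbind(assigned, data.frame(motif = mo, tf = pick,
                                               stage = k,
                                               stringsAsFactors = FALSE))
        progress <- TRUE
      }
    }
    done <- all(allTfs %in% assigned$tf)
    if (done || k >= maxK) break
    k <- k + 1L
  }
  list(assignment = assigned,
       unassigned_tfs = setdiff(allTfs, assigned$tf))
}
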