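# Shared in-code fixtures: everything is built programmatically so the test
# suite carries no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# GRanges from 0-based half-open triples, the convention used on disk
gr0 <- function(chrom, start0, end0, strand = "*", seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- seqlen[GenomeInfoDb::seqlevels(gr)]
  gr
}

tinyGenome <- c(chr1 = 100000L, chr2 = 50000L)

# a deterministic non-overlapping accessome on the tiny genome
tinyAccessome <- function(n = 40L, width = 400L, gap = 800L) {
  starts <- seq(1000L, by = width + gap, length.out = n)
  chrom <- rep(c("chr1", "chr2"), c(ceiling(n * 0.7), floor(n * 0.3)))
  starts[chrom == "chr2"] <- seq(500L, by = width + gap,
                                 length.out = sum(chrom == "chr2"))
  Accessome(gr0(chrom, starts, starts + width, seqlen = tinyGenome))
}

# one + strand and one - strand transcript with UTRs, for window arithmetic
twoTxModels <- function(seqlen = c(chr1 = 100000L)) {
  si <- GenomeInfoDb::Seqinfo(names(seqlen), unname(seqlen))
  mk <- function(s, e, strand, tid, gid) {
    g <- GRanges("chr1", IRanges(s, e), strand = strand, seqinfo = si)
    mcols(g)$tx_id <- tid
    if (!missing(gid)) mcols(g)$gene_id <- gid
    g
  }
  # + strand: 5'UTR begins at 0-based 10000; exons [10001,10800], [11201,12000]
  txP <- mk(10001, 12000, "+", "txP.1", "geneP")
  exP <- c(mk(10001, 10800, "+", "txP.1"), mk(11201, 12000, "+", "txP.1"))
  u5P <- mk(10001, 10150, "+", "txP.1")
  u3P <- mk(11801, 12000, "+", "txP.1")
  # - strand: TSS at its right end (0-based 29999)
  txM <- mk(28001, 30000, "-", "txM.1", "geneM")
  exM <- c(mk(28001, 28900, "-", "txM.1"), mk(29301, 30000, "-", "txM.1"))
  u5M <- mk(29851, 30000, "-", "txM.1")
  u3M <- mk(28001, 28200, "-", "txM.1")
  GeneModels(transcripts = c(txP, txM), exons = c(exP, exM),
             utr5 = c(u5P, u5M), utr3 = c(u3P, u3M))
}

# toy DA tables covering the contrasts the set algebra needs
mkDaTable <- function(ids, lfc = 0, p = 1, fdr = 1) {
  data.frame(peak_id = ids,
             log2fc = rep_len(lfc, length(ids)),
             p_value = rep_len(p, length(ids)),
             fdr = rep_len(fdr, length(ids)),
             stringsAsFactors = FALSE)
}

daContrastKeys <- c("FgfrDN_vs_LacZ@10", "MekAct_vs_LacZ@10",
                    "MekAct_vs_FgfrDN@10", "FgfrDN_vs_LacZ@18",
                    "MRasCA_vs_LacZ@18", "MRasCA_vs_FgfrDN@18",
                    "t10_vs_t18")

nullDaTables <- function(ids) {
  tabs <- lapply(daContrastKeys, function(k) mkDaTable(ids))
  names(tabs) <- daContrastKeys
  tabs
}

# independent exhaustive-enumeration oracle for the two-sided binomial test
binomEnumOracle <- function(k, n, p0) {
  d <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
              numeric(1))
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# independent hypergeometric upper-tail oracle by explicit summation
hyperEnumOracle <- function(a, m, N, n) {
  if (a > min(m, n)) return(0)
  ks <- max(0, a):min(m, n)
  sum(vapply(ks, function(k)
    choose(m, k) * choose(N - m, n - k) / choose(N, n), numeric(1)))
}

# a near-deterministic PWM around a consensus site
sharpPwm <- function(consensus, id = "m", strength = 1000L) {
  L <- nchar(consensus)
  counts <- matrix(1L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(consensus, "")[[1]]
  for (j in seq_len(L)) counts[b[j], j] <- strength
  pwmFromCounts(counts, id = id)
}

# exhaustive 4^L oracle for the PWM score threshold: enumerate every
# sequence's lattice score and its background probability, aggregate equal
# scores, and take the smallest achievable score whose tail passes
thresholdEnumOracle <- function(pwm, bg, pCutoff, granularity = 1e-3) {
  u <- round(log2(pwm@matrix / bg[c("A", "C", "G", "T")]) / granularity)
  L <- ncol(u)
  scores <- 0; probs <- 1
  for (j in seq_len(L)) {
    scores <- as.vector(outer(scores, u[, j], "+"))
    probs <- as.vector(outer(probs, bg[c("A", "C", "G", "T")], "*"))
  }
  byScore <- tapply(probs, scores, sum)
  sc <- as.numeric(names(byScore))
  o <- order(sc)
  sc <- sc[o]; pb <- unname(byScore[o])
  tail <- rev(cumsum(rev(pb)))
  ok <- which(tail <= pCutoff)
  if (!length(ok)) return(Inf)
  sc[ok[1]] * granularity
}
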