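# Accessome construction: merge raw peak sets into a unique, non-overlapping
# reference atlas, filtered for a minimum retained length.

#' Merge raw peak sets into a reference accessome
#'
#' Concatenates any number of peak interval sets, merges overlapping and
#' book-ended intervals (intervals that share a boundary are fused, matching
#' `bedtools merge` defaults), drops merged intervals of length <= 50 bp
#' (strictly: a 51 bp interval is the shortest retained at the default
#' `minLength`), and assigns stable peak identifiers in (chromosome, start)
#' order. Merging ignores strand: ATAC-seq peaks are unstranded.
#'
#' @param peakSets A `GRanges`, or a list of `GRanges`, of raw peak calls.
#' @param genomeSizes Chromosome lengths: a named numeric vector, a
#'   `Seqinfo`, or a two-column data.frame (chrom, length).
#' @param minLength Minimum retained peak length in bp (default 51, i.e.
#'   "length > 50 bp").
#' @return An [Accessome].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 151, 301), c(200, 260, 340)))
#' mergeToAccessome(gr, c(chr1 = 1000))
#' @export
mergeToAccessome <- function(peakSets, genomeSizes, minLength = 51L) {
  si <- asSeqinfo(genomeSizes)
  if (is(peakSets, "GRanges")) peakSets <- list(peakSets)
  if (!length(peakSets) || !sum(lengths(peakSets))) {
    empty <- GRanges(seqinfo = si)
    mcols(empty)$peak_id <- character()
    return(new("Accessome", empty))
  }
  all <- suppressWarnings(do.call(c, lapply(unname(peakSets), granges)))
  checkWithinBounds(all, si)
  seqlevels(all) <- seqlevels(si)
  seqinfo(all) <- si
  strand(all) <- "*"
  merged <- reduce(GenomicRanges::sort(all), ignore.strand = TRUE)
  merged <- merged[width(merged) >= minLength]
  mcols(merged)$peak_id <- peakIdsFromRanges(merged)
  new("Accessome", merged)
}

asSeqinfo <- function(genomeSizes) {
  if (is(genomeSizes, "Seqinfo")) return(genomeSizes)
  if (is.data.frame(genomeSizes))
    genomeSizes <- stats::setNames(as.numeric(genomeSizes[[2]]),
                                   as.character(genomeSizes[[1]]))
  if (is.null(names(genomeSizes)) || any(!is.finite(genomeSizes)) ||
      any(genomeSizes <= 0))
    stop("genomeSizes must be named, finite and positive")
  Seqinfo(names(genomeSizes), as.integer(genomeSizes))
}

checkWithinBounds <- function(gr, si) {
  unknown <- setdiff(as.character(unique(seqnames(gr))), seqlevels(si))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  per <- seqlengths(si)[as.character(seqnames(gr))]
  bad <- which(start(gr) < 1L | end(gr) > per)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "interval out of chromosome bounds: %s:%d-%d (length %d bp chromosome)",
      as.character(seqnames(gr))[b], start(gr)[b] - 1L, end(gr)[b],
      per[b]))
  }
  invisible(TRUE)
}

#' Fraction of the genome covered by the accessome
#'
#' Sum of peak lengths divided by total genome length; the denominator comes
#' from the accessome's `seqlengths`.
#'
#' @param accessome An [Accessome].
#' @return A fraction in `[0, 1]`.
#' @export
genomeCoverageFraction <- function(accessome) {
  total <- sum(as.numeric(seqlengths(accessome)))
  if (!isTRUE(total > 0)) stop("zero-length genome")
  sum(as.numeric(width(accessome))) / total
}

#' Resize peaks to a fixed width around their centers
#'
#' Each peak is replaced by a fixed-width window centered on
#' `floor((start0 + end0) / 2)` in 0-based coordinates, then clipped at
#' chromosome bounds (so boundary peaks may come out shorter). Used before
#' motif deviation analysis so every peak contributes a comparable sequence
#' window.
#'
#' @param accessome An [Accessome] (or any `GRanges` with seqlengths).
#' @param width Target width in bp (default 200).
#' @return A `GRanges` with the original `peak_id`s; resized windows may
#'   overlap, so the result is deliberately not an `Accessome`.
#' @export
resizePeaks <- function(accessome, width = 200L) {
  gr <- granges(accessome)
  mcols(gr)$peak_id <- peakIds(accessome)
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  ctr <- (s0 + e0) %/% 2L
  half <- as.integer(width) %/% 2L
  new_s0 <- pmax(ctr - half, 0L)
  new_e0 <- pmin(ctr + (as.integer(width) - half),
                 seqlengths(gr)[as.character(seqnames(gr))])
  IRanges::ranges(gr) <- IRanges(new_s0 + 1L, new_e0)
  gr
}
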