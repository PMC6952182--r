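#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import SummarizedExperiment
NULL

#' Accessome: an atlas of unique, non-overlapping accessible regions
#'
#' An `Accessome` is a [GenomicRanges::GRanges] subclass holding the reference
#' atlas of accessible chromatin regions that serves as the universe for all
#' downstream enrichment statistics. Peaks are unstranded, sorted by
#' (chromosome, start), pairwise non-overlapping, and carry stable identifiers
#' in `mcols()$peak_id`. Chromosome lengths must be present in `seqinfo()` so
#' that genome-fraction nulls are well defined.
#'
#' Construct with [mergeToAccessome()] (the normal route, which merges raw
#' per-sample peak sets) or [Accessome()] for ranges already known to be
#' disjoint.
#'
#' @seealso [mergeToAccessome()], [genomeCoverageFraction()]
#' @export
setClass("Accessome", contains = "GRanges")

setValidity("Accessome", function(object) {
  msg <- character()
  if (length(object)) {
    if (is.null(mcols(object)$peak_id))
      msg <- c(msg, "peaks must carry a 'peak_id' metadata column")
    else if (anyDuplicated(mcols(object)$peak_id))
      msg <- c(msg, "peak_id values must be unique")
    if (!all(strand(object) == "*"))
      msg <- c(msg, "accessome peaks must be unstranded ('*')")
    if (is.unsorted(order(as.integer(seqnames(object)), start(object))) ||
        !identical(order(as.integer(seqnames(object)), start(object)),
                   seq_along(object)))
      msg <- c(msg, "peaks must be sorted by (chromosome, start)")
    if (!GenomicRanges::isDisjoint(object))
      msg <- c(msg, "peaks must be pairwise non-overlapping")
    sl <- seqlengths(object)
    if (any(is.na(sl)))
      msg <- c(msg, "all chromosome lengths must be known (seqlengths)")
    else {
      per <- sl[as.character(seqnames(object))]
      if (any(end(object) > per) || any(start(object) < 1L))
        msg <- c(msg, "peaks must lie within chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Accessome Construct an Accessome from a disjoint GRanges.
#'   Assigns `peak_id`s in sorted order when absent.
#' @param peaks A `GRanges` with complete `seqlengths`.
#' @export
Accessome <- function(peaks) {
  peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
  strand(peaks) <- "*"
  if (is.null(mcols(peaks)$peak_id))
    mcols(peaks)$peak_id <- peakIdsFromRanges(peaks)
  new("Accessome", peaks)
}

peakIdsFromRanges <- function(gr) {
  # BED-convention (0-based half-open) coordinates in the id, plus a rank
  sprintf("%s:%d-%d_%d", as.character(seqnames(gr)), start(gr) - 1L,
          end(gr), seq_along(gr))
}

#' @describeIn Accessome Stable peak identifiers, in atlas order.
#' @param x An `Accessome`.
#' @export
peakIds <- function(x) mcols(x)$peak_id

setMethod("show", "Accessome", function(object) {
  cat(sprintf("Accessome with %d peaks on %d sequences (%.2f%% of genome)\n",
              length(object), length(seqlevels(object)),
              100 * genomeCoverageFraction(object)))
  callNextMethod()
})

#' PeakSet and GeneSet: named member sets with provenance
#'
#' Lightweight containers for the named peak sets and gene sets produced by
#' threshold-based set algebra over differential tables. `provenance` records
#' the contrasts and thresholds that defined the set, so membership is always
#' traceable to the rules that produced it.
#'
#' @slot name Set name.
#' @slot members Character vector of member identifiers.
#' @slot provenance Character vector describing the defining rules.
#' @export
setClass("AnnotatedSet", representation("VIRTUAL",
  name = "character", members = "character", provenance = "character"))

#' @rdname AnnotatedSet-class
#' @export
setClass("PeakSet", contains = "AnnotatedSet")

#' @rdname AnnotatedSet-class
#' @export
setClass("GeneSet", contains = "AnnotatedSet")

setValidity("AnnotatedSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (!length(object@provenance)) msg <- c(msg, "provenance must be non-empty")
  if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
  if (length(msg)) msg else TRUE
})

#' @param name,members,provenance See slots.
#' @rdname AnnotatedSet-class
#' @export
PeakSet <- function(name, members, provenance = "user-defined") {
  new("PeakSet", name = name, members = unique(as.character(members)),
      provenance = provenance)
}

#' @rdname AnnotatedSet-class
#' @export
GeneSet <- function(name, members, provenance = "user-defined") {
  new("GeneSet", name = name, members = unique(as.character(members)),
      provenance = provenance)
}

#' @describeIn AnnotatedSet-class Member identifiers.
#' @param x An `AnnotatedSet`.
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname AnnotatedSet-class
#' @export
setMethod("memberIds", "AnnotatedSet", function(x) x@members)

#' @describeIn AnnotatedSet-class Set name.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname AnnotatedSet-class
#' @export
setMethod("setName", "AnnotatedSet", function(x) x@name)

#' @describeIn AnnotatedSet-class Defining rules.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname AnnotatedSet-class
#' @export
setMethod("provenance", "AnnotatedSet", function(x) x@provenance)

setMethod("show", "AnnotatedSet", function(object) {
  cat(sprintf("%s '%s': %d members\n  provenance: %s\n", class(object),
              object@name, length(object@members),
              paste(object@provenance, collapse = "; ")))
})

setMethod("length", "AnnotatedSet", function(x) length(x@members))

#' PWMotif: a position weight matrix
#'
#' A probability matrix over A/C/G/T per motif position, together with the
#' pseudocount used to regularize it. Columns are positions; rows are the four
#' bases. Every column sums to 1 and all entries are strictly positive, so
#' log-odds scores against any positive background are finite.
#'
#' @slot id Motif identifier.
#' @slot matrix 4 x L numeric matrix, rownames `c("A","C","G","T")`.
#' @slot pseudocount Pseudocount applied when the matrix was built.
#' @export
setClass("PWMotif", representation(id = "character", matrix = "matrix",
                                   pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  m <- object@matrix
  msg <- character()
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix rows must be A, C, G, T")
  if (ncol(m) < 1L) msg <- c(msg, "motif must have at least one position")
  if (any(m <= 0)) msg <- c(msg, "all entries must be > 0 (use a pseudocount)")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "each position must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s', %d positions, consensus %s\n", object@id,
              ncol(object@matrix), motifConsensus(object)))
})

#' @describeIn PWMotif Motif length in bp.
#' @param x A `PWMotif`.
#' @export
setMethod("length", "PWMotif", function(x) ncol(x@matrix))

#' MotifHitMatrix: motif occupancy over an accessome
#'
#' Result of scanning peak sequences with a set of PWMs at an exact
#' score-threshold p-value cutoff. `occupancy` is the peak x motif logical
#' matrix (any hit in the peak); `hits` records every individual match with
#' position, strand and score; `thresholds` are the log2-odds score cutoffs
#' actually applied.
#'
#' @slot occupancy Logical matrix, peaks x motifs.
#' @slot hits data.frame with columns peak, motif, position, strand, score.
#' @slot thresholds Named numeric vector of score thresholds (bits).
#' @slot background Background nucleotide frequencies used for scoring.
#' @export
setClass("MotifHitMatrix", representation(
  occupancy = "matrix", hits = "data.frame", thresholds = "numeric",
  background = "numeric"))

setMethod("show", "MotifHitMatrix", function(object) {
  cat(sprintf(
    "MotifHitMatrix: %d peaks x %d motifs, %d individual hits\n",
    nrow(object@occupancy), ncol(object@occupancy), nrow(object@hits)))
})

#' @describeIn MotifHitMatrix The peak x motif logical occupancy matrix.
#' @param x A `MotifHitMatrix`.
#' @export
occupancy <- function(x) x@occupancy

#' @describeIn MotifHitMatrix Per-hit table (peak, motif, position, strand,
#'   score).
#' @export
motifHits <- function(x) x@hits

#' MotifDeviations: motif-level accessibility deviations and Z-scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with assays
#' `deviations` (raw, library-size-normalized accessibility deviations) and
#' `z` (deviation Z-scores against sampled background peak sets). Background
#' sampling parameters live in `metadata()`.
#'
#' @export
setClass("MotifDeviations", contains = "SummarizedExperiment")

setMethod("show", "MotifDeviations", function(object) {
  cat(sprintf("MotifDeviations: %d motifs x %d samples (%d background iterations)\n",
              nrow(object), ncol(object),
              metadata(object)$n_iterations %||% NA_integer_))
  invisible(NULL)
})

#' @describeIn MotifDeviations Deviation Z-score matrix (motif x sample).
#' @param x A `MotifDeviations`.
#' @export
deviationZ <- function(x) assay(x, "z")

#' @describeIn MotifDeviations Raw deviation matrix (motif x sample).
#' @export
rawDeviations <- function(x) assay(x, "deviations")

`%||%` <- function(a, b) if (is.null(a)) b else a
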