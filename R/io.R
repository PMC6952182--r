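# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED6, chrom.sizes, GFF3 gene models, count/metadata TSVs, MEME minimal
# and JASPAR PFM motif files, and GMT-like gene-set tables. Coordinates are
# BED-convention (0-based half-open) on disk and GRanges (1-based closed) in
# memory; rtracklayer performs the conversion for BED/GFF3.

#' Read a BED3/BED6 file of intervals
#'
#' @param path Path to a tab-separated BED file (0-based half-open).
#' @param genomeSizes Optional chromosome lengths to attach as `seqinfo`.
#' @return A `GRanges`.
#' @export
readBed <- function(path, genomeSizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genomeSizes)) {
    si <- asSeqinfo(genomeSizes)
    checkWithinBounds(gr, si)
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
  }
  gr
}

#' Write intervals to BED
#'
#' Writes BED6 when `name`/`score` metadata are present, BED3-style otherwise;
#' `peak_id`s are written as the name column.
#'
#' @param gr A `GRanges` or [Accessome].
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  out <- granges(gr)
  if (!is.null(mcols(gr)$peak_id)) names(out) <- mcols(gr)$peak_id
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns chromosome, length.
#' @return A `Seqinfo`.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
  asSeqinfo(tab)
}

#' @rdname readChromSizes
#' @param genomeSizes Named lengths or `Seqinfo`.
#' @export
writeChromSizes <- function(genomeSizes, path) {
  si <- asSeqinfo(genomeSizes)
  utils::write.table(
    data.frame(chrom = seqlevels(si), length = seqlengths(si)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models

#' GeneModels: transcript structures for annotation
#'
#' Holds transcripts with their exon, CDS and UTR intervals, each carrying
#' `tx_id` (and `gene_id` on transcripts). Exons must be non-overlapping
#' within a transcript, and CDS/UTR intervals must lie within the exon union.
#'
#' @slot transcripts `GRanges` of transcript spans (mcols: tx_id, gene_id).
#' @slot exons,cds,utr5,utr3 `GRanges` with an mcols `tx_id` column.
#' @export
setClass("GeneModels", representation(
  transcripts = "GRanges", exons = "GRanges", cds = "GRanges",
  utr5 = "GRanges", utr3 = "GRanges"))

setValidity("GeneModels", function(object) {
  msg <- character()
  tx <- object@transcripts
  if (length(tx) && (is.null(mcols(tx)$tx_id) || is.null(mcols(tx)$gene_id)))
    msg <- c(msg, "transcripts need tx_id and gene_id metadata")
  for (slot in c("exons", "cds", "utr5", "utr3")) {
    gr <- slot(object, slot)
    if (length(gr) && is.null(mcols(gr)$tx_id))
      msg <- c(msg, paste(slot, "needs a tx_id metadata column"))
  }
  if (length(object@exons)) {
    byTx <- split(granges(object@exons), mcols(object@exons)$tx_id)
    if (any(!vapply(byTx, GenomicRanges::isDisjoint, logical(1))))
      msg <- c(msg, "exons must be non-overlapping within each transcript")
  }
  if (length(msg)) msg else TRUE
})

#' @param transcripts,exons,cds,utr5,utr3 See slots.
#' @rdname GeneModels-class
#' @export
GeneModels <- function(transcripts, exons,
                       cds = GRanges(), utr5 = GRanges(), utr3 = GRanges()) {
  missing_ex <- setdiff(mcols(transcripts)$tx_id, mcols(exons)$tx_id)
  if (length(missing_ex))
    stop("transcript(s) with no exons: ", paste(missing_ex, collapse = ", "))
  new("GeneModels", transcripts = transcripts, exons = exons, cds = cds,
      utr5 = utr5, utr3 = utr3)
}

#' @describeIn GeneModels-class Gene identifiers present in the models.
#' @param x A `GeneModels`.
#' @export
geneIds <- function(x) unique(mcols(x@transcripts)$gene_id)

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d transcripts, %d genes, %d exons\n",
              length(object@transcripts), length(geneIds(object)),
              length(object@exons)))
})

#' Read gene models from GFF3
#'
#' Restricted to `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features; anything else in the file is ignored.
#' Transcript-to-gene relationships follow `Parent`/`ID` attributes
#' (1-based GFF3 coordinates are converted on import).
#'
#' @param path Path to a GFF3 file.
#' @param genomeSizes Optional chromosome lengths attached as `seqinfo`.
#' @return A [GeneModels].
#' @export
readGff3GeneModels <- function(path, genomeSizes = NULL) {
  gff <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(genomeSizes)) {
    si <- asSeqinfo(genomeSizes)
    seqlevels(gff) <- seqlevels(si)
    seqinfo(gff) <- si
  }
  type <- as.character(gff$type)
  mrna <- gff[type == "mRNA"]
  tx2gene <- stats::setNames(as.character(unlist(mrna$Parent)),
                             as.character(mrna$ID))
  tx <- granges(mrna)
  mcols(tx)$tx_id <- as.character(mrna$ID)
  mcols(tx)$gene_id <- unname(tx2gene[mcols(tx)$tx_id])
  pull <- function(what) {
    sub <- gff[type == what]
    out <- granges(sub)
    mcols(out)$tx_id <- as.character(unlist(sub$Parent))
    out
  }
  GeneModels(transcripts = tx, exons = pull("exon"), cds = pull("CDS"),
             utr5 = pull("five_prime_UTR"), utr3 = pull("three_prime_UTR"))
}

#' Write gene models to GFF3
#'
#' @param models A [GeneModels].
#' @param path Output path.
#' @export
writeGff3GeneModels <- function(models, path) {
  tx <- models@transcripts
  genes <- unlist(range(split(granges(tx), mcols(tx)$gene_id)))
  grow <- function(gr, type, id = NULL, parent = NULL) {
    if (!length(gr)) return(GRanges())
    out <- granges(gr)
    mcols(out)$type <- type
    mcols(out)$ID <- id
    mcols(out)$Parent <- if (is.null(parent)) IRanges::CharacterList(
      vector("list", length(out))) else IRanges::CharacterList(as.list(parent))
    # nominal phase on CDS rows keeps the GFF3 writer quiet; the reader
    # does not use phase
    mcols(out)$phase <- if (type == "CDS") 0L else NA_integer_
    out
  }
  rows <- c(
    grow(genes, "gene", id = names(genes)),
    grow(tx, "mRNA", id = mcols(tx)$tx_id, parent = mcols(tx)$gene_id),
    grow(models@exons, "exon", parent = mcols(models@exons)$tx_id),
    grow(models@cds, "CDS", parent = mcols(models@cds)$tx_id),
    grow(models@utr5, "five_prime_UTR", parent = mcols(models@utr5)$tx_id),
    grow(models@utr3, "three_prime_UTR", parent = mcols(models@utr3)$tx_id))
  rtracklayer::export(rows, path, format = "GFF3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Counts, metadata, DA/DE tables, sets

#' Read a peak x sample count table
#'
#' @param path TSV with a `peak_id` column followed by one column per sample.
#' @return Integer matrix with peak_id rownames.
#' @export
readCountsTsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname readCountsTsv
#' @param counts Matrix with rownames.
#' @export
writeCountsTsv <- function(counts, path) {
  writeTsv(data.frame(peak_id = rownames(counts), counts,
                      check.names = FALSE), path)
}

#' Read sample metadata
#'
#' @param path TSV with columns sample, lineage, condition, timepoint,
#'   replicate.
#' @return data.frame with `sample` as rownames.
#' @export
readSampleMeta <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample", "lineage", "condition", "timepoint", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  rownames(meta) <- meta$sample
  meta
}

#' Read a differential table (gene or peak level)
#'
#' @param path TSV with an id column plus log2fc, p_value and fdr (or p)
#'   columns.
#' @return data.frame.
#' @export
readDiffTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write two-column set files (set_name, member_id)
#'
#' @param path TSV path.
#' @param kind `"peak"` or `"gene"`.
#' @return A named list of [PeakSet] or [GeneSet] objects.
#' @export
readSetsTsv <- function(path, kind = c("peak", "gene")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ctor <- if (kind == "peak") PeakSet else GeneSet
  sets <- lapply(split(tab[[2]], tab[[1]]), function(m)
    ctor(name = "x", members = m, provenance = paste("read from", basename(path))))
  for (nm in names(sets)) sets[[nm]]@name <- nm
  sets
}

#' @rdname readSetsTsv
#' @param sets Named list of `AnnotatedSet`s.
#' @export
writeSetsTsv <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    if (length(memberIds(s))) data.frame(set_name = setName(s),
                                       member_id = memberIds(s))))
  writeTsv(df %||% data.frame(set_name = character(), member_id = character()),
           path)
}

# ---------------------------------------------------------------------------
# Motif formats

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their letter-probability matrices. Probabilities
#' are re-regularized with the package pseudocount so all entries are strictly
#' positive.
#'
#' @param path Path to a MEME minimal-format file.
#' @param pseudocount Pseudocount mass (split by background) used to keep
#'   probabilities strictly positive; default 0.8.
#' @param nsites Assumed site count behind the probability matrix when the
#'   file does not state one (default 100).
#' @return Named list of [PWMotif] objects.
#' @export
readMeme <- function(path, pseudocount = 0.8, nsites = 100) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  bgline <- grep("^Background letter frequencies", lines)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (length(bgline) && bgline[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgline[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    if (!anyNA(vals) && length(vals) == 4)
      bg <- stats::setNames(vals, toks[c(TRUE, FALSE)])[c("A", "C", "G", "T")]
  }
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[lp])
    ns <- if (grepl("nsites=", lines[lp]))
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", lines[lp])) else nsites
    w <- as.integer(w)
    rows <- lines[(lp + 1):(lp + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
    # back to pseudo-counts, regularize, renormalize
    probs <- t((t(m) * ns) + pseudocount * bg[c("A", "C", "G", "T")])
    probs <- probs / rowSums(probs)
    mat <- t(probs)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- new("PWMotif", id = id, matrix = mat,
                     pseudocount = pseudocount)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms Named list of [PWMotif]s.
#' @param path Output path.
#' @param background Background frequencies recorded in the header.
#' @export
writeMeme <- function(pwms, path, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background["A"],
                       background["C"], background["G"], background["T"]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p@id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 100 E= 0",
      ncol(p@matrix)), con)
    apply(p@matrix, 2, function(col)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3],
                         col[4]), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read a JASPAR PFM file
#'
#' Accepts the four-row count format, with or without `A [ ... ]` brackets,
#' one `>`-prefixed header per motif.
#'
#' @inheritParams readMeme
#' @return Named list of [PWMotif]s.
#' @export
readJasparPfm <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    id <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]][1]
    rows <- lines[(h + 1):(h + 4)]
    counts <- t(vapply(rows, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, FUN.VALUE = as.numeric(
      strsplit(trimws(gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", rows[1])),
               "\\s+")[[1]]), USE.NAMES = FALSE))
    out[[id]] <- pwmFromCounts(t(counts), id = id, pseudocount = pseudocount)
  }
  out
}

#' Build a PWMotif from a count matrix
#'
#' Applies a background-split pseudocount: `p = (n + pc * bg) / (N + pc)`.
#'
#' @param counts 4 x L (or L x 4) count matrix.
#' @param id Motif id.
#' @param pseudocount Total pseudocount mass per position (default 0.8).
#' @param background Background distribution splitting the pseudocount.
#' @return A [PWMotif].
#' @export
pwmFromCounts <- function(counts, id = "motif", pseudocount = 0.8,
                          background = c(A = 0.25, C = 0.25, G = 0.25,
                                         T = 0.25)) {
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  rownames(counts) <- c("A", "C", "G", "T")
  tot <- colSums(counts)
  probs <- sweep(counts + pseudocount * background[rownames(counts)], 2,
                 tot + pseudocount, "/")
  new("PWMotif", id = id, matrix = probs, pseudocount = pseudocount)
}

#' Most probable base at each motif position
#'
#' @param pwm A [PWMotif].
#' @return Consensus string.
#' @export
motifConsensus <- function(pwm) {
  paste0(rownames(pwm@matrix)[apply(pwm@matrix, 2, which.max)], collapse = "")
}
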