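# Synthetic-data generator: a small multi-chromosome genome with gene
# models, non-overlapping peaks, NB-distributed counts following the
# lineage x condition x timepoint study design with planted peak-set
# effects, synthetic differential-expression tables, and motif instances
# planted into chosen peak sequences. Everything is deterministic under the
# config seed, with ground truth recorded alongside every emitted file.

#' Simulation configuration
#'
#' Defaults emulate the study design at desk scale: a 1 Mb genome over four
#' chromosomes; a B7.5 lineage sampled at 6, 10, 15, 18 and 20 hpf with a
#' mesenchyme outgroup; FGF-MAPK perturbations (FgfrDN, MekAct, MRasCA) and
#' Foxf CRISPR with controls; three replicates per cell; NB counts with
#' dispersion 0.1 and planted |log2FC| = 2 effects on disjoint truth peak
#' sets; a Fox-family motif planted into the FGF-MAPK-opened truth set.
#'
#' @param seed Integer seed driving all randomness.
#' @param nChromosomes,chromLength,gc Genome shape and GC content.
#' @param nGenes Number of gene models to place.
#' @param nPeaks Target number of accessome peaks.
#' @param peakWidthRange Raw peak width range in bp.
#' @param design data.frame (lineage, condition, timepoint, n_replicates);
#'   NULL for the packaged study design.
#' @param dispersion NB dispersion (`Var = mu + alpha mu^2`).
#' @param meanCountRange Per-peak base mean range (log-uniform).
#' @param libFactorRange Per-sample library scale range (log-uniform).
#' @param effectLfc Planted effect size in log2 units.
#' @param plantedFractions Named fractions of peaks per truth set
#'   (opened, closed, de_novo, lineage).
#' @param insertionRate Fraction of target peaks receiving a planted motif.
#' @param nDeGenesPerSet Planted genes per synthetic expression gene set.
#' @return A `simulation_config` list.
#' @export
simulationConfig <- function(seed = 0L, nChromosomes = 4L,
                             chromLength = 250000L, gc = 0.4,
                             nGenes = 120L, nPeaks = 1500L,
                             peakWidthRange = c(200L, 500L),
                             design = NULL, dispersion = 0.1,
                             meanCountRange = c(20, 300),
                             libFactorRange = c(0.6, 1.6),
                             effectLfc = 2,
                             plantedFractions = c(opened = 0.08,
                                                  closed = 0.05,
                                                  de_novo = 0.05,
                                                  lineage = 0.08),
                             insertionRate = 0.8,
                             nDeGenesPerSet = 25L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(c(meanCountRange, libFactorRange) <= 0))
    stop("count and library ranges must be positive")
  cfg <- list(seed = seed, nChromosomes = nChromosomes,
              chromLength = chromLength, gc = gc, nGenes = nGenes,
              nPeaks = nPeaks, peakWidthRange = peakWidthRange,
              design = design %||% studyDesign(), dispersion = dispersion,
              meanCountRange = meanCountRange,
              libFactorRange = libFactorRange, effectLfc = effectLfc,
              plantedFractions = plantedFractions,
              insertionRate = insertionRate,
              nDeGenesPerSet = nDeGenesPerSet)
  class(cfg) <- "simulation_config"
  cfg
}

#' The packaged study design
#'
#' @param nReplicates Replicates per (lineage, condition, timepoint) cell.
#' @return data.frame (lineage, condition, timepoint, n_replicates).
#' @export
studyDesign <- function(nReplicates = 3L) {
  rows <- rbind(
    data.frame(lineage = "B7.5", condition = "LacZ",
               timepoint = c(6, 10, 15, 18, 20)),
    data.frame(lineage = "mesenchyme", condition = "LacZ",
               timepoint = c(10, 18)),
    data.frame(lineage = "B7.5",
               condition = c("FgfrDN", "MekAct", "FoxfCRISPR",
                             "ControlCRISPR"), timepoint = 10),
    data.frame(lineage = "B7.5", condition = "FgfrDN",
               timepoint = c(15, 18, 20)),
    data.frame(lineage = "B7.5", condition = "MRasCA", timepoint = 18))
  rows$n_replicates <- nReplicates
  rows
}

randomSequence <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a genome with gene models
#'
#' I.i.d. background sequence at the configured GC content; gene models
#' (one transcript per gene, 2-4 exons, 5'/3' UTRs at the transcript ends,
#' CDS in between) placed left to right without overlap, alternating
#' random strand. Byte-identical outputs under a fixed seed.
#'
#' @param config A [simulationConfig()].
#' @return list(genome = named character of chromosome sequences,
#'   genomeSizes, geneModels).
#' @export
simulateGenomeAndGenes <- function(config) {
  withSeed(config$seed, {
    chroms <- paste0("chr", seq_len(config$nChromosomes))
    genome <- stats::setNames(
      vapply(chroms, function(ch) randomSequence(config$chromLength,
                                                 config$gc), character(1)),
      chroms)
    sizes <- stats::setNames(rep(config$chromLength, length(chroms)), chroms)
    si <- asSeqinfo(sizes)
    tx <- ex <- u5 <- u3 <- cds <- list()
    if (config$nGenes > 0) {
      perChrom <- rep(ceiling(config$nGenes / length(chroms)), length(chroms))
      made <- 0L
      for (ci in seq_along(chroms)) {
        cursor <- 2000L
        for (g in seq_len(perChrom[ci])) {
          if (made >= config$nGenes) break
          nEx <- sample(2:4, 1)
          exLen <- sample(200:600, nEx, replace = TRUE)
          inLen <- if (nEx > 1) sample(300:800, nEx - 1, replace = TRUE)
          else integer(0)
          span <- sum(exLen) + sum(inLen)
          gap <- sample(1500:6000, 1)
          startPos <- cursor + gap
          if (startPos + span > config$chromLength - 2000L) break
          made <- made + 1L
          gid <- sprintf("gene%03d", made)
          tid <- paste0(gid, ".t1")
          strand <- sample(c("+", "-"), 1)
          exStart <- startPos + cumsum(c(0L, utils::head(exLen, -1) + inLen))
          exEnd <- exStart + exLen - 1L
          txGr <- GRanges(chroms[ci], IRanges(startPos, startPos + span - 1L),
                          strand = strand, seqinfo = si)
          mcols(txGr)$tx_id <- tid
          mcols(txGr)$gene_id <- gid
          exGr <- GRanges(chroms[ci], IRanges(exStart, exEnd),
                          strand = strand, seqinfo = si)
          mcols(exGr)$tx_id <- tid
          # UTRs at the transcript's 5'/3' ends (strand-aware)
          u5len <- 150L; u3len <- 200L
          if (strand == "+") {
            u5Gr <- GRanges(chroms[ci], IRanges(exStart[1],
                                                exStart[1] + u5len - 1L),
                            strand = strand, seqinfo = si)
            u3Gr <- GRanges(chroms[ci], IRanges(exEnd[nEx] - u3len + 1L,
                                                exEnd[nEx]),
                            strand = strand, seqinfo = si)
          } else {
            u5Gr <- GRanges(chroms[ci], IRanges(exEnd[nEx] - u5len + 1L,
                                                exEnd[nEx]),
                            strand = strand, seqinfo = si)
            u3Gr <- GRanges(chroms[ci], IRanges(exStart[1],
                                                exStart[1] + u3len - 1L),
                            strand = strand, seqinfo = si)
          }
          mcols(u5Gr)$tx_id <- tid
          mcols(u3Gr)$tx_id <- tid
          cdsGr <- GenomicRanges::setdiff(exGr, c(granges(u5Gr),
                                                  granges(u3Gr)))
          strand(cdsGr) <- strand
          if (length(cdsGr)) mcols(cdsGr)$tx_id <- tid
          tx[[tid]] <- txGr; ex[[tid]] <- exGr
          u5[[tid]] <- u5Gr; u3[[tid]] <- u3Gr; cds[[tid]] <- cdsGr
          cursor <- startPos + span
        }
      }
    }
    cat0 <- function(lst) if (length(lst))
      suppressWarnings(do.call(c, unname(lst)))
    else GRanges(seqinfo = si)
    models <- if (length(tx)) GeneModels(cat0(tx), cat0(ex), cat0(cds),
                                         cat0(u5), cat0(u3))
    else new("GeneModels", transcripts = GRanges(seqinfo = si),
             exons = GRanges(seqinfo = si), cds = GRanges(seqinfo = si),
             utr5 = GRanges(seqinfo = si), utr3 = GRanges(seqinfo = si))
    list(genome = genome, genomeSizes = sizes, geneModels = models)
  })
}

#' Simulate raw peak calls and merge them into an accessome
#'
#' Candidate peaks are seeded at gene TSS/promoter neighborhoods (so
#' peak-to-gene association is well exercised) plus uniform intergenic
#' draws, split over two pseudo-replicate peak sets with jitter, then merged
#' through [mergeToAccessome()].
#'
#' @param config A [simulationConfig()].
#' @param sim Output of [simulateGenomeAndGenes()].
#' @return An [Accessome].
#' @export
simulateAccessomePeaks <- function(config, sim) {
  withSeed(config$seed + 1L, {
    sizes <- sim$genomeSizes
    tx <- sim$geneModels@transcripts
    centers <- integer(0); chrom <- character(0)
    if (length(tx)) {
      minus <- as.logical(strand(tx) == "-")
      tss <- ifelse(minus, end(tx), start(tx))
      for (off in c(0L, -1200L, 2500L)) {
        centers <- c(centers, tss + ifelse(minus, -off, off))
        chrom <- c(chrom, as.character(seqnames(tx)))
      }
    }
    nRand <- max(config$nPeaks - length(centers), 0L)
    randChrom <- sample(names(sizes), nRand, replace = TRUE)
    randPos <- vapply(randChrom, function(ch)
      sample.int(sizes[ch] - 1000L, 1) + 500L, integer(1))
    centers <- c(centers, randPos)
    chrom <- c(chrom, randChrom)
    wid <- sample(config$peakWidthRange[1]:config$peakWidthRange[2],
                  length(centers), replace = TRUE)
    start <- pmax(centers - wid %/% 2L, 1L)
    end <- pmin(start + wid - 1L, sizes[chrom])
    raw <- GRanges(chrom, IRanges(start, end))
    jit <- sample(-50:50, length(raw), replace = TRUE)
    rep2 <- GenomicRanges::shift(raw, jit)
    start(rep2) <- pmax(start(rep2), 1L)
    end(rep2) <- pmin(end(rep2), sizes[as.character(seqnames(rep2))])
    mergeToAccessome(list(raw, rep2), sizes)
  })
}

studyEffectRules <- function(effectLfc) {
  list(
    opened_FGF_MAPK_10 = list(
      lfc = effectLfc,
      applies = function(m) m$lineage == "B7.5" & m$timepoint >= 10 &
        m$condition != "FgfrDN"),
    closed_FGF_MAPK_10 = list(
      lfc = effectLfc,
      applies = function(m) m$lineage == "B7.5" & m$timepoint <= 10 &
        m$condition != "MekAct"),
    de_novo = list(
      lfc = effectLfc,
      applies = function(m) m$lineage == "B7.5" & m$timepoint >= 15),
    lineage_b75 = list(
      lfc = effectLfc,
      applies = function(m) m$lineage == "B7.5"))
}

#' Simulate NB counts under the study design with planted effects
#'
#' Counts are `NB(mean = base x libFactor x 2^effect, dispersion)`; planted
#' effects apply only in the conditions/timepoints each truth set names
#' (`Var = mu + alpha mu^2` parameterization, matching the differential
#' module's model). Truth-set memberships are disjoint and recorded in the
#' returned truth bundle.
#'
#' @param config A [simulationConfig()].
#' @param accessome An [Accessome].
#' @return list(counts, meta, truth) where truth holds the planted peak-set
#'   memberships and per-sample library factors.
#' @export
simulateCounts <- function(config, accessome) {
  n <- length(accessome)
  withSeed(config$seed + 2L, {
    des <- config$design
    meta <- do.call(rbind, lapply(seq_len(nrow(des)), function(i)
      data.frame(lineage = des$lineage[i], condition = des$condition[i],
                 timepoint = des$timepoint[i],
                 replicate = seq_len(des$n_replicates[i]))))
    meta$sample <- sprintf("%s_%s_%ghpf_r%d", meta$lineage, meta$condition,
                           meta$timepoint, meta$replicate)
    rownames(meta) <- meta$sample
    meta <- meta[, c("sample", "lineage", "condition", "timepoint",
                     "replicate")]
    fr <- config$plantedFractions
    sizes <- pmax(1L, round(n * fr))
    idx <- sample.int(n, sum(sizes))
    split <- stats::setNames(
      split(idx, rep(seq_along(sizes), sizes)), names(fr))
    truthSets <- list(
      opened_FGF_MAPK_10 = peakIds(accessome)[sort(split$opened)],
      closed_FGF_MAPK_10 = peakIds(accessome)[sort(split$closed)],
      de_novo = peakIds(accessome)[sort(split$de_novo)],
      lineage_b75 = peakIds(accessome)[sort(split$lineage)])
    # planted FGF-MAPK-opened elements persist through 18 hpf: primed
    truthSets$primed <- truthSets$opened_FGF_MAPK_10
    base <- exp(stats::runif(n, log(config$meanCountRange[1]),
                             log(config$meanCountRange[2])))
    libf <- exp(stats::runif(nrow(meta), log(config$libFactorRange[1]),
                             log(config$libFactorRange[2])))
    rules <- studyEffectRules(config$effectLfc)
    ruleSet <- list(opened_FGF_MAPK_10 = split$opened,
                    closed_FGF_MAPK_10 = split$closed,
                    de_novo = split$de_novo, lineage_b75 = split$lineage)
    lfcMat <- matrix(0, n, nrow(meta))
    for (nm in names(rules)) {
      on <- rules[[nm]]$applies(meta)
      lfcMat[ruleSet[[nm]], on] <- lfcMat[ruleSet[[nm]], on] +
        rules[[nm]]$lfc
    }
    mu <- outer(base, libf) * 2^lfcMat
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$dispersion),
                     n, nrow(meta),
                     dimnames = list(peakIds(accessome), meta$sample))
    storage.mode(counts) <- "integer"
    list(counts = counts, meta = meta,
         truth = list(peak_sets = truthSets, lib_factors = libf,
                      base_means = base))
  })
}

#' Simulate differential-expression tables with planted gene sets
#'
#' Emits the comparisons consumed by [defineExpressionGeneSets()] and the
#' primed/de novo classification, with planted genes given strong fold
#' changes and near-zero p-values in the comparisons their set definition
#' names; all other genes get null statistics. Gene-set truth is returned.
#'
#' @param config A [simulationConfig()].
#' @param genes Character vector of gene ids.
#' @return list(tables = named list of DE data.frames,
#'   gene_sets = named list of planted gene id vectors).
#' @export
simulateDeTables <- function(config, genes) {
  withSeed(config$seed + 3L, {
    nset <- min(config$nDeGenesPerSet,
                max(1L, length(genes) %/% 8L))
    setNames <- c("foxf_targets", "mapk_activated_18", "mapk_inhibited_18",
                  "mapk_activated_10", "mapk_inhibited_10",
                  "de_novo_cardiac", "de_novo_asm")
    pick <- sample(genes, min(length(genes), nset * length(setNames)))
    planted <- split(pick, rep(seq_along(setNames),
                               length.out = length(pick)))
    names(planted) <- setNames
    comparisons <- c("FoxfCRISPR_vs_ControlCRISPR", "MRasCA_vs_LacZ@18",
                     "FgfrDN_vs_LacZ@18", "MRasCA_vs_FgfrDN@18",
                     "FgfrDN_vs_LacZ@10")
    nullTab <- function() data.frame(
      gene_id = genes, log2fc = stats::rnorm(length(genes), 0, 0.3),
      p_value = stats::runif(length(genes)), stringsAsFactors = FALSE)
    tabs <- stats::setNames(lapply(comparisons, function(x) nullTab()),
                            comparisons)
    plant <- function(tab, ids, lfc) {
      i <- match(ids, tab$gene_id)
      tab$log2fc[i] <- lfc + stats::rnorm(length(i), 0, 0.1)
      tab$p_value[i] <- 1e-8
      tab
    }
    tabs$FoxfCRISPR_vs_ControlCRISPR <-
      plant(tabs$FoxfCRISPR_vs_ControlCRISPR, planted$foxf_targets, -2)
    tabs$`MRasCA_vs_LacZ@18` <-
      plant(tabs$`MRasCA_vs_LacZ@18`, planted$mapk_inhibited_18, -2)
    tabs$`MRasCA_vs_FgfrDN@18` <-
      plant(tabs$`MRasCA_vs_FgfrDN@18`, planted$mapk_inhibited_18, -2)
    tabs$`FgfrDN_vs_LacZ@18` <-
      plant(tabs$`FgfrDN_vs_LacZ@18`, planted$mapk_activated_18, -2)
    tabs$`MRasCA_vs_FgfrDN@18` <-
      plant(tabs$`MRasCA_vs_FgfrDN@18`, planted$mapk_activated_18, 2)
    tabs$`FgfrDN_vs_LacZ@10` <-
      plant(tabs$`FgfrDN_vs_LacZ@10`, planted$mapk_activated_10, -2)
    tabs$`FgfrDN_vs_LacZ@10` <-
      plant(tabs$`FgfrDN_vs_LacZ@10`, planted$mapk_inhibited_10, 2)
    tabs <- lapply(tabs, function(t) {
      t$fdr <- stats::p.adjust(t$p_value, method = "BH")
      t
    })
    geneSets <- planted
    geneSets$cardiac <- planted$de_novo_cardiac
    geneSets$asm <- planted$de_novo_asm
    list(tables = tabs, gene_sets = geneSets)
  })
}

#' A small synthetic motif catalog
#'
#' Strongly informative PWMs built from count matrices around consensus
#' sites typical of the TF families discussed in cardiopharyngeal biology
#' (Fox, GATA, Ets, bHLH, T-box, homeodomain). Purely synthetic constructs
#' for simulation and testing; not derived from any measured motif database.
#'
#' @param pseudocount Pseudocount for [pwmFromCounts()].
#' @return Named list of [PWMotif]s.
#' @export
syntheticMotifCatalog <- function(pseudocount = 0.8) {
  fromConsensus <- function(id, consensus, strength = 40L) {
    L <- nchar(consensus)
    counts <- matrix(2L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    b <- strsplit(consensus, "")[[1]]
    for (j in seq_len(L)) counts[b[j], j] <- strength
    pwmFromCounts(counts, id = id, pseudocount = pseudocount)
  }
  list(
    FOX_synth = fromConsensus("FOX_synth", "TGTAAACA"),
    GATA_synth = fromConsensus("GATA_synth", "AGATAAGA"),
    ETS_synth = fromConsensus("ETS_synth", "ACAGGAAGT"),
    BHLH_synth = fromConsensus("BHLH_synth", "AACAGCTGTT"),
    TBX_synth = fromConsensus("TBX_synth", "AGGTGTGA"),
    HOMEO_synth = fromConsensus("HOMEO_synth", "CTAATTAG"))
}

#' Plant motif instances into chromosome sequences at chosen peaks
#'
#' For each selected target peak a site is sampled from the PWM (each
#' position drawn from its base distribution), reverse-complemented half the
#' time, and spliced into the genome at a random offset inside the peak.
#' Returns the modified genome and a registry of (peak, position, strand).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param accessome An [Accessome].
#' @param pwm A [PWMotif].
#' @param targetPeaks Peak ids to consider.
#' @param insertionRate Probability each target receives an insertion.
#' @param seed RNG seed.
#' @return list(genome, registry).
#' @export
plantMotifs <- function(genome, accessome, pwm, targetPeaks,
                        insertionRate = 1, seed = 0L) {
  L <- length(pwm)
  ids <- peakIds(accessome)
  withSeed(seed, {
    rows <- list()
    for (pk in targetPeaks) {
      i <- match(pk, ids)
      if (is.na(i)) stop("target peak '", pk, "' not in accessome")
      if (stats::runif(1) > insertionRate) next
      wid <- width(accessome)[i]
      if (L > wid) {
        warning("motif longer than peak '", pk, "': skipped")
        next
      }
      site <- paste(vapply(seq_len(L), function(j)
        sample(rownames(pwm@matrix), 1, prob = pwm@matrix[, j]),
        character(1)), collapse = "")
      strand <- sample(c("+", "-"), 1)
      if (strand == "-")
        site <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(site)))
      off <- sample.int(wid - L + 1L, 1)        # 1-based offset in peak
      ch <- as.character(seqnames(accessome))[i]
      absStart <- start(accessome)[i] + off - 1L
      substr(genome[[ch]], absStart, absStart + L - 1L) <- site
      rows[[length(rows) + 1L]] <- data.frame(
        peak = pk, position = off, strand = strand, motif = pwm@id,
        stringsAsFactors = FALSE)
    }
    registry <- if (length(rows)) do.call(rbind, rows)
    else data.frame(peak = character(), position = integer(),
                    strand = character(), motif = character(),
                    stringsAsFactors = FALSE)
    list(genome = genome, registry = registry)
  })
}

#' Extract peak sequences from a genome
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param accessome An [Accessome] (or `GRanges` with peak_id).
#' @return Named character vector of peak sequences.
#' @export
peakSequences <- function(genome, accessome) {
  if (is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  ch <- as.character(seqnames(accessome))
  out <- substring(genome[ch], start(accessome), end(accessome))
  names(out) <- mcols(accessome)$peak_id
  out
}

#' Generate a complete fixture bundle on disk
#'
#' Runs the whole generator and writes: `genome.fa`, `genes.gff3`,
#' `chrom.sizes`, `peaks.bed`, `counts.tsv`, `samples.tsv`,
#' `de_tables/<comparison>.tsv`, `motifs.meme` and `truth.json`. The Fox
#' motif of the synthetic catalog is planted into the FGF-MAPK-opened truth
#' peaks before the genome is written, so re-extracted peak sequences carry
#' the planted sites. All outputs are byte-stable under the config seed.
#'
#' @param config A [simulationConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
makeFixtures <- function(config = simulationConfig(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenomeAndGenes(config)
  acc <- simulateAccessomePeaks(config, sim)
  cnt <- simulateCounts(config, acc)
  de <- simulateDeTables(config, geneIds(sim$geneModels))
  motifs <- syntheticMotifCatalog()
  planted <- plantMotifs(sim$genome, acc, motifs$FOX_synth,
                         cnt$truth$peak_sets$opened_FGF_MAPK_10,
                         insertionRate = config$insertionRate,
                         seed = config$seed + 4L)
  genome <- planted$genome
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    peaks = file.path(outdir, "peaks.bed"),
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    de_dir = file.path(outdir, "de_tables"),
    motifs = file.path(outdir, "motifs.meme"),
    truth = file.path(outdir, "truth.json"))
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, paths$genome, width = 80L)
  writeGff3GeneModels(sim$geneModels, paths$gff3)
  writeChromSizes(sim$genomeSizes, paths$chrom_sizes)
  writeBed(acc, paths$peaks)
  writeCountsTsv(cnt$counts, paths$counts)
  writeTsv(cnt$meta, paths$samples)
  dir.create(paths$de_dir, showWarnings = FALSE)
  for (nm in names(de$tables))
    writeTsv(de$tables[[nm]],
             file.path(paths$de_dir, paste0(gsub("@", "_at_", nm), ".tsv")))
  writeMeme(motifs, paths$motifs)
  truth <- list(seed = config$seed, peak_sets = cnt$truth$peak_sets,
                gene_sets = de$gene_sets,
                motif_registry = planted$registry,
                planted_motif = "FOX_synth",
                effect_lfc = config$effectLfc,
                dispersion = config$dispersion)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, genome = genome, accessome = acc,
                 geneModels = sim$geneModels, counts = cnt$counts,
                 meta = cnt$meta, deTables = de$tables, truth = truth,
                 motifs = motifs, paths = paths))
}
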