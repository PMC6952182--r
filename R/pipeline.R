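# Pipeline orchestration: run the analysis stages in the order the study's
# methods prescribe (accessome -> annotation -> differential accessibility ->
# set algebra -> GSEA / motifs / deviations) from a single config, writing
# per-stage tabular reports and a provenance manifest. Stage outputs are
# write-once: no stage mutates an upstream file.

#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: peak length > 50 bp,
#' TSS half-width 107 bp, 1 kb promoter, 200 bp TTS half-width, 10 kb
#' association window, 500,000-read library filter, |log2FC| > 0.5 with
#' FDR < 0.05 for peak sets, GSEA minSize 5 with 10,000 permutations, PWM
#' match cutoff p < 5e-5, 50 background iterations with FDR < 0.01 for
#' differential deviations.
#'
#' @param fixtureDir Directory holding the input bundle (as written by
#'   [makeFixtures()]).
#' @param seed Seed for all stochastic stages.
#' @return A nested list; override any entry before passing to
#'   [runPipeline()].
#' @export
defaultPipelineConfig <- function(fixtureDir = NULL, seed = 0L) {
  list(
    seed = seed,
    inputs = list(dir = fixtureDir),
    stages = list(accessome = TRUE, annotate = TRUE, da = TRUE, sets = TRUE,
                  gsea = TRUE, motifs = TRUE, deviations = TRUE),
    thresholds = list(
      min_peak_length = 51, tss_halfwidth = 107, promoter_length = 1000,
      tts_halfwidth = 200, assoc_window = 10000, min_reads = 5e5,
      lfc = 0.5, fdr = 0.05, gsea_nperm = 10000, gsea_min_size = 5,
      pwm_p_cutoff = 5e-5, dev_iterations = 50, dev_bins = 10,
      dev_fdr = 0.01))
}

#' Pipeline configuration scaled to the packaged synthetic fixtures
#'
#' Identical to [defaultPipelineConfig()] except the library filter, which is
#' scaled to the fixture sequencing depth (10,000 fragments; the fixture
#' genome is ~1 Mb, three orders of magnitude below a real genome, and
#' library totals scale accordingly).
#'
#' @inheritParams defaultPipelineConfig
#' @export
fixturePipelineConfig <- function(fixtureDir, seed = 0L) {
  cfg <- defaultPipelineConfig(fixtureDir, seed)
  cfg$thresholds$min_reads <- 1e4
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  mergeIn <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeIn(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  mergeIn(cfg, user)
}

pipeLog <- function(...) message(sprintf("[accessome] %s", sprintf(...)))

#' Run the full analysis pipeline
#'
#' Executes every enabled stage on the input bundle, writing stage reports
#' under `outdir` and a `manifest.json` recording the package version, the
#' thresholds actually applied, the seed, and md5 checksums of all inputs
#' and outputs. Disabled stages whose outputs a later stage needs produce a
#' dependency error naming the stage. Reruns with the same config and seed
#' are reproducible checksum-for-checksum.
#'
#' @param config Config list from [defaultPipelineConfig()] /
#'   [fixturePipelineConfig()] / [readPipelineConfig()], or a YAML path.
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  stages <- config$stages
  indir <- config$inputs$dir
  if (is.null(indir) || !dir.exists(indir))
    stop("config$inputs$dir must point at an input bundle directory")
  inFile <- function(nm) file.path(indir, nm)
  outputs <- character()
  emit <- function(df, nm) {
    path <- file.path(outdir, nm)
    if (file.exists(path))
      stop("write-once violation: '", nm, "' already exists in outdir")
    writeTsv(df, path)
    outputs <<- c(outputs, path)
    path
  }
  need <- function(obj, stage, neededBy) {
    if (is.null(obj))
      stop("stage '", neededBy, "' needs outputs of disabled stage '",
           stage, "'")
    obj
  }

  sizes <- readChromSizes(inFile("chrom.sizes"))
  acc <- annot <- map <- da <- sets <- geneSets <- NULL

  if (isTRUE(stages$accessome)) {
    pipeLog("accessome: merging peaks (min length %d bp)",
            as.integer(thr$min_peak_length))
    raw <- readBed(inFile("peaks.bed"), sizes)
    acc <- mergeToAccessome(raw, sizes, minLength = thr$min_peak_length)
    writeBed(acc, file.path(outdir, "accessome.bed"))
    outputs <- c(outputs, file.path(outdir, "accessome.bed"))
    emit(data.frame(metric = c("n_peaks", "genome_coverage_fraction"),
                    value = c(length(acc), genomeCoverageFraction(acc))),
         "accessome_stats.tsv")
  }

  models <- readGff3GeneModels(inFile("genes.gff3"), sizes)

  if (isTRUE(stages$annotate)) {
    need(acc, "accessome", "annotate")
    pipeLog("annotate: feature windows and peak-gene association")
    fm <- buildFeatureMap(models, tssHalfwidth = thr$tss_halfwidth,
                          promoterLength = thr$promoter_length,
                          ttsHalfwidth = thr$tts_halfwidth)
    annot <- classifyPeaks(acc, fm)
    emit(annot, "annotation.tsv")
    emit(featureEnrichment(acc, fm), "feature_enrichment.tsv")
    map <- associatePeaksToGenes(acc, models, window = thr$assoc_window)
    emit(map, "peak_gene_map.tsv")
    smry <- peakGeneSummary(map)
    emit(data.frame(metric = names(smry), value = unlist(smry)),
         "peak_gene_summary.tsv")
  }

  if (isTRUE(stages$da)) {
    need(acc, "accessome", "da")
    pipeLog("da: NB LRT models (library filter %g reads)", thr$min_reads)
    counts <- readCountsTsv(inFile("counts.tsv"))
    meta <- readSampleMeta(inFile("samples.tsv"))
    se <- peakCountExperiment(counts, meta, acc)
    se <- filterLibraries(se, minReads = thr$min_reads)
    da <- runDifferentialModels(se)
    for (nm in names(da))
      emit(da[[nm]], sprintf("da_%s.tsv", gsub("@", "_at_", nm)))
    qc <- sampleCorrelation(se)
    emit(data.frame(sample = rownames(qc), qc, check.names = FALSE),
         "sample_correlation.tsv")
  }

  deDir <- inFile("de_tables")
  deTables <- NULL
  if (dir.exists(deDir)) {
    files <- list.files(deDir, pattern = "\\.tsv$", full.names = TRUE)
    deTables <- stats::setNames(
      lapply(files, readDiffTable),
      gsub("_at_", "@", sub("\\.tsv$", "", basename(files))))
  }

  if (isTRUE(stages$sets)) {
    need(da, "da", "sets")
    pipeLog("sets: accessibility and expression set algebra")
    sets <- defineAccessibilitySets(da, lfcThreshold = thr$lfc,
                                    fdrThreshold = thr$fdr)
    writeSetsTsv(sets, file.path(outdir, "peak_sets.tsv"))
    outputs <- c(outputs, file.path(outdir, "peak_sets.tsv"))
    if (!is.null(deTables)) {
      geneSets <- suppressWarnings(defineExpressionGeneSets(deTables))
      writeSetsTsv(geneSets, file.path(outdir, "gene_sets.tsv"))
      outputs <- c(outputs, file.path(outdir, "gene_sets.tsv"))
    }
    core <- sets[c("opened_FGF_MAPK_10", "closed_FGF_MAPK_10", "primed",
                   "de_novo")]
    core <- Filter(function(s) length(memberIds(s)) > 0, core)
    if (length(core) >= 2)
      emit(intersectionIndependenceTest(core, acc),
           "set_intersections.tsv")
  }

  if (isTRUE(stages$gsea)) {
    need(da, "da", "gsea")
    need(map, "annotate", "gsea")
    pipeLog("gsea: peak-level GSEA (%d permutations)",
            as.integer(thr$gsea_nperm))
    ranks <- da[["t6_vs_t10"]]
    stats <- stats::setNames(ranks$log2fc, ranks$peak_id)
    stats <- stats[is.finite(stats)]
    gs <- if (!is.null(geneSets)) geneSets
    else need(NULL, "sets", "gsea")
    peakLift <- lapply(gs, peaksForGeneSet, peakGeneMap = map)
    res <- runGsea(stats, peakLift, nPerm = thr$gsea_nperm,
                   minSize = thr$gsea_min_size, seed = config$seed)
    emit(res, "gsea.tsv")
  }

  hits <- NULL
  if (isTRUE(stages$motifs) || isTRUE(stages$deviations)) {
    need(acc, "accessome", "motifs/deviations")
    genome <- Biostrings::readDNAStringSet(inFile("genome.fa"))
    names(genome) <- sub("\\s.*", "", names(genome))
    pwms <- readMeme(inFile("motifs.meme"))
    seqs <- peakSequences(genome, acc)
    pipeLog("motifs: scanning %d peaks x %d PWMs (p < %g)", length(seqs),
            length(pwms), thr$pwm_p_cutoff)
    hits <- scanSequences(seqs, pwms, pCutoff = thr$pwm_p_cutoff)
  }

  if (isTRUE(stages$motifs)) {
    need(sets, "sets", "motifs")
    hitsLong <- motifHits(hits)
    emit(hitsLong, "motif_hits.tsv")
    enr <- motifEnrichment(hits, sets$opened_FGF_MAPK_10)
    enr <- enr[order(-enr$log2_or), ]
    emit(enr, "motif_enrichment_opened_FGF_MAPK_10.tsv")
  }

  if (isTRUE(stages$deviations)) {
    need(da, "da", "deviations")
    pipeLog("deviations: chromVAR-style Z-scores (%d iterations)",
            as.integer(thr$dev_iterations))
    counts <- readCountsTsv(inFile("counts.tsv"))
    meta <- readSampleMeta(inFile("samples.tsv"))
    keepSamp <- meta$timepoint %in% c(6, 10) & meta$lineage == "B7.5"
    counts10 <- counts[, keepSamp, drop = FALSE]
    meta10 <- meta[keepSamp, , drop = FALSE]
    # deviations over the FGF-MAPK-dependent preselection (10 hpf model
    # FDR < 0.05), falling back to all peaks when the selection is tiny
    daPeaks <- unique(unlist(lapply(
      da[grep("@10$", names(da))],
      function(t) t$peak_id[!is.na(t$fdr) & t$fdr < thr$fdr])))
    if (length(daPeaks) < 50) daPeaks <- peakIds(acc)
    sel <- peakIds(acc) %in% daPeaks
    resized <- resizePeaks(acc[sel], width = 200)
    genome <- Biostrings::readDNAStringSet(inFile("genome.fa"))
    names(genome) <- sub("\\s.*", "", names(genome))
    devSeqs <- peakSequences(genome, resized)
    pwms <- readMeme(inFile("motifs.meme"))
    devHits <- scanSequences(devSeqs, pwms, pCutoff = thr$pwm_p_cutoff)
    bg <- sampleBackgroundSets(counts10[sel, , drop = FALSE], devSeqs,
                               nIterations = thr$dev_iterations,
                               nBins = thr$dev_bins, seed = config$seed)
    devs <- deviationZscores(counts10[sel, , drop = FALSE], devHits, bg)
    z <- deviationZ(devs)
    emit(data.frame(motif = rownames(z), z, check.names = FALSE),
         "deviations_z.tsv")
    groups <- interaction(meta10$condition, meta10$timepoint, drop = TRUE)
    dd <- differentialDeviations(devs, groups, fdrThreshold = thr$dev_fdr)
    emit(dd, "differential_deviations.tsv")
  }

  inputFiles <- list.files(indir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "accessome",
    version = as.character(utils::packageVersion("accessome")),
    seed = config$seed,
    thresholds = thr,
    stages = stages,
    inputs = as.list(tools::md5sum(inputFiles)),
    outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeLog("done: %d stage reports in %s", length(outputs), outdir)
  invisible(manifest)
}
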