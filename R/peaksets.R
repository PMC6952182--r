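# Peak-set and gene-set algebra: threshold-based set construction from
# differential tables, primed / de novo element classification, the
# intersection-independence binomial test, and overlap summaries.
#
# All printed thresholds are strict inequalities (|log2FC| > 0.5 means a peak
# at exactly -0.5 is excluded). "Associated with" always means membership in
# the peak-to-gene map built with the +/-10 kb rule -- one association
# dialect shared by every module.

thresholdMembers <- function(tab, lfcSign, lfc, fdr = NULL, p = NULL,
                             idCol = NULL) {
  if (is.null(idCol))
    idCol <- intersect(c("peak_id", "gene_id", "id"), names(tab))[1]
  if (is.na(idCol)) stop("differential table lacks an id column")
  sel <- if (lfcSign > 0) tab$log2fc > lfc else tab$log2fc < -lfc
  if (!is.null(fdr)) sel <- sel & tab$fdr < fdr
  if (!is.null(p)) {
    pcol <- if ("p_value" %in% names(tab)) tab$p_value else tab$p
    sel <- sel & pcol < p
  }
  tab[[idCol]][which(sel)]
}

getTable <- function(tables, name) {
  if (!name %in% names(tables))
    stop("missing differential table for contrast '", name, "'")
  tables[[name]]
}

#' Define the six cell-type-specific accessibility peak sets
#'
#' Implements the study's six named definitions over the differential
#' accessibility contrasts, with strict thresholds (`|log2fc| > lfcThreshold`,
#' `fdr < fdrThreshold`):
#' \describe{
#'   \item{opened_FGF_MAPK_10}{union of peaks closed in FgfrDN vs control
#'     (log2fc < -0.5) and peaks open in MekAct vs FgfrDN (log2fc > 0.5), in
#'     the 10 hpf model.}
#'   \item{closed_FGF_MAPK_10}{union of peaks closed in MekAct vs control and
#'     closed in MekAct vs FgfrDN.}
#'   \item{opened_FGF_MAPK_18}{union of peaks closed in FgfrDN vs control,
#'     open in MRasCA vs control and open in MRasCA vs FgfrDN, in the
#'     15-20 hpf model.}
#'   \item{closed_FGF_MAPK_18}{the mirrored union.}
#'   \item{de_novo}{peaks closed in control 10 vs 18 hpf (time model) that
#'     are not opened by FGF-MAPK at 10 hpf.}
#'   \item{primed}{peaks opened by FGF-MAPK at 10 hpf that are not closed in
#'     control 10 vs 18 hpf.}
#' }
#' `primed` and `de_novo` are disjoint by construction.
#'
#' @param daTables Named list of DA tables; required keys:
#'   `FgfrDN_vs_LacZ@10`, `MekAct_vs_LacZ@10`, `MekAct_vs_FgfrDN@10`,
#'   `FgfrDN_vs_LacZ@18`, `MRasCA_vs_LacZ@18`, `MRasCA_vs_FgfrDN@18`,
#'   `t10_vs_t18`.
#' @param lfcThreshold,fdrThreshold Strict thresholds (defaults 0.5, 0.05).
#' @return Named list of six [PeakSet]s.
#' @export
defineAccessibilitySets <- function(daTables, lfcThreshold = 0.5,
                                    fdrThreshold = 0.05) {
  thr <- function(contrast, sign)
    thresholdMembers(getTable(daTables, contrast), sign, lfcThreshold,
                     fdr = fdrThreshold)
  prov <- function(...) sprintf("%s at |log2fc|>%g, fdr<%g",
                                paste(..., collapse = " "), lfcThreshold,
                                fdrThreshold)
  opened10 <- union(thr("FgfrDN_vs_LacZ@10", -1), thr("MekAct_vs_FgfrDN@10", 1))
  closed10 <- union(thr("MekAct_vs_LacZ@10", -1), thr("MekAct_vs_FgfrDN@10", -1))
  opened18 <- Reduce(union, list(thr("FgfrDN_vs_LacZ@18", -1),
                                 thr("MRasCA_vs_LacZ@18", 1),
                                 thr("MRasCA_vs_FgfrDN@18", 1)))
  closed18 <- Reduce(union, list(thr("FgfrDN_vs_LacZ@18", 1),
                                 thr("MRasCA_vs_LacZ@18", -1),
                                 thr("MRasCA_vs_FgfrDN@18", -1)))
  closing10v18 <- thr("t10_vs_t18", -1)  # less accessible at 10 than 18
  list(
    opened_FGF_MAPK_10 = PeakSet("opened_FGF_MAPK_10", opened10,
      prov("down(FgfrDN_vs_LacZ@10) | up(MekAct_vs_FgfrDN@10)")),
    closed_FGF_MAPK_10 = PeakSet("closed_FGF_MAPK_10", closed10,
      prov("down(MekAct_vs_LacZ@10) | down(MekAct_vs_FgfrDN@10)")),
    opened_FGF_MAPK_18 = PeakSet("opened_FGF_MAPK_18", opened18,
      prov("down(FgfrDN_vs_LacZ@18) | up(MRasCA_vs_LacZ@18) | up(MRasCA_vs_FgfrDN@18)")),
    closed_FGF_MAPK_18 = PeakSet("closed_FGF_MAPK_18", closed18,
      prov("up(FgfrDN_vs_LacZ@18) | down(MRasCA_vs_LacZ@18) | down(MRasCA_vs_FgfrDN@18)")),
    de_novo = PeakSet("de_novo", setdiff(closing10v18, opened10),
      prov("down(t10_vs_t18) minus opened_FGF_MAPK_10")),
    primed = PeakSet("primed", setdiff(opened10, closing10v18),
      prov("opened_FGF_MAPK_10 minus down(t10_vs_t18)")))
}

#' Define cell-type-specific expression gene sets
#'
#' The study's threshold rules over differential-expression tables:
#' \describe{
#'   \item{foxf_targets}{log2fc < -0.75 and FDR < 0.05 in Foxf CRISPR vs
#'     control CRISPR.}
#'   \item{mapk_inhibited_18}{down in MRasCA vs control AND down in MRasCA vs
#'     FgfrDN, both at log2fc < -1, FDR < 0.05.}
#'   \item{mapk_activated_18}{down in FgfrDN vs control AND up in MRasCA vs
#'     FgfrDN at |log2fc| > 1, FDR < 0.05.}
#'   \item{mapk_activated_10 / mapk_inhibited_10}{microarray-based: down
#'     (resp. up) in FgfrDN vs control at |log2fc| > 1 and unadjusted
#'     p < 0.05.}
#' }
#' Required table keys: `FoxfCRISPR_vs_ControlCRISPR`, `MRasCA_vs_LacZ@18`,
#' `FgfrDN_vs_LacZ@18`, `MRasCA_vs_FgfrDN@18`, `FgfrDN_vs_LacZ@10`.
#'
#' @param deTables Named list of DE tables (columns gene_id, log2fc, and
#'   fdr and/or p_value).
#' @return Named list of [GeneSet]s (possibly empty sets, with a warning).
#' @export
defineExpressionGeneSets <- function(deTables) {
  thr <- function(contrast, sign, lfc, fdr = NULL, p = NULL)
    thresholdMembers(getTable(deTables, contrast), sign, lfc, fdr = fdr,
                     p = p)
  sets <- list(
    foxf_targets = GeneSet("foxf_targets",
      thr("FoxfCRISPR_vs_ControlCRISPR", -1, 0.75, fdr = 0.05),
      "log2fc < -0.75 & fdr < 0.05 in FoxfCRISPR_vs_ControlCRISPR"),
    mapk_inhibited_18 = GeneSet("mapk_inhibited_18",
      intersect(thr("MRasCA_vs_LacZ@18", -1, 1, fdr = 0.05),
                thr("MRasCA_vs_FgfrDN@18", -1, 1, fdr = 0.05)),
      "down(MRasCA_vs_LacZ@18) & down(MRasCA_vs_FgfrDN@18) at |log2fc|>1, fdr<0.05"),
    mapk_activated_18 = GeneSet("mapk_activated_18",
      intersect(thr("FgfrDN_vs_LacZ@18", -1, 1, fdr = 0.05),
                thr("MRasCA_vs_FgfrDN@18", 1, 1, fdr = 0.05)),
      "down(FgfrDN_vs_LacZ@18) & up(MRasCA_vs_FgfrDN@18) at |log2fc|>1, fdr<0.05"),
    mapk_activated_10 = GeneSet("mapk_activated_10",
      thr("FgfrDN_vs_LacZ@10", -1, 1, p = 0.05),
      "log2fc < -1 & p < 0.05 in FgfrDN_vs_LacZ@10 (microarray)"),
    mapk_inhibited_10 = GeneSet("mapk_inhibited_10",
      thr("FgfrDN_vs_LacZ@10", 1, 1, p = 0.05),
      "log2fc > 1 & p < 0.05 in FgfrDN_vs_LacZ@10 (microarray)"))
  if (any(!vapply(sets, length, integer(1))))
    warning("empty gene set(s): ",
            paste(names(sets)[!vapply(sets, length, integer(1))],
                  collapse = ", "))
  sets
}

#' Evaluate a threshold-rule specification into a set
#'
#' A small grammar, YAML-friendly, for user-defined sets: a rule is a list
#' with `comparison`, `sign` (`"up"`/`"down"`), `lfc`, and `fdr` or `p`;
#' rules combine via `list(combine = "union"|"intersect"|"minus",
#' rules = list(...))` nested to any depth (for `minus`, the second and later
#' operands are subtracted from the first).
#'
#' @param spec A rule or combination list (e.g. parsed from YAML).
#' @param tables Named list of differential tables.
#' @param name,kind Name and kind (`"peak"`/`"gene"`) of the resulting set.
#' @return A [PeakSet] or [GeneSet].
#' @export
thresholdSet <- function(spec, tables, name = "custom",
                         kind = c("gene", "peak")) {
  kind <- match.arg(kind)
  evalSpec <- function(s) {
    if (!is.null(s$combine)) {
      parts <- lapply(s$rules, evalSpec)
      op <- switch(s$combine, union = union, intersect = intersect,
                   minus = setdiff,
                   stop("unknown combine '", s$combine, "'"))
      return(Reduce(op, parts))
    }
    sign <- switch(s$sign, up = 1, down = -1,
                   stop("rule sign must be 'up' or 'down'"))
    thresholdMembers(getTable(tables, s$comparison), sign, s$lfc,
                     fdr = s$fdr, p = s$p)
  }
  ctor <- if (kind == "peak") PeakSet else GeneSet
  ctor(name, evalSpec(spec),
       provenance = as.character(jsonlite::toJSON(spec, auto_unbox = TRUE)))
}

#' Classify primed / de novo elements as cardiac- or ASM-accessible
#'
#' Takes the primed and de novo peak sets, keeps elements associated with
#' de novo cardiac (resp. pharyngeal muscle, ASM) genes, requires directional
#' consistency of the 18 hpf contrasts (cardiac: log2fc < 0 in MRasCA vs
#' control OR > 0 in FgfrDN vs control; ASM: the mirror, both strict), and
#' then removes elements whose accessibility could reflect an earlier
#' program: ASM elements also associated with a cardiac or MAPK-inhibited-18
#' gene are dropped, cardiac elements also associated with an ASM or
#' MAPK-activated-18 gene are dropped.
#'
#' @param peakGeneMap Output of [associatePeaksToGenes()].
#' @param daTables DA tables including `MRasCA_vs_LacZ@18` and
#'   `FgfrDN_vs_LacZ@18`.
#' @param geneSets Named list of [GeneSet]s with members
#'   `de_novo_cardiac`, `de_novo_asm`, `cardiac`, `asm`,
#'   `mapk_inhibited_18`, `mapk_activated_18`.
#' @param primed,deNovo The primed and de novo [PeakSet]s.
#' @return Named list of four [PeakSet]s: `primed_cardiac`, `de_novo_cardiac`,
#'   `primed_asm`, `de_novo_asm`.
#' @export
classifyPrimedDenovoElements <- function(peakGeneMap, daTables, geneSets,
                                         primed, deNovo) {
  need <- c("de_novo_cardiac", "de_novo_asm", "cardiac", "asm",
            "mapk_inhibited_18", "mapk_activated_18")
  miss <- setdiff(need, names(geneSets))
  if (length(miss))
    stop("missing prerequisite gene set(s): ", paste(miss, collapse = ", "))
  mras <- getTable(daTables, "MRasCA_vs_LacZ@18")
  fgfr <- getTable(daTables, "FgfrDN_vs_LacZ@18")
  lfcOf <- function(tab) stats::setNames(tab$log2fc, tab$peak_id)
  lm <- lfcOf(mras); lf <- lfcOf(fgfr)
  dirOk <- function(ids, class) {
    a <- lm[ids]; b <- lf[ids]
    keep <- if (class == "cardiac") (!is.na(a) & a < 0) | (!is.na(b) & b > 0)
    else (!is.na(a) & a > 0) | (!is.na(b) & b < 0)
    ids[which(keep)]
  }
  peaksOf <- function(genes)
    unique(peakGeneMap$peak_id[peakGeneMap$gene_id %in% genes])
  build <- function(elements, class, label) {
    assoc <- intersect(memberIds(elements),
                       peaksOf(memberIds(geneSets[[paste0("de_novo_", class)]])))
    kept <- dirOk(assoc, class)
    conflict <- if (class == "asm")
      union(peaksOf(memberIds(geneSets$cardiac)),
            peaksOf(memberIds(geneSets$mapk_inhibited_18)))
    else
      union(peaksOf(memberIds(geneSets$asm)),
            peaksOf(memberIds(geneSets$mapk_activated_18)))
    PeakSet(label, setdiff(kept, conflict),
            sprintf("%s elements assoc. de novo %s genes, 18 hpf direction rule, conflicting associations removed",
                    setName(elements), class))
  }
  list(primed_cardiac = build(primed, "cardiac", "primed_cardiac"),
       de_novo_cardiac = build(deNovo, "cardiac", "de_novo_cardiac"),
       primed_asm = build(primed, "asm", "primed_asm"),
       de_novo_asm = build(deNovo, "asm", "de_novo_asm"))
}

#' Intersection-independence binomial test
#'
#' For each requested intersection pattern, the null probability is the
#' product of the constituent sets' relative sizes (`p0 = prod |S_i| / |U|`),
#' the observation is `k = |intersection|` out of `n = |U|` universe
#' elements, and the p-value is the exact two-tailed minimum-likelihood
#' binomial test ([binomialEnrichment()]). A pattern over a single set always
#' yields p = 1.
#'
#' @param sets Named list of [PeakSet]s (or [GeneSet]s).
#' @param universe Character vector of universe ids, or an [Accessome].
#' @param patterns List of character vectors naming the sets in each
#'   intersection; default: every subset of size >= 2 plus each single set.
#' @return data.frame (pattern, k, n, p0, expected, p_value, direction).
#' @export
intersectionIndependenceTest <- function(sets, universe, patterns = NULL) {
  uni <- if (is(universe, "Accessome")) peakIds(universe)
  else as.character(universe)
  if (!length(uni)) stop("empty universe")
  bad <- names(sets)[!vapply(sets, function(s)
    all(memberIds(s) %in% uni), logical(1))]
  if (length(bad))
    stop("set(s) not contained in the universe: ",
         paste(bad, collapse = ", "))
  if (is.null(patterns)) {
    nm <- names(sets)
    patterns <- unlist(lapply(seq_along(nm), function(k)
      utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  }
  n <- length(uni)
  rows <- lapply(patterns, function(pat) {
    memb <- lapply(sets[pat], memberIds)
    k <- length(Reduce(intersect, memb))
    p0 <- prod(vapply(memb, length, integer(1)) / n)
    res <- binomialEnrichment(k, n, p0)
    data.frame(pattern = paste(pat, collapse = "&"), k = k, n = n, p0 = p0,
               expected = n * p0, p_value = res$p_value,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap summary between two sets of the same kind
#'
#' @param a,b Two [PeakSet]s or two [GeneSet]s.
#' @return list(intersection, size_a, percentage) where
#'   `percentage = 100 * |a intersect b| / |a|` rounded to one decimal.
#' @export
summarizeOverlap <- function(a, b) {
  if (!identical(class(a), class(b)))
    stop("sets must be of the same kind")
  if (!length(memberIds(a))) stop("overlap percentage undefined: |a| = 0")
  i <- length(intersect(memberIds(a), memberIds(b)))
  list(intersection = i, size_a = length(memberIds(a)),
       percentage = round(100 * i / length(memberIds(a)), 1))
}
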