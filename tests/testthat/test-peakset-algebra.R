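# Threshold set algebra, primed/de novo classification, intersection
# independence, and overlap summaries.

test_that("the six accessibility sets implement the definitions verbatim", {
  ids <- paste0("p", 1:8)
  tabs <- nullDaTables(ids)
  # p1 qualifies via FgfrDN closure at 10 hpf
  tabs[["FgfrDN_vs_LacZ@10"]][1, c("log2fc", "fdr")] <- c(-0.6, 0.01)
  # p2 qualifies only via the second union branch (MekAct vs FgfrDN up)
  tabs[["MekAct_vs_FgfrDN@10"]][2, c("log2fc", "fdr")] <- c(0.8, 0.001)
  # p3 sits exactly at the boundary: strict inequality excludes it
  tabs[["FgfrDN_vs_LacZ@10"]][3, c("log2fc", "fdr")] <- c(-0.5, 0.01)
  # p4 closes in the control 10 vs 18 comparison (opens over time)
  tabs[["t10_vs_t18"]][4, c("log2fc", "fdr")] <- c(-1.2, 0.001)
  # p1 also closes 10 vs 18: de novo must exclude it (it is FGF-opened)
  tabs[["t10_vs_t18"]][1, c("log2fc", "fdr")] <- c(-1.2, 0.001)
  # p5 closed by Mek activation vs both controls
  tabs[["MekAct_vs_LacZ@10"]][5, c("log2fc", "fdr")] <- c(-2, 0.001)
  sets <- defineAccessibilitySets(tabs)
  expect_setequal(memberIds(sets$opened_FGF_MAPK_10), c("p1", "p2"))
  expect_setequal(memberIds(sets$closed_FGF_MAPK_10), "p5")
  expect_setequal(memberIds(sets$de_novo), "p4")
  expect_setequal(memberIds(sets$primed), "p2")
  expect_length(intersect(memberIds(sets$primed), memberIds(sets$de_novo)), 0)
  # a missing contrast table errors by name
  expect_error(defineAccessibilitySets(tabs[-7]), "t10_vs_t18")
})

test_that("set definitions are pure and monotone in the FDR threshold", {
  withr::with_seed(21, {
    ids <- paste0("p", 1:300)
    tabs <- lapply(nullDaTables(ids), function(t) {
      t$log2fc <- rnorm(300, 0, 1)
      t$fdr <- runif(300)
      t
    })
  })
  s1 <- defineAccessibilitySets(tabs)
  s2 <- defineAccessibilitySets(tabs)
  for (nm in names(s1))
    expect_identical(memberIds(s1[[nm]]), memberIds(s2[[nm]]))
  loose <- defineAccessibilitySets(tabs, fdrThreshold = 0.2)
  for (nm in c("opened_FGF_MAPK_10", "closed_FGF_MAPK_10",
               "opened_FGF_MAPK_18", "closed_FGF_MAPK_18"))
    expect_true(all(memberIds(s1[[nm]]) %in% memberIds(loose[[nm]])))
  expect_length(intersect(memberIds(s1$primed), memberIds(s1$de_novo)), 0)
})

test_that("expression gene sets apply the stated thresholds strictly", {
  genes <- paste0("g", 1:6)
  mk <- function() data.frame(gene_id = genes, log2fc = 0, p_value = 1,
                              fdr = 1, stringsAsFactors = FALSE)
  tabs <- list("FoxfCRISPR_vs_ControlCRISPR" = mk(),
               "MRasCA_vs_LacZ@18" = mk(), "FgfrDN_vs_LacZ@18" = mk(),
               "MRasCA_vs_FgfrDN@18" = mk(), "FgfrDN_vs_LacZ@10" = mk())
  # g1 at exactly -0.75 in the Foxf contrast: excluded (strict)
  tabs[["FoxfCRISPR_vs_ControlCRISPR"]][1:2, c("log2fc", "fdr")] <-
    cbind(c(-0.75, -0.76), c(0.01, 0.01))
  # g3 down in MRasCA vs control AND down in MRasCA vs FgfrDN
  tabs[["MRasCA_vs_LacZ@18"]][3, c("log2fc", "fdr")] <- c(-1.5, 0.01)
  tabs[["MRasCA_vs_FgfrDN@18"]][3, c("log2fc", "fdr")] <- c(-1.2, 0.01)
  # g4 down in only one of the two: not in the intersection
  tabs[["MRasCA_vs_LacZ@18"]][4, c("log2fc", "fdr")] <- c(-1.5, 0.01)
  sets <- suppressWarnings(defineExpressionGeneSets(tabs))
  expect_setequal(memberIds(sets$foxf_targets), "g2")
  expect_setequal(memberIds(sets$mapk_inhibited_18), "g3")
  # empty tables give empty sets with a warning
  empty <- lapply(tabs, function(t) t[0, ])
  expect_warning(es <- defineExpressionGeneSets(empty), "empty")
  expect_true(all(vapply(es, length, integer(1)) == 0))
})

test_that("the threshold-rule grammar evaluates unions and differences", {
  ids <- paste0("x", 1:4)
  tabs <- list(A = mkDaTable(ids, lfc = c(1, 1, 0, 0), fdr = 0.01),
               B = mkDaTable(ids, lfc = c(1, 0, 1, 0), fdr = 0.01))
  spec <- list(combine = "minus", rules = list(
    list(comparison = "A", sign = "up", lfc = 0.5, fdr = 0.05),
    list(comparison = "B", sign = "up", lfc = 0.5, fdr = 0.05)))
  s <- thresholdSet(spec, tabs, name = "AminusB", kind = "peak")
  expect_setequal(memberIds(s), "x2")
})

test_that("primed/de novo elements classify into the four labeled sets", {
  # map: e1 -> de novo cardiac gene; e2 -> de novo ASM gene;
  # e3 -> both an ASM gene and a cardiac gene (conflict: removed);
  # e4 -> cardiac gene but 18 hpf log2fc of 0 (strict sign rule excludes)
  map <- data.frame(
    peak_id = c("e1", "e2", "e3", "e3", "e4", "e5", "e6"),
    gene_id = c("gc1", "ga1", "ga1", "gc1", "gc2", "gc1", "ga1"),
    distance = 0, stringsAsFactors = FALSE)
  ids <- paste0("e", 1:6)
  da <- list(
    "MRasCA_vs_LacZ@18" = mkDaTable(ids, lfc = c(-1, 1, 1, 0, -1, 1)),
    "FgfrDN_vs_LacZ@18" = mkDaTable(ids, lfc = c(0, -1, -1, 0, 0, -1)))
  gs <- list(
    de_novo_cardiac = GeneSet("de_novo_cardiac", c("gc1", "gc2")),
    de_novo_asm = GeneSet("de_novo_asm", "ga1"),
    cardiac = GeneSet("cardiac", c("gc1", "gc2")),
    asm = GeneSet("asm", "ga1"),
    mapk_inhibited_18 = GeneSet("mapk_inhibited_18", character()),
    mapk_activated_18 = GeneSet("mapk_activated_18", character()))
  primed <- PeakSet("primed", c("e1", "e2", "e3", "e4"))
  deNovo <- PeakSet("de_novo", c("e5", "e6"))
  out <- classifyPrimedDenovoElements(map, da, gs, primed, deNovo)
  expect_setequal(memberIds(out$primed_cardiac), "e1")
  expect_setequal(memberIds(out$primed_asm), "e2")   # e3 removed by conflict
  expect_setequal(memberIds(out$de_novo_cardiac), "e5")
  expect_setequal(memberIds(out$de_novo_asm), "e6")
  expect_error(
    classifyPrimedDenovoElements(map, da, gs[-1], primed, deNovo),
    "de_novo_cardiac")
})

test_that("intersection independence testing follows the joint-probability null", {
  uni <- paste0("u", 1:100)
  A <- PeakSet("A", uni[1:50])
  B <- PeakSet("B", uni[c(1:20, 51:70)])  # |B| = 40, |A&B| = 20 = 100 * 0.2
  res <- intersectionIndependenceTest(list(A = A, B = B), uni,
                                      patterns = list(c("A", "B")))
  expect_equal(res$k, 20)
  expect_equal(res$p0, 0.2)
  expect_equal(res$p_value, 1)  # observation at the expectation
  # enrichment case checked against the enumeration oracle
  B2 <- PeakSet("B", uni[c(1:30, 51:60)])
  res2 <- intersectionIndependenceTest(list(A = A, B = B2), uni,
                                       patterns = list(c("A", "B")))
  expect_equal(res2$k, 30)
  expect_equal(res2$p_value, binomEnumOracle(30, 100, 0.2),
               tolerance = 1e-12)
  # disjoint sets: exact enumeration of the k = 0 outcome
  C <- PeakSet("C", uni[1:10])
  D <- PeakSet("D", uni[11:20])
  res3 <- intersectionIndependenceTest(list(C = C, D = D), uni,
                                       patterns = list(c("C", "D")))
  expect_equal(res3$p_value, binomEnumOracle(0, 100, 0.01), tolerance = 1e-12)
  # a single set is always null-consistent
  res4 <- intersectionIndependenceTest(list(A = A), uni,
                                       patterns = list("A"))
  expect_equal(res4$p_value, 1)
  expect_error(intersectionIndependenceTest(list(A = A), character()),
               "empty universe")
  expect_error(
    intersectionIndependenceTest(list(X = PeakSet("X", "zzz")), uni),
    "not contained")
})

test_that("overlap summaries reproduce printed-ratio arithmetic", {
  a <- GeneSet("a", paste0("g", 1:5450))
  b <- GeneSet("b", paste0("g", 1:3525))
  expect_equal(summarizeOverlap(a, b)$percentage, 64.7)
  a2 <- GeneSet("a2", paste0("g", 1:1252))
  b2 <- GeneSet("b2", paste0("g", 1:486))
  expect_equal(summarizeOverlap(a2, b2)$percentage, 38.8)
  sub <- GeneSet("sub", paste0("g", 1:10))
  sup <- GeneSet("sup", paste0("g", 1:100))
  expect_equal(summarizeOverlap(sub, sup)$percentage, 100.0)
  expect_error(summarizeOverlap(GeneSet("e", character()), b), "undefined")
  expect_error(summarizeOverlap(a, PeakSet("p", "x")), "same kind")
})
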