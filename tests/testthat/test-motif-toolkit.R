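# PWM thresholds, sequence scanning, hypergeometric enrichment, and the
# motif-to-TF assignment algorithm.

test_that("the DP threshold equals exhaustive enumeration", {
  bgU <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgAT <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  # an irregular informative PWM: rich, non-degenerate score lattice
  withr::with_seed(29, {
    counts <- matrix(sample(1:60, 24, replace = TRUE), 4, 6,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
  })
  pwm <- pwmFromCounts(counts, id = "rich")
  for (bg in list(bgU, bgAT)) {
    expect_equal(pwmThreshold(pwm, bg, 1e-3),
                 thresholdEnumOracle(pwm, bg, 1e-3), tolerance = 1e-9)
    expect_equal(pwmThreshold(pwm, bg, 5e-3),
                 thresholdEnumOracle(pwm, bg, 5e-3), tolerance = 1e-9)
  }
  # a uniform PWM on a uniform background can never match
  uni <- new("PWMotif", id = "uni",
             matrix = matrix(0.25, 4, 6,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
             pseudocount = 0)
  expect_warning(thr <- pwmThreshold(uni, bgU), "\\+Inf")
  expect_identical(thr, Inf)
  expect_error(pwmThreshold(pwm, bgU, pCutoff = 0), "pCutoff")
})

test_that("scanning finds planted sites on both strands", {
  pwm <- sharpPwm("TGTAAACA")
  withr::with_seed(37, {
    bgseq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = "")
  })
  seq1 <- bgseq
  substr(seq1, 37, 44) <- "TGTAAACA"
  hits <- scanSequences(c(pk = seq1), list(pwm),
                        background = c(A = .25, C = .25, G = .25, T = .25))
  h <- motifHits(hits)
  expect_true(any(h$position == 37 & h$strand == "+"))
  expect_true(occupancy(hits)["pk", "m"])
  # the reverse complement of the whole sequence mirrors the hit
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq1)))
  hitsRc <- scanSequences(c(pk = rc), list(pwm),
                          background = c(A = .25, C = .25, G = .25, T = .25))
  hRc <- motifHits(hitsRc)
  expect_true(any(hRc$position == 200 - 37 - 8 + 2 & hRc$strand == "-"))
  # sequence shorter than the motif: no hits
  short <- scanSequences(c(s = "TGTAA"), list(pwm),
                         background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(nrow(motifHits(short)), 0)
  # N bases score as background and cannot create a match
  nseq <- paste(rep("N", 100), collapse = "")
  nh <- scanSequences(c(s = nseq), list(pwm),
                      background = c(A = .25, C = .25, G = .25, T = .25))
  expect_false(any(occupancy(nh)))
  expect_error(scanSequences(c(s = "ACGTX"), list(pwm),
                             background = c(A = .25, C = .25, G = .25,
                                            T = .25)),
               "peak 's'")
})

test_that("scanning is strand-consistent over a random sequence panel", {
  pwm <- sharpPwm("GGAAGT", strength = 60)
  withr::with_seed(41, {
    seqs <- vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
            collapse = ""), character(1))
  })
  names(seqs) <- paste0("p", 1:20)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  fwd <- scanSequences(seqs, list(pwm), background = bg, pCutoff = 1e-3)
  rcs <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), character(1))
  rev <- scanSequences(rcs, list(pwm), background = bg, pCutoff = 1e-3)
  expect_equal(unname(occupancy(fwd)[, 1]), unname(occupancy(rev)[, 1]))
  h1 <- motifHits(fwd); h2 <- motifHits(rev)
  expect_equal(nrow(h1), nrow(h2))
  # mirrored coordinates and flipped strands
  m1 <- h1[order(h1$peak, h1$position), ]
  m2 <- h2[order(h2$peak, 150 - h2$position - 6 + 2), ]
  expect_equal(m1$position, 150 - m2$position - 6 + 2)
  expect_true(all(m1$strand != m2$strand))
})

test_that("hypergeometric enrichment matches the worked example and oracle", {
  # N=100, m=20, |set|=10, a=6
  occ <- matrix(FALSE, 100, 1, dimnames = list(paste0("p", 1:100), "mo"))
  occ[c(1:6, 11:24), 1] <- TRUE   # 6 in the set (p1..p10), 20 overall
  hits <- new("MotifHitMatrix", occupancy = occ,
              hits = data.frame(), thresholds = c(mo = 1),
              background = c(A = .25, C = .25, G = .25, T = .25))
  res <- motifEnrichment(hits, PeakSet("s", paste0("p", 1:10)))
  expect_equal(res$a, 6)
  expect_equal(res$odds_ratio, 6.0)
  expect_equal(res$log2_or, log2(6), tolerance = 1e-12)
  expect_equal(res$p_value, hyperEnumOracle(6, 20, 100, 10),
               tolerance = 1e-12)
  # phyper agrees with the explicit sum across a grid (N <= 200)
  for (N in c(40, 200)) for (m in c(5, N / 4)) for (n in c(8, 20)) {
    a <- min(m, n) - 1
    expect_equal(stats::phyper(a - 1, m, N - m, n, lower.tail = FALSE),
                 hyperEnumOracle(a, m, N, n), tolerance = 1e-12)
  }
  # set = accessome: odds ratio 1, p = 1
  resAll <- motifEnrichment(hits, PeakSet("all", rownames(occ)))
  expect_equal(resAll$odds_ratio, 1)
  expect_equal(resAll$p_value, 1)
  # motif absent from the accessome: p = 1, flagged
  occ0 <- occ; occ0[] <- FALSE
  hits0 <- new("MotifHitMatrix", occupancy = occ0, hits = data.frame(),
               thresholds = c(mo = 1),
               background = c(A = .25, C = .25, G = .25, T = .25))
  res0 <- motifEnrichment(hits0, PeakSet("s", paste0("p", 1:10)))
  expect_equal(res0$p_value, 1)
  expect_true(res0$flagged)
  expect_true(res0$corrected)  # Haldane correction on the zero cell
  # relative-risk variant
  resRr <- motifEnrichment(hits, PeakSet("s", paste0("p", 1:10)),
                           effect = "rr")
  expect_equal(resRr$odds_ratio, (6 / 10) / (20 / 100))
})

test_that("motif-to-TF assignment reproduces the hand trace and terminates", {
  # identity when every motif has exactly one candidate TF
  cat1 <- data.frame(motif = c("m1", "m2"), tf = c("A", "B"))
  out1 <- assignMotifsToTfs(cat1)
  expect_equal(out1$assignment$tf[match(c("m1", "m2"),
                                        out1$assignment$motif)],
               c("A", "B"))
  # hand trace: m1{A}, m2{A,B}, m3{B,C}, m4{C}
  cat2 <- data.frame(motif = c("m1", "m2", "m2", "m3", "m3", "m4"),
                     tf = c("A", "A", "B", "B", "C", "C"))
  out2 <- assignMotifsToTfs(cat2)
  asg <- with(out2$assignment, stats::setNames(tf, motif))
  expect_equal(asg[["m1"]], "A")
  expect_equal(asg[["m4"]], "C")
  expect_equal(asg[["m2"]], "B")
  expect_equal(asg[["m3"]], "B")
  expect_length(out2$unassigned_tfs, 0)
  # empty catalog
  out0 <- assignMotifsToTfs(data.frame(motif = character(),
                                       tf = character()))
  expect_equal(nrow(out0$assignment), 0)
  # termination and the one-TF-per-motif invariant on random catalogs
  withr::with_seed(47, {
    for (i in 1:200) {
      nm <- sample(2:12, 1); nt <- sample(2:8, 1)
      cat <- unique(data.frame(
        motif = sample(paste0("m", 1:nm), 3 * nm, replace = TRUE),
        tf = sample(paste0("t", 1:nt), 3 * nm, replace = TRUE)))
      out <- assignMotifsToTfs(cat)
      expect_equal(anyDuplicated(out$assignment$motif), 0)
      # every TF with any candidate either got a motif or is reported
      expect_setequal(c(out$unassigned_tfs, unique(out$assignment$tf)),
                      unique(cat$tf))
    }
  })
})

test_that("MEME and JASPAR motif files round-trip", {
  dir <- withr::local_tempdir()
  pwms <- syntheticMotifCatalog()
  writeMeme(pwms, file.path(dir, "m.meme"))
  back <- readMeme(file.path(dir, "m.meme"))
  expect_setequal(names(back), names(pwms))
  expect_equal(back$FOX_synth@matrix, pwms$FOX_synth@matrix,
               tolerance = 0.02)
  expect_equal(motifConsensus(back$FOX_synth),
               motifConsensus(pwms$FOX_synth))
  jas <- c(">MA0001 test",
           "A [ 10  0  2 ]", "C [  0 12  0 ]", "G [  2  0 10 ]",
           "T [  0  0  0 ]")
  writeLines(jas, file.path(dir, "j.pfm"))
  pj <- readJasparPfm(file.path(dir, "j.pfm"))
  expect_equal(motifConsensus(pj$MA0001), "ACG")
  expect_equal(ncol(pj$MA0001@matrix), 3)
  expect_true(validObject(pj$MA0001))
})
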