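# Motif accessibility deviations: resizing, observed/expected arithmetic,
# matched background sampling, Z-scores, and differential deviations.

test_that("peak resizing centers and clips as specified", {
  seqlen <- c(chr1 = 10000L)
  acc <- Accessome(gr0("chr1", c(0, 3000, 5010), c(1000, 3200, 5060),
                       seqlen = seqlen))
  rs <- resizePeaks(acc, width = 200)
  # [0, 1000) -> [400, 600)
  expect_equal(start(rs)[1] - 1L, 400)
  expect_equal(end(rs)[1], 600)
  # an already-200 bp peak is unchanged
  expect_equal(start(rs)[2], start(acc)[2])
  expect_equal(end(rs)[2], end(acc)[2])
  # [10, 60) near the origin: center 35, window clipped to [0, 135)
  near <- Accessome(gr0("chr1", 10, 60, seqlen = seqlen))
  rsNear <- resizePeaks(near, width = 200)
  expect_equal(start(rsNear) - 1L, 0)
  expect_equal(end(rsNear), 135)
})

test_that("observed/expected deviations follow the hand arithmetic", {
  # 2 samples, 2 peaks, motif on peak 1; counts [[10,30],[90,70]]
  counts <- matrix(c(10, 90, 30, 70), 2, 2,
                   dimnames = list(c("p1", "p2"), c("s1", "s2")))
  occ <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(c("p1", "p2"), "mo"))
  oe <- motifObservedExpected(counts, occ)
  expect_equal(unname(oe$observed["mo", ]), c(10, 30))
  expect_equal(unname(oe$expected["mo", ]), c(20, 20))
  expect_equal(unname(oe$deviations["mo", ]), c(-0.5, 0.5))
  # single sample: expected = observed, deviation 0
  oe1 <- motifObservedExpected(counts[, 1, drop = FALSE], occ)
  expect_equal(unname(oe1$deviations["mo", 1]), 0)
  # motif on every peak: observed = library size, deviation 0
  occAll <- matrix(TRUE, 2, 1, dimnames = list(c("p1", "p2"), "mo"))
  oeAll <- motifObservedExpected(counts, occAll)
  expect_equal(unname(oeAll$observed["mo", ]), unname(colSums(counts)))
  expect_equal(unname(oeAll$deviations["mo", ]), c(0, 0))
})

test_that("deviation invariants hold on random fixtures", {
  withr::with_seed(31, {
    counts <- matrix(rpois(600, 40), 60, 10,
                     dimnames = list(paste0("p", 1:60), paste0("s", 1:10)))
    occ <- matrix(runif(60 * 4) < 0.3, 60, 4,
                  dimnames = list(paste0("p", 1:60), paste0("mo", 1:4)))
  })
  oe <- motifObservedExpected(counts, occ)
  lib <- colSums(counts)
  # library-size-weighted mean deviation is 0 per motif (exact identity,
  # up to float cancellation on sums of order 1e3)
  expect_equal(unname(oe$deviations %*% lib)[, 1] / sum(lib), rep(0, 4),
               tolerance = 1e-13)
  # uniform sequencing-depth rescaling leaves every deviation unchanged
  oe2 <- motifObservedExpected(counts * 7L, occ)
  expect_equal(oe2$deviations, oe$deviations, tolerance = 1e-12)
})

test_that("background sampling is binned, seeded and reproducible", {
  withr::with_seed(33, {
    counts <- matrix(rpois(500, 30), 50, 10)
    seqs <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""),
      character(1))
  })
  names(seqs) <- rownames(counts) <- paste0("p", 1:50)
  expect_error(sampleBackgroundSets(counts, seqs, nIterations = 0),
               "at least 2")
  b1 <- sampleBackgroundSets(counts, seqs, nIterations = 5, seed = 3)
  b2 <- sampleBackgroundSets(counts, seqs, nIterations = 5, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 1 & b1 <= 50))
  # identical GC and accessibility: sampling is uniform over all peaks
  flat <- matrix(25L, 50, 4, dimnames = list(paste0("p", 1:50), NULL))
  same <- stats::setNames(rep(strrep("ACGT", 20), 50), paste0("p", 1:50))
  bu <- sampleBackgroundSets(flat, same, nIterations = 200, seed = 1)
  expect_gt(length(unique(as.vector(bu))), 45)  # draws reach most peaks
})

test_that("z-scores match an independent straight-line recomputation", {
  withr::with_seed(35, {
    counts <- matrix(rpois(400, 50), 40, 10,
                     dimnames = list(paste0("p", 1:40), paste0("s", 1:10)))
    occ <- matrix(runif(40 * 3) < 0.35, 40, 3,
                  dimnames = list(paste0("p", 1:40), paste0("mo", 1:3)))
    bg <- matrix(sample.int(40, 40 * 6, replace = TRUE), 40, 6)
  })
  dv <- deviationZscores(counts, occ, bg)
  # straight-line reimplementation of the formula chain
  lib <- colSums(counts)
  devOf <- function(cnt) {
    obs <- t(occ) %*% cnt
    expd <- outer(rowSums(obs) / sum(lib), lib)
    (obs - expd) / expd
  }
  fg <- devOf(counts)
  bgDevs <- lapply(1:6, function(i) devOf(counts[bg[, i], ]))
  arr <- simplify2array(bgDevs)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  zExp <- (fg - mu) / sdv
  expect_equal(unname(deviationZ(dv)), unname(as.matrix(zExp)),
               tolerance = 1e-9)
  expect_equal(unname(rawDeviations(dv)), unname(as.matrix(fg)),
               tolerance = 1e-12)
  # permuting background iteration order leaves z unchanged
  dv2 <- deviationZscores(counts, occ, bg[, 6:1])
  expect_equal(deviationZ(dv2), deviationZ(dv), tolerance = 1e-12)
  # degenerate case: identical count rows make every background set carry
  # the same counts, so an all-peak motif has background sd 0 -> NA flagged
  flat <- matrix(20L, 10, 4, dimnames = list(paste0("p", 1:10),
                                             paste0("s", 1:4)))
  occFlat <- matrix(TRUE, 10, 1, dimnames = list(rownames(flat), "all"))
  bgFlat <- withr::with_seed(8, matrix(sample.int(10, 30, replace = TRUE),
                                       10, 3))
  dvAll <- deviationZscores(flat, occFlat, bgFlat)
  expect_true(all(is.na(deviationZ(dvAll)["all", ])))
  expect_error(deviationZscores(counts, occ, bg[, 1, drop = FALSE]),
               ">= 2 background")
})

test_that("library scaling invariance propagates to z-scores", {
  withr::with_seed(36, {
    counts <- matrix(rpois(300, 60), 30, 10,
                     dimnames = list(paste0("p", 1:30), paste0("s", 1:10)))
    occ <- matrix(runif(30 * 2) < 0.4, 30, 2,
                  dimnames = list(paste0("p", 1:30), c("a", "b")))
    bg <- matrix(sample.int(30, 30 * 5, replace = TRUE), 30, 5)
  })
  z1 <- deviationZ(deviationZscores(counts, occ, bg))
  z2 <- deviationZ(deviationZscores(counts * 3L, occ, bg))
  expect_equal(z2, z1, tolerance = 1e-9)
})

test_that("differential deviations test groups as specified", {
  z <- rbind(flat = rep(c(0.5, 0.5), each = 4),
             shifted = rep(c(0, 5), each = 4))
  withr::with_seed(39, {
    z["shifted", ] <- z["shifted", ] + rnorm(8, 0, 1)
  })
  groups <- rep(c("g1", "g2"), each = 4)
  res <- differentialDeviations(z, groups)
  expect_equal(res$p_value[res$motif == "flat"], 1)   # identical vectors
  expect_lt(res$p_value[res$motif == "shifted"], 0.01)
  expect_false(res$significant[res$motif == "flat"])
  # three groups run through ANOVA
  z3 <- matrix(rnorm(24), 2, 12, dimnames = list(c("a", "b"), NULL))
  res3 <- differentialDeviations(z3, rep(c("x", "y", "z"), each = 4))
  expect_true(all(res3$p_value > 0 & res3$p_value <= 1))
  expect_true(all(c("mean_x", "mean_y", "mean_z") %in% names(res3)))
  expect_error(differentialDeviations(z, c("g1", rep("g2", 7))),
               "fewer than 2")
})
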