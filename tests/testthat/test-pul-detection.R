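test_that("adjacent SusC/SusD genes pair; isolated susD does not", {
  genes <- buildGenes(strand = rep("+", 10), susC = 6, susD = 7)
  p <- findSusCDPairs(genes)
  expect_equal(nrow(p), 1)
  expect_equal(p$susC, "g006")
  expect_equal(p$susD, "g007")

  lone <- buildGenes(strand = rep("+", 10), susD = 5)
  expect_equal(nrow(findSusCDPairs(lone)), 0)

  far <- buildGenes(strand = rep("+", 10), susC = 1, susD = 5)
  expect_equal(nrow(findSusCDPairs(far)), 0)

  ## opposite strands never pair
  diffStrand <- buildGenes(strand = c("+", "-", rep("+", 4)),
                           susC = 1, susD = 2)
  expect_equal(nrow(findSusCDPairs(diffStrand)), 0)
})

test_that("a susD with several susC candidates takes the nearest, tie upstream", {
  genes <- buildGenes(strand = rep("+", 7), susC = c(2, 6), susD = 4)
  p <- findSusCDPairs(genes)
  expect_equal(p$susC, "g002")  # distance tie 2 vs 2 -> upstream wins
  genes2 <- buildGenes(strand = rep("+", 7), susC = c(2, 5), susD = 4)
  expect_equal(findSusCDPairs(genes2)$susC, "g005")  # nearest wins
})

test_that("pairing equals the exhaustive all-pairs oracle on random scaffolds", {
  set.seed(101)
  for (rep in 1:25) {
    genes <- randomGeneTable(50)
    got <- findSusCDPairs(genes)
    want <- oraclePairs(genes)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wantDf <- do.call(rbind, lapply(want, function(x)
        data.frame(susC = x[["susC"]], susD = x[["susD"]],
                   stringsAsFactors = FALSE)))
      wantDf <- wantDf[order(wantDf$susD), ]
      gotDf <- got[order(got$susD), c("susC", "susD")]
      rownames(wantDf) <- rownames(gotDf) <- NULL
      expect_equal(gotDf, wantDf)
    }
  }
})

test_that("a forward SusCD pair with GH5, GH5, GH26 yields one mannan locus", {
  genes <- buildGenes(strand = rep("+", 6), susC = 1, susD = 2,
                      cazy = list("3" = "GH5", "5" = "GH5", "6" = "GH26"))
  calls <- pulCalls(callPULs(annotationFromGenes(genes)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cazy_order[[1]], c("GH5", "GH5", "GH26"))
  expect_equal(calls$substrate, "mannan")
})

test_that("the divergent-operon extension absorbs a reverse-sense enzyme block", {
  ## forward locus, then a reverse-sense CE7/GH26/GH130 block inside the
  ## same six-ORF window
  strand <- c(rep("+", 5), rep("-", 3))
  genes <- buildGenes(strand, susC = 1, susD = 2,
                      cazy = list("3" = "GH5", "4" = "GH5", "5" = "GH26",
                                  "6" = "CE7", "7" = "GH26", "8" = "GH130"))
  same <- pulCalls(callPULs(annotationFromGenes(genes)))
  expect_equal(length(same$members[[1]]), 5)
  div <- pulCalls(callPULs(annotationFromGenes(genes),
                           includeDivergent = TRUE))
  expect_equal(nrow(div), 1)
  expect_equal(length(div$members[[1]]), 8)
  expect_true(all(c("CE7", "GH130") %in% unlist(div$cazy_order)))
  expect_equal(div$substrate, "mannan")
})

test_that("window boundary: an enzyme 7 ordinals out leaves a susCD-only locus", {
  genes6 <- buildGenes(strand = rep("+", 10), susC = 1, susD = 2,
                       cazy = list("8" = "GH5"))   # ordinal 7, within 6 of susD
  expect_false(pulCalls(callPULs(annotationFromGenes(genes6)))$substrate ==
                 "susCD-only")
  genes7 <- buildGenes(strand = rep("+", 10), susC = 1, susD = 2,
                       cazy = list("9" = "GH5"))   # ordinal 8, 7 past susD
  calls <- pulCalls(callPULs(annotationFromGenes(genes7)))
  expect_equal(calls$substrate, "susCD-only")

  ## same-orientation rule: an opposite-strand CAZyme two ordinals away
  ## is excluded
  opp <- buildGenes(strand = c("+", "+", "+", "-", "+"), susC = 1, susD = 2,
                    cazy = list("4" = "GH13"))
  expect_equal(pulCalls(callPULs(annotationFromGenes(opp)))$substrate,
               "susCD-only")
  expect_error(callPULs(annotationFromGenes(opp), window = 0), "window")
})

test_that("locus calling equals the brute-force window oracle on random scaffolds", {
  set.seed(202)
  for (rep in 1:30) {
    genes <- randomGeneTable(sample(10:120, 1))
    calls <- pulCalls(callPULs(annotationFromGenes(genes)))
    got <- lapply(calls$members, sort)
    got <- got[order(vapply(got, `[`, character(1), 1))]
    want <- oraclePULMembers(genes)
    expect_equal(got, want)
  }
})

test_that("locus calls are invariant to gene-table row order", {
  set.seed(303)
  genes <- randomGeneTable(60)
  shuffled <- genes[sample.int(nrow(genes)), ]
  ## ordinals are part of the record; a reader would reassign them, so the
  ## shuffled table carries the same ordinals in a different row order
  a <- pulCalls(callPULs(annotationFromGenes(genes)))
  b <- pulCalls(callPULs(GenomeAnnotation("G1", assignOrdinals(shuffled))))
  expect_equal(a$substrate, b$substrate)
  expect_equal(lapply(a$members, sort), lapply(b$members, sort))
})

test_that("substrate classification follows the prioritized rulebook", {
  rb <- readPULRulebook()
  expect_equal(classifySubstrate(c("GH16", "GH30", "GH3"), 0, rb),
               "mixed-linked glucan")
  expect_equal(classifySubstrate(c("GH5", "GH3"), 0, rb), "beta-1,4-glucan")
  ## side-chain-targeting families veto the beta-1,4-glucan call
  expect_equal(classifySubstrate(c("GH5", "GH3", "GH43"), 0, rb),
               "unknown")
  expect_equal(classifySubstrate(c("GH43", "GH51"), 0, rb), "arabinan")
  expect_equal(classifySubstrate(c("GH999"), 0, rb), "unknown")
  expect_equal(classifySubstrate(character(0), 2, rb), "protein")
  expect_equal(classifySubstrate(c("GH13", "GH97"), 1, rb), "starch")
  ## no rule may ever assign cellulose
  expect_false("cellulose" %in% vapply(rb, `[[`, character(1), "substrate"))

  dup <- rb
  dup[[2]]$priority <- dup[[1]]$priority
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rules = dup), yml)
  expect_error(readPULRulebook(yml), "duplicate priorities")
})

test_that("expression needs >= 2 unique peptides mapping to one genome", {
  genes <- buildGenes(strand = rep("+", 5), susC = 1, susD = 2,
                      cazy = list("3" = "GH5", "4" = "GH3"))
  pulSet <- callPULs(annotationFromGenes(genes))

  ok <- makeDetections("g003", "G1", 2)
  expect_true(pulCalls(flagExpression(pulSet, ok))$expressed)
  one <- makeDetections("g003", "G1", 1)
  expect_false(pulCalls(flagExpression(pulSet, one))$expressed)
  shared <- makeDetections("g003", list(c("G1", "G2")), 3)
  expect_false(pulCalls(flagExpression(pulSet, shared))$expressed)
  wrongGenome <- makeDetections("g003", "G9", 3)
  expect_false(pulCalls(flagExpression(pulSet, wrongGenome))$expressed)
})
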