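randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

test_that("length filter is strict at 10 kb; terminal repeats mark circularity", {
  set.seed(21)
  lin <- randSeq(10500)
  circ <- paste0(lin, substr(lin, 1, 25))
  contigs <- Biostrings::DNAStringSet(c(short = randSeq(9999),
                                        atCut = randSeq(10000),
                                        just = randSeq(10001),
                                        linear = lin, circular = circ))
  out <- filterViralContigs(contigs)
  expect_setequal(out$contig_id, c("just", "linear", "circular"))
  expect_false(out$circular[out$contig_id == "linear"])
  expect_true(out$circular[out$contig_id == "circular"])
})

test_that("viral detection needs one unique peptide where microbes need two", {
  set.seed(22)
  contigs <- Biostrings::DNAStringSet(c(V1 = randSeq(11000),
                                        V2 = randSeq(11000)))
  det <- makeDetections(c("V1_p1", "V2_p1"), c("V1", "V2"), c(1, 0))
  out <- filterViralContigs(contigs, det)
  expect_true(out$detected[out$contig_id == "V1"])
  expect_false(out$detected[out$contig_id == "V2"])
  expect_equal(nrow(filterViralContigs(Biostrings::DNAStringSet())), 0)
})

test_that("TNF profiles: single window, strand symmetry, naive-count oracle", {
  p <- tnfProfile("AAAA")
  expect_equal(sum(p), 1)
  expect_equal(unname(p["AAAA"]), 1)

  set.seed(23)
  sq <- randSeq(2000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  expect_equal(tnfProfile(sq), tnfProfile(rc))

  got <- tnfProfile(sq)
  want <- naiveTNF(sq)
  expect_equal(got[names(want)], want)
  expect_equal(sum(got), 1)
  gotFull <- tnfProfile(sq, strandCollapse = FALSE)
  wantFull <- naiveTNF(sq, collapse = FALSE)
  expect_equal(gotFull[names(wantFull)], wantFull)
  expect_error(tnfProfile("ACG"), "shorter")
})

test_that("a virus excised from a genome maps back to that genome by TNF", {
  set.seed(24)
  genomes <- lapply(1:5, function(i) {
    m <- matrix(rgamma(256, 1), 64, 4)
    m <- m / rowSums(m)
    ruminet:::markovSeq(15000, m)
  })
  names(genomes) <- paste0("G", 1:5)
  gProfiles <- lapply(genomes, tnfProfile)
  virus <- substr(genomes$G3, 2001, 14000)
  links <- predictHostsTNF(list(V1 = tnfProfile(virus)), gProfiles)
  expect_equal(links$genome_id, "G3")
  expect_equal(links$method, "TNF")

  ## two identical candidates make the assignment ambiguous: no link
  twin <- list(Ga = gProfiles$G3, Gb = gProfiles$G3)
  expect_equal(nrow(predictHostsTNF(list(V1 = tnfProfile(virus)), twin)), 0)
  expect_equal(nrow(predictHostsTNF(list(V1 = tnfProfile(virus)),
                                    list())), 0)
})

test_that("CRISPR detection recovers planted arrays and rejects two-copy runs", {
  set.seed(25)
  rep1 <- randSeq(30)
  spacers <- vapply(1:2, function(i) randSeq(34), character(1))
  array <- paste0(rep1, spacers[1], rep1, spacers[2], rep1)
  genome <- paste0(randSeq(4000), array, randSeq(4000))
  arrays <- detectCrisprArrays(Biostrings::DNAStringSet(c(G1 = genome)))
  expect_equal(nrow(arrays), 2)
  expect_equal(arrays$spacer, spacers)
  expect_equal(arrays$repeat_consensus, c(rep1, rep1))

  twoCopies <- paste0(randSeq(3000), rep1, spacers[1], rep1, randSeq(3000))
  expect_equal(nrow(detectCrisprArrays(
    Biostrings::DNAStringSet(c(G1 = twoCopies)))), 0)
})

test_that("five planted arrays are recovered with zero false arrays", {
  set.seed(26)
  genome <- randSeq(3000)
  plantedStart <- integer(0)
  plantedLen <- integer(0)
  for (i in 1:5) {
    rp <- randSeq(sample(24:40, 1))
    sp <- vapply(1:3, function(j) randSeq(sample(26:44, 1)), character(1))
    for (j in 1:3) {
      plantedStart <- c(plantedStart,
                        nchar(genome) + j * nchar(rp) + 1 +
                          sum(nchar(sp[seq_len(j - 1)])))
      plantedLen <- c(plantedLen, nchar(sp[j]))
    }
    genome <- paste0(genome, rp, sp[1], rp, sp[2], rp, sp[3], rp,
                     randSeq(2500))
  }
  arrays <- detectCrisprArrays(Biostrings::DNAStringSet(c(G1 = genome)))
  expect_equal(length(unique(arrays$array_id)), 5)
  expect_equal(nrow(arrays), 15)
  ## every planted spacer is recovered at its position; repeat boundaries
  ## of a mismatch-tolerant finder may shift by a few bases when flanking
  ## characters coincide, so compare coordinates, not exact strings
  ord <- order(arrays$start)
  expect_true(all(abs(arrays$start[ord] - plantedStart) <= 4))
  expect_true(all(abs(nchar(arrays$spacer[ord]) - plantedLen) <= 8))
})

test_that("protospacer matching honors the mismatch bound and the naive oracle", {
  set.seed(27)
  spacer <- randSeq(34)
  contig <- randSeq(11000)
  exact <- paste0(substr(contig, 1, 5000), spacer,
                  substr(contig, 5001, 11000))
  sp2 <- strsplit(spacer, "")[[1]]
  sp2[c(5, 20)] <- vapply(sp2[c(5, 20)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  twoMM <- paste0(substr(contig, 1, 5000), paste(sp2, collapse = ""),
                  substr(contig, 5001, 11000))
  arrays <- data.frame(genome_id = "G1", scaffold = "G1", array_id = "a1",
                       repeat_consensus = "x", spacer_id = "s1",
                       spacer = spacer, start = 1,
                       stringsAsFactors = FALSE)
  contigs <- Biostrings::DNAStringSet(c(V1 = exact, V2 = twoMM))
  links <- matchProtospacers(arrays, contigs)
  expect_equal(links$virus_id, "V1")
  expect_equal(links$score, 0)

  ## reverse-complement insertions still match
  rcContig <- Biostrings::DNAStringSet(c(V3 = paste0(
    substr(contig, 1, 4000),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spacer))),
    substr(contig, 4001, 11000))))
  expect_equal(nrow(matchProtospacers(arrays, rcContig)), 1)
})

test_that("matching equals a naive positionwise scan on random instances", {
  set.seed(28)
  for (rep in 1:10) {
    spacer <- randSeq(25)
    contig <- randSeq(3000)
    if (rep %% 2 == 0) {
      sp <- strsplit(spacer, "")[[1]]
      if (rep %% 4 == 0) {
        i <- sample(25, 1)
        sp[i] <- sample(setdiff(c("A", "C", "G", "T"), sp[i]), 1)
      }
      contig <- paste0(substr(contig, 1, 1500), paste(sp, collapse = ""),
                       substr(contig, 1501, 3000))
    }
    arrays <- data.frame(genome_id = "G1", scaffold = "G1", array_id = "a",
                         repeat_consensus = "x", spacer_id = "s",
                         spacer = spacer, start = 1,
                         stringsAsFactors = FALSE)
    got <- matchProtospacers(arrays,
                             Biostrings::DNAStringSet(c(V = contig)))
    want <- naiveSpacerHits(spacer, contig)
    if (is.na(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$score, want)
    }
  }
})

test_that("CRISPR evidence dominates TNF for the same virus-genome pair", {
  tnf <- data.frame(virus_id = c("V1", "V2"), genome_id = c("G1", "G2"),
                    method = "TNF", score = c(0.01, 0.02),
                    stringsAsFactors = FALSE)
  crispr <- data.frame(virus_id = "V1", genome_id = "G1",
                       method = "CRISPR", score = 0,
                       stringsAsFactors = FALSE)
  merged <- mergeHostLinks(crispr, tnf)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$method[merged$virus_id == "V1"], "CRISPR")
  expect_equal(merged$method[merged$virus_id == "V2"], "TNF")
})
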