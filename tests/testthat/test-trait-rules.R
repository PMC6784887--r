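rb <- readPathwayRulebook()
empECs <- sub("^EC:", "", rb$pathways$EMP$members)
pppECs <- sub("^EC:", "", rb$pathways$PPP$members)

## genome with an arbitrary set of planted ECs (one gene per EC)
ecGenome <- function(ecs, ...) {
  n <- max(length(ecs), 1)
  genes <- buildGenes(strand = rep("+", n + 2),
                      ec = setNames(as.list(ecs), seq_along(ecs)), ...)
  annotationFromGenes(genes)
}

test_that("pathway completeness respects the 60% rule on both sides", {
  members <- paste0("EC:9.9.9.", 1:10)
  ann6 <- ecGenome(sub("^EC:", "", members[1:6]))
  r6 <- pathwayCompleteness(ann6, members)
  expect_equal(r6$fraction, 0.6)
  expect_true(r6$present)
  ann5 <- ecGenome(sub("^EC:", "", members[1:5]))
  r5 <- pathwayCompleteness(ann5, members)
  expect_equal(r5$fraction, 0.5)
  expect_false(r5$present)
  r0 <- pathwayCompleteness(ecGenome("1.1.1.1"), members)
  expect_equal(r0$fraction, 0)
  expect_false(r0$present)
  expect_error(pathwayCompleteness(ann6, character(0)), "empty pathway")
})

test_that("rare 6C sugars need the full monomer pathway and 6 of 9 EMP genes", {
  fuc <- sub("^EC:", "", rb$pathways$fucose_monomer$members)
  expect_true("fucose" %in%
                encodedSugarTraits(ecGenome(c(fuc, empECs[1:6])), rb))
  expect_false("fucose" %in%
                 encodedSugarTraits(ecGenome(c(fuc, empECs[1:5])), rb))
  expect_false("fucose" %in%
                 encodedSugarTraits(ecGenome(c(fuc[-1], empECs[1:6])), rb))
})

test_that("5C sugars need isomerase AND epimerase AND the full PPP", {
  iso <- sub("^EC:", "", rb$sugars$arabinose$isomerase)
  epi <- sub("^EC:", "", rb$sugars$arabinose$epimerase)
  expect_true("arabinose" %in%
                encodedSugarTraits(ecGenome(c(iso, epi, pppECs)), rb))
  ## isomerase without the specific epimerase is not enough
  expect_false("arabinose" %in%
                 encodedSugarTraits(ecGenome(c(iso, pppECs)), rb))
  ## nor is an incomplete PPP ("full pathway" means 100%)
  expect_false("arabinose" %in%
                 encodedSugarTraits(
                   ecGenome(c(iso, epi, setdiff(pppECs, "2.2.1.2"))), rb))
  ## xylose shares its epimerase with the PPP, so a full PPP plus the
  ## isomerase carries it
  xiso <- sub("^EC:", "", rb$sugars$xylose$isomerase)
  expect_true("xylose" %in%
                encodedSugarTraits(ecGenome(c(xiso, pppECs)), rb))
})

test_that("fermentation products follow the two-thirds rule over alternatives", {
  but <- sub("^EC:", "", unlist(rb$fermentation$butyrate[[1]]))
  expect_length(but, 6)
  expect_true("butyrate" %in% encodedFermentation(ecGenome(but[1:4]), rb))
  expect_false("butyrate" %in% encodedFermentation(ecGenome(but[1:3]), rb))
  ## acetate via either of two pathways, one complete
  expect_true("acetate" %in% encodedFermentation(ecGenome("6.2.1.1"), rb))
  expect_true("acetate" %in%
                encodedFermentation(ecGenome(c("2.3.1.8", "2.7.2.1")), rb))
  expect_false("acetate" %in% encodedFermentation(ecGenome("2.3.1.8"), rb))
})

test_that("cellulose needs a full cellulosome; other polymers follow PULs", {
  emptyPuls <- callPULs(annotationFromGenes(buildGenes(strand = "+")))
  cellu <- buildGenes(strand = rep("+", 4),
                      product = list("1" = "cohesin module",
                                     "2" = "dockerin module"),
                      cazy = list("3" = "GH48"))
  enc <- encodedPolymerTraits(annotationFromGenes(cellu), emptyPuls)
  expect_true("cellulose" %in% enc)

  gh48only <- buildGenes(strand = rep("+", 2), cazy = list("1" = "GH48"))
  expect_false("cellulose" %in%
                 encodedPolymerTraits(annotationFromGenes(gh48only),
                                      emptyPuls))

  mannanGenes <- buildGenes(strand = rep("+", 5), susC = 1, susD = 2,
                            cazy = list("3" = "GH26", "4" = "GH5"))
  ann <- annotationFromGenes(mannanGenes)
  pulSet <- callPULs(ann)
  expect_true("mannan" %in% encodedPolymerTraits(ann, pulSet))
})

test_that("sugar expression gating matches its boolean truth table", {
  ## evidence genes: glucose-6P isomerase (EMP entry), glucokinase, a
  ## glucose transporter and enolase (a downstream EMP member)
  genes <- buildGenes(strand = rep("+", 6),
                      ec = list("1" = "5.3.1.9", "2" = "2.7.1.2",
                                "4" = "4.2.1.11", "5" = "2.7.1.6"),
                      product = list("2" = "glucokinase",
                                     "3" = "glucose-specific transporter",
                                     "5" = "galactokinase"))
  ann <- annotationFromGenes(genes)
  emptyPuls <- callPULs(ann)
  ids <- genes$gene_id[1:5]
  names(ids) <- c("gpi", "glk", "tr", "eno", "galK")

  for (mask in 0:31) {
    on <- ids[bitwAnd(mask, 2^(0:4)) > 0]
    det <- if (length(on)) makeDetections(unname(on), "G1", 2) else NULL
    prof <- traitProfile(ann, emptyPuls, det)
    expressed <- expressedTraits(prof)
    gpi <- "gpi" %in% names(on); glk <- "glk" %in% names(on)
    tr <- "tr" %in% names(on); eno <- "eno" %in% names(on)
    galK <- "galK" %in% names(on)
    ## independent statement of the rules
    expect_equal("glucose" %in% expressed, gpi && (glk || tr),
                 info = paste("mask", mask))
    expect_equal("galactose" %in% expressed, galK && (gpi || eno),
                 info = paste("mask", mask))
  }
})

test_that("5C sugar expression needs the isomerase plus a downstream EMP gene", {
  genes <- buildGenes(strand = rep("+", 4),
                      ec = list("1" = "5.3.1.5", "2" = "4.2.1.11",
                                "3" = "5.1.3.1"))
  ann <- annotationFromGenes(genes)
  emptyPuls <- callPULs(ann)
  both <- makeDetections(c("g001", "g002"), c("G1", "G1"), c(2, 2))
  expect_true("xylose" %in%
                expressedTraits(traitProfile(ann, emptyPuls, both)))
  isoOnly <- makeDetections("g001", "G1", 3)
  expect_false("xylose" %in%
                 expressedTraits(traitProfile(ann, emptyPuls, isoOnly)))
  empOnly <- makeDetections("g002", "G1", 3)
  expect_false("xylose" %in%
                 expressedTraits(traitProfile(ann, emptyPuls, empOnly)))
})

test_that("expression gating is monotone in the detection set", {
  set.seed(404)
  comm <- sharedAnalysis()
  g <- comm$meta$genome_id[1]
  det <- comm$detections
  own <- det[vapply(det$genome_ids, function(x) identical(x, g),
                    logical(1)), ]
  sub <- own[sample.int(nrow(own), ceiling(nrow(own) / 2)), ]
  full <- traitProfile(comm$annotations[[g]], comm$pulSets[[g]], own)
  half <- traitProfile(comm$annotations[[g]], comm$pulSets[[g]], sub)
  expect_true(all(expressedTraits(half) %in% expressedTraits(full)))
})

test_that("every expressed trait carries evidence proteins", {
  comm <- sharedAnalysis()
  for (p in comm$profiles) {
    for (t in expressedTraits(p)) {
      expect_gt(length(traitEvidence(p)[[t]]), 0)
    }
  }
})
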