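## Synthetic rumen community generator.  Emits annotated genomes (GFF3 +
## annotation TSV), proteomic detection tables, CoMPP/NMR-style metabolite
## panels, genome bin sequences (with planted CRISPR arrays and redundant
## duplicate bins) and viral contigs (host-matched composition, planted
## protospacers), together with a ground-truth ledger, so every downstream
## stage can be scored exactly.

DNA_BASES <- c("A", "C", "G", "T")

## canonical family sets planted per PUL substrate; each set satisfies its
## own rulebook rule and no higher-priority rule
plantedFamilySets <- function() {
  list("mixed-linked glucan" = list(c("GH16", "GH30", "GH3")),
       "beta-1,4-glucan" = list(c("GH5", "GH3"), c("GH9", "GH94")),
       "mannan" = list(c("GH26", "GH5"), c("GH130", "GH2"),
                       c("GH26", "GH36")),
       "xylan" = list(c("GH10", "GH43"), c("GH11", "GH67")),
       "starch" = list(c("GH13", "GH97"), c("GH13", "GH31")),
       "arabinan" = list(c("GH43", "GH51")),
       "pectin" = list(c("GH28"), c("PL1", "GH53")),
       "protein" = list(character(0)))
}

#' Construct a synthetic community configuration
#'
#' Defaults describe the community used throughout the package's tests: 20
#' genomes, 150 planted PULs over the eight rulebook substrates, two decoy
#' SusCD pairs per genome, 60% of planted features expressed, 40 viral
#' contigs with full host-composition mimicry, and one 3-spacer CRISPR array
#' per genome.
#'
#' @param nGenomes,genesPerGenome,nPULs,pulSubstrates,decoysPerGenome
#'   community plan; see \code{\linkS4class{CommunityConfig}}.
#' @param expressionFraction,sharedProteinFraction,onePeptideFraction
#'   expression plan and detection noise.
#' @param sugarTraitsPerGenome,scfaTraitsPerGenome,celluloseFraction
#'   planted trait complements.
#' @param nViruses,virusLengthRange,mimicry,protospacerFraction,
#'   circularFraction,viralDetectionFraction viral plan.
#' @param crisprArraysPerGenome,spacersPerArray CRISPR plan.
#' @param nDuplicateBins,duplicateMutationRate redundant bins for
#'   dereplication.
#' @param genomeSeqLength sequence scaffold length per genome (bp).
#' @param seed RNG seed; the same seed reproduces the community byte for
#'   byte.
#' @return a validated \code{\linkS4class{CommunityConfig}}.
#' @export
communityConfig <- function(nGenomes = 20, genesPerGenome = 260,
                            nPULs = 150,
                            pulSubstrates = names(plantedFamilySets()),
                            decoysPerGenome = 2, expressionFraction = 0.6,
                            sharedProteinFraction = 0.05,
                            onePeptideFraction = 0.05,
                            sugarTraitsPerGenome = 3,
                            scfaTraitsPerGenome = 2,
                            celluloseFraction = 0.15, nViruses = 40,
                            virusLengthRange = c(12000, 15000),
                            mimicry = 1.0, protospacerFraction = 0.5,
                            circularFraction = 0.2,
                            viralDetectionFraction = 0.5,
                            crisprArraysPerGenome = 1, spacersPerArray = 3,
                            nDuplicateBins = 3,
                            duplicateMutationRate = 0.005,
                            genomeSeqLength = 20000, seed = 1) {
  obj <- new("CommunityConfig", nGenomes = nGenomes,
             genesPerGenome = genesPerGenome, nPULs = nPULs,
             pulSubstrates = pulSubstrates,
             decoysPerGenome = decoysPerGenome,
             expressionFraction = expressionFraction,
             sharedProteinFraction = sharedProteinFraction,
             onePeptideFraction = onePeptideFraction,
             sugarTraitsPerGenome = sugarTraitsPerGenome,
             scfaTraitsPerGenome = scfaTraitsPerGenome,
             celluloseFraction = celluloseFraction, nViruses = nViruses,
             virusLengthRange = virusLengthRange, mimicry = mimicry,
             protospacerFraction = protospacerFraction,
             circularFraction = circularFraction,
             viralDetectionFraction = viralDetectionFraction,
             crisprArraysPerGenome = crisprArraysPerGenome,
             spacersPerArray = spacersPerArray,
             nDuplicateBins = nDuplicateBins,
             duplicateMutationRate = duplicateMutationRate,
             genomeSeqLength = genomeSeqLength, seed = seed)
  validObject(obj)
  obj
}

## order-3 Markov transition matrix (64 states x 4 bases), Dirichlet(1) rows
randTransitionMatrix <- function() {
  m <- matrix(rgamma(64 * 4, shape = 1), 64, 4)
  m / rowSums(m)
}

## generate n bases from an order-3 Markov chain
markovSeq <- function(n, trans) {
  cum <- t(apply(trans, 1, cumsum))
  u <- runif(n)
  bases <- integer(n)
  state <- sample.int(64, 1)
  for (i in seq_len(n)) {
    b <- 1L + (u[i] > cum[state, 1]) + (u[i] > cum[state, 2]) +
      (u[i] > cum[state, 3])
    bases[i] <- b
    state <- ((state - 1L) %% 16L) * 4L + b
  }
  paste(DNA_BASES[bases], collapse = "")
}

## substitute a fraction of positions with a different base
mutateSeq <- function(seqChr, rate) {
  n <- nchar(seqChr)
  k <- round(n * rate)
  if (k == 0) return(seqChr)
  pos <- sample.int(n, k)
  chars <- strsplit(seqChr, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(DNA_BASES, b), 1), character(1))
  paste(chars, collapse = "")
}

insertAt <- function(seqChr, insert, pos) {
  paste0(substr(seqChr, 1, pos), insert,
         substr(seqChr, pos + 1, nchar(seqChr)))
}

randDNA <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                             collapse = "")

#' Generate a synthetic community on disk
#'
#' Writes, under \code{outDir}: \code{genomes/} (GFF3 + annotation TSV per
#' genome), \code{bins/} (FASTA per bin, including duplicate bins),
#' \code{viruses/viral_contigs.fna}, \code{proteomics/detections.tsv},
#' \code{metabolites/compp_raw.csv} and \code{sugars.csv},
#' \code{census.tsv}, \code{metadata.tsv} and \code{ground_truth.tsv}.
#' Planted PULs obey the detection geometry (SusC and SusD adjacent on one
#' strand, enzymes within six open reading frames in the same orientation);
#' decoy SusCD pairs are guaranteed to have no CAZyme or peptidase within
#' six open reading frames.  Viral sequences are drawn from their host's
#' order-3 Markov composition model and carry exact copies of host CRISPR
#' spacers when the plan says so.
#'
#' @param config a \code{\linkS4class{CommunityConfig}}.
#' @param outDir output directory, created if needed.
#' @return invisibly, a \code{\linkS4class{GroundTruth}}.
#' @export
generateCommunity <- function(config, outDir) {
  stopifnot(is(config, "CommunityConfig"))
  set.seed(config@seed)
  for (d in c("", "genomes", "bins", "viruses", "proteomics", "metabolites"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)

  nG <- config@nGenomes
  gids <- sprintf("G%02d", seq_len(nG))
  famSets <- plantedFamilySets()
  unknownSub <- setdiff(config@pulSubstrates, names(famSets))
  if (length(unknownSub))
    stop("no planted family set for substrate(s): ",
         paste(unknownSub, collapse = ", "))

  ## distribute PULs over genomes
  base <- config@nPULs %/% max(nG, 1)
  extra <- config@nPULs %% max(nG, 1)
  pulsPerGenome <- rep(base, nG) + (seq_len(nG) <= extra)

  rb <- readPathwayRulebook()
  sugarNames <- names(rb$sugars)
  scfaNames <- names(rb$fermentation)
  phyla <- c("Bacteroidetes", "Firmicutes", "Fibrobacteres",
             "Proteobacteria", "Spirochaetes")
  celluGenomes <- if (config@celluloseFraction > 0) {
    sort(sample(gids, ceiling(config@celluloseFraction * nG)))
  } else character(0)

  detRows <- list()
  pulTruth <- list()
  traitTruth <- list()
  metadata <- data.frame(genome_id = gids,
                         taxonomy = sample(phyla, nG, replace = TRUE),
                         completeness = round(runif(nG, 76, 99.5), 1),
                         coverage = round(runif(nG, 5, 300), 1),
                         stringsAsFactors = FALSE)

  addDetection <- function(gene, genomes, up, sc = NULL) {
    detRows[[length(detRows) + 1]] <<- data.frame(
      protein_id = gene, genome_ids = paste(genomes, collapse = ";"),
      unique_peptides = up, spectral_count = sc %||% (2 * up),
      stringsAsFactors = FALSE)
  }

  for (g in seq_len(nG)) {
    gid <- gids[g]
    nGenes <- config@genesPerGenome
    scaffold <- paste0(gid, "_s1")

    ## ---- block layout: planted PULs and decoy SusCD pairs
    subs <- sample(config@pulSubstrates, pulsPerGenome[g], replace = TRUE)
    blocks <- lapply(subs, function(s) {
      fams <- famSets[[s]][[sample.int(length(famSets[[s]]), 1)]]
      list(kind = "pul", substrate = s, fams = fams,
           len = 2 + max(length(fams), 1) + 1)
    })
    blocks <- c(blocks, rep(list(list(kind = "decoy", substrate = NA,
                                      fams = character(0), len = 2)),
                            config@decoysPerGenome))
    hasCellulosome <- gid %in% celluGenomes
    if (hasCellulosome) {
      ## cellulosome genes carry a CAZy family, so they get their own spaced
      ## block and can never fall inside a SusCD locus window
      blocks <- c(blocks, list(list(kind = "cellulosome", substrate = NA,
                                    fams = character(0), len = 3)))
    }
    if (length(blocks)) blocks <- blocks[sample.int(length(blocks))]
    cursor <- sample(3:6, 1)
    for (k in seq_along(blocks)) {
      blocks[[k]]$start <- cursor
      cursor <- cursor + blocks[[k]]$len + 12
    }
    if (length(blocks) && cursor > nGenes - 2)
      stop("planted features exceed genesPerGenome for ", gid,
           " (need ~", cursor, " genes)")

    ## ---- base gene table (filler everywhere, blocks written over)
    product <- rep("hypothetical protein", nGenes)
    pfam <- rep(list(character(0)), nGenes)
    cazy <- rep(list(character(0)), nGenes)
    ec <- rep(list(character(0)), nGenes)
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    blocked <- rep(FALSE, nGenes)

    susDpfams <- defaultFlagConfig()$susD_pfams
    celluIdx <- integer(0)
    for (bl in blocks) {
      idx <- seq(bl$start, bl$start + bl$len - 1)
      blocked[idx] <- TRUE
      st <- sample(c("+", "-"), 1)
      strand[idx] <- st
      if (bl$kind == "cellulosome") {
        celluIdx <- idx
        product[idx[1]] <- "cellulosome cohesin domain protein"
        product[idx[2]] <- "cellulosome dockerin domain protein"
        product[idx[3]] <- "glycoside hydrolase family 48 protein"
        cazy[[idx[3]]] <- "GH48"
        next
      }
      product[idx[1]] <- "TonB-dependent receptor SusC-like protein"
      product[idx[2]] <- "SusD-like lipoprotein"
      pfam[[idx[2]]] <- sample(susDpfams, 1)
      if (bl$kind == "pul") {
        enzymeIdx <- idx[-c(1, 2)]
        if (identical(bl$substrate, "protein")) {
          product[enzymeIdx[1]] <- "peptidase S8 family protein"
        } else {
          slots <- sample(enzymeIdx, length(bl$fams))
          for (j in seq_along(bl$fams)) {
            fam <- bl$fams[j]
            label <- if (startsWith(fam, "GH") && runif(1) < 0.3) {
              paste0(fam, "_", sample(1:9, 1))
            } else fam
            cazy[[slots[j]]] <- label
            product[slots[j]] <- paste("glycoside hydrolase family",
                                       sub("^GH", "", fam), "protein")
          }
        }
      }
    }

    ## trait genes may only use slots > 6 ordinals from every block span, so
    ## a planted (and possibly detected) metabolic gene can never fall inside
    ## a SusCD locus window and perturb locus membership or expression
    nearBlock <- rep(FALSE, nGenes)
    for (bl in blocks) {
      lo <- max(1, bl$start - 7)
      hi <- min(nGenes, bl$start + bl$len - 1 + 7)
      nearBlock[lo:hi] <- TRUE
    }
    fillerIdx <- which(!blocked & !nearBlock)
    usedIdx <- integer(0)
    takeFiller <- function(n) {
      pool <- fillerIdx[!fillerIdx %in% usedIdx]
      if (length(pool) < n) stop("not enough filler genes in ", gid)
      take <- sort(sample(pool, n))
      usedIdx <<- c(usedIdx, take)
      take
    }

    ## ---- trait complements
    empMembers <- sub("^EC:", "", rb$pathways$EMP$members)
    pppMembers <- sub("^EC:", "", rb$pathways$PPP$members)
    sugars <- character(0)
    if (config@sugarTraitsPerGenome > 0) {
      sugars <- unique(c("glucose",
                         sample(setdiff(sugarNames, "glucose"),
                                max(config@sugarTraitsPerGenome - 1, 0))))
    }
    scfas <- if (config@scfaTraitsPerGenome > 0) {
      sort(sample(scfaNames, min(config@scfaTraitsPerGenome,
                                 length(scfaNames))))
    } else character(0)

    plantEC <- function(ecs, products = NULL) {
      ecs <- sub("^EC:", "", ecs)
      idx <- takeFiller(length(ecs))
      for (j in seq_along(ecs)) {
        ec[[idx[j]]] <<- ecs[j]
        product[idx[j]] <<- products[j] %||% "predicted metabolic enzyme"
      }
      setNames(idx, ecs)
    }

    ecGeneIdx <- c()
    if (length(sugars)) {
      ecGeneIdx <- c(ecGeneIdx, plantEC(empMembers[1:7]))
    } else {
      plantEC(empMembers[1:5])   # below the 6-of-9 rule
    }
    if (any(vapply(sugars, function(s) rb$sugars[[s]]$class == "5C",
                   logical(1)))) {
      ecGeneIdx <- c(ecGeneIdx, plantEC(pppMembers))
    }
    for (s in sugars) {
      def <- rb$sugars[[s]]
      if (def$class == "6C_rare") {
        mono <- sub("^EC:", "", rb$pathways[[def$monomer_pathway]]$members)
        ecGeneIdx <- c(ecGeneIdx, plantEC(setdiff(mono, names(ecGeneIdx))))
      } else if (def$class == "5C") {
        iso <- sub("^EC:", "", def$isomerase)
        epi <- sub("^EC:", "", def$epimerase)
        ecGeneIdx <- c(ecGeneIdx,
                       plantEC(setdiff(c(iso, epi), names(ecGeneIdx))))
      } else if (s == "glucose") {
        ecGeneIdx <- c(ecGeneIdx, plantEC("2.7.1.2", "glucokinase"))
      } else if (s == "galactose") {
        ecGeneIdx <- c(ecGeneIdx, plantEC("2.7.1.6", "galactokinase"))
      }
    }
    scfaGeneIdx <- list()
    for (p in scfas) {
      members <- sub("^EC:", "", unlist(rb$fermentation[[p]][[1]]))
      keep <- members[seq_len(ceiling(2 * length(members) / 3 - 1e-9))]
      new <- setdiff(keep, names(ecGeneIdx))
      planted <- plantEC(new)
      ecGeneIdx <- c(ecGeneIdx, planted)
      scfaGeneIdx[[p]] <- ecGeneIdx[keep]
    }
    ## ---- gene table on disk
    geneIds <- sprintf("%s_%04d", gid, seq_len(nGenes))
    starts <- (seq_len(nGenes) - 1L) * 1200L + 1L
    genesDf <- data.frame(gene_id = geneIds, genome_id = gid,
                          scaffold_id = scaffold, start = starts,
                          end = starts + 999L, strand = strand,
                          ordinal = seq_len(nGenes) - 1L,
                          product = product, stringsAsFactors = FALSE)
    genesDf$pfam <- pfam
    genesDf$cazy <- cazy
    genesDf$ec <- ec
    genesDf$flags <- deriveFlags(pfam, product)
    ann <- GenomeAnnotation(genomeId = gid, genes = genesDf,
                            scaffoldLengths =
                              setNames(nGenes * 1200, scaffold),
                            taxonomy = metadata$taxonomy[g],
                            completeness = metadata$completeness[g],
                            coverage = metadata$coverage[g])
    writeGenomeAnnotations(ann, file.path(outDir, "genomes",
                                          paste0(gid, ".gff3")),
                           file.path(outDir, "genomes",
                                     paste0(gid, "_annotation.tsv")))

    ## ---- expression plan + detections
    pulBlocks <- Filter(function(b) b$kind == "pul", blocks)
    decoyBlocks <- Filter(function(b) b$kind == "decoy", blocks)
    polymerExpressed <- character(0)
    for (bl in pulBlocks) {
      expressed <- runif(1) < config@expressionFraction
      idx <- seq(bl$start, bl$start + bl$len - 1)
      if (expressed) {
        polymerExpressed <- c(polymerExpressed, bl$substrate)
        targets <- geneIds[c(idx[2], idx[sample(3:bl$len, 1)])]
        for (t in unique(targets)) addDetection(t, gid, sample(2:4, 1))
      } else {
        if (runif(1) < config@sharedProteinFraction) {
          other <- sample(setdiff(gids, gid), 1)
          addDetection(geneIds[idx[2]], sort(c(gid, other)),
                       sample(2:3, 1))
        }
        if (runif(1) < config@onePeptideFraction) {
          addDetection(geneIds[idx[sample.int(bl$len, 1)]], gid, 1)
        }
      }
      pulTruth[[length(pulTruth) + 1]] <- data.frame(
        genome_id = gid, scaffold_id = scaffold,
        susC = geneIds[idx[1]], susD = geneIds[idx[2]],
        substrate = bl$substrate, decoy = FALSE, expressed = expressed,
        stringsAsFactors = FALSE)
    }
    for (bl in decoyBlocks) {
      idx <- seq(bl$start, bl$start + bl$len - 1)
      pulTruth[[length(pulTruth) + 1]] <- data.frame(
        genome_id = gid, scaffold_id = scaffold,
        susC = geneIds[idx[1]], susD = geneIds[idx[2]],
        substrate = "susCD-only", decoy = TRUE, expressed = FALSE,
        stringsAsFactors = FALSE)
    }

    sugarExpressed <- character(0)
    for (s in sugars) {
      if (runif(1) >= config@expressionFraction) next
      sugarExpressed <- c(sugarExpressed, s)
      def <- rb$sugars[[s]]
      entry <- sub("^EC:", "", def$entry)
      addDetection(geneIds[ecGeneIdx[[entry]]], gid, sample(2:4, 1))
      if (s == "glucose") {
        addDetection(geneIds[ecGeneIdx[["2.7.1.2"]]], gid, sample(2:3, 1))
      } else {
        down <- setdiff(intersect(empMembers, names(ecGeneIdx)), entry)[1]
        addDetection(geneIds[ecGeneIdx[[down]]], gid, sample(2:3, 1))
      }
    }
    scfaExpressed <- character(0)
    for (p in scfas) {
      if (runif(1) >= config@expressionFraction) next
      scfaExpressed <- c(scfaExpressed, p)
      addDetection(geneIds[scfaGeneIdx[[p]][1]], gid, sample(2:3, 1))
    }
    celluExpressed <- FALSE
    if (hasCellulosome && runif(1) < config@expressionFraction) {
      celluExpressed <- TRUE
      addDetection(geneIds[celluIdx[1]], gid, sample(2:3, 1))
    }

    ## ---- truth trait rows
    polymerEncoded <- unique(vapply(pulBlocks, `[[`, character(1),
                                    "substrate"))
    tr <- list()
    for (p in polymerEncoded) {
      tr[[length(tr) + 1]] <- data.frame(
        genome_id = gid, trait = p, class = "polymer", encoded = TRUE,
        expressed = p %in% polymerExpressed, stringsAsFactors = FALSE)
    }
    if (hasCellulosome) {
      tr[[length(tr) + 1]] <- data.frame(
        genome_id = gid, trait = "cellulose", class = "polymer",
        encoded = TRUE, expressed = celluExpressed, stringsAsFactors = FALSE)
    }
    for (s in sugars) {
      tr[[length(tr) + 1]] <- data.frame(
        genome_id = gid, trait = s, class = "sugar", encoded = TRUE,
        expressed = s %in% sugarExpressed, stringsAsFactors = FALSE)
    }
    for (p in scfas) {
      tr[[length(tr) + 1]] <- data.frame(
        genome_id = gid, trait = p, class = "scfa", encoded = TRUE,
        expressed = p %in% scfaExpressed, stringsAsFactors = FALSE)
    }
    traitTruth <- c(traitTruth, tr)
  }

  ## ---- metabolite panels
  polymerSubstrates <- c(setdiff(config@pulSubstrates, character(0)),
                         "cellulose", "xyloglucan")
  polymerSubstrates <- unique(polymerSubstrates)
  mu <- setNames(runif(length(polymerSubstrates), 30, 400),
                 polymerSubstrates)
  if ("mannan" %in% polymerSubstrates) mu["mannan"] <- 420
  comppRows <- list()
  probes <- setNames(sprintf("mAb%02d", seq_along(polymerSubstrates)),
                     polymerSubstrates)
  for (extraction in c("CDTA", "NaOH")) {
    for (smp in 1:6) {
      for (s in polymerSubstrates) {
        for (rep in 1:4) {
          comppRows[[length(comppRows) + 1]] <- data.frame(
            probe = probes[[s]], substrate = s, extraction = extraction,
            sample = smp, replicate = rep,
            signal = round(mu[[s]] * runif(1, 0.8, 1.2), 2),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  compp <- do.call(rbind, comppRows)
  write.csv(compp, file.path(outDir, "metabolites", "compp_raw.csv"),
            row.names = FALSE)
  sugarClass <- vapply(names(rb$sugars), function(s)
    if (rb$sugars[[s]]$class == "5C") "5C" else "6C", character(1))
  conc <- round(runif(length(sugarClass), 5, 40), 2)
  names(conc) <- names(sugarClass)
  conc["mannose"] <- 0.3   # trace monomer under abundant mannan
  conc["glucose"] <- 45
  sugarsDf <- data.frame(sugar = names(sugarClass),
                         class = unname(sugarClass),
                         concentration = unname(conc),
                         stringsAsFactors = FALSE)
  write.csv(sugarsDf, file.path(outDir, "metabolites", "sugars.csv"),
            row.names = FALSE)

  ## ---- sequences: genome bins with CRISPR arrays, duplicates, viruses
  transList <- lapply(gids, function(x) randTransitionMatrix())
  names(transList) <- gids
  spacerTruth <- list()
  genomeSeqs <- character(0)
  for (gid in gids) {
    s <- markovSeq(config@genomeSeqLength, transList[[gid]])
    if (config@crisprArraysPerGenome > 0 && config@spacersPerArray > 0) {
      for (a in seq_len(config@crisprArraysPerGenome)) {
        rep <- randDNA(sample(28:36, 1))
        spacers <- vapply(seq_len(config@spacersPerArray), function(i)
          randDNA(sample(32:38, 1)), character(1))
        array <- paste0(rep, paste0(spacers, rep, collapse = ""))
        pos <- sample.int(nchar(s) - 1, 1)
        s <- insertAt(s, array, pos)
        spacerTruth[[length(spacerTruth) + 1]] <- data.frame(
          genome_id = gid, spacer = spacers, virus_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    genomeSeqs[[gid]] <- s
  }
  dupTruth <- data.frame(bin_id = character(0), parent_id = character(0),
                         stringsAsFactors = FALSE)
  binSeqs <- genomeSeqs
  if (config@nDuplicateBins > 0) {
    parents <- sample(gids, config@nDuplicateBins)
    for (i in seq_along(parents)) {
      bin <- paste0(parents[i], "_dup", i)
      binSeqs[[bin]] <- mutateSeq(genomeSeqs[[parents[i]]],
                                  config@duplicateMutationRate)
      dupTruth <- rbind(dupTruth, data.frame(bin_id = bin,
                                             parent_id = parents[i],
                                             stringsAsFactors = FALSE))
    }
  }
  for (bin in names(binSeqs)) {
    ss <- Biostrings::DNAStringSet(setNames(binSeqs[[bin]],
                                            paste0(bin, "_seq1")))
    Biostrings::writeXStringSet(ss, file.path(outDir, "bins",
                                              paste0(bin, ".fna")))
  }

  ## census: duplicates always score below their parent
  census <- data.frame(genome_id = names(binSeqs),
                       n_scg_present = NA_integer_,
                       n_scg_multicopy = NA_integer_,
                       total_length = nchar(unlist(binSeqs)),
                       stringsAsFactors = FALSE)
  pres <- setNames(sample(36:40, length(gids), replace = TRUE), gids)
  multi <- setNames(sample(0:1, length(gids), replace = TRUE), gids)
  for (i in seq_len(nrow(census))) {
    bin <- census$genome_id[i]
    if (bin %in% gids) {
      census$n_scg_present[i] <- pres[[bin]]
      census$n_scg_multicopy[i] <- multi[[bin]]
    } else {
      parent <- dupTruth$parent_id[dupTruth$bin_id == bin]
      census$n_scg_present[i] <- pres[[parent]] - sample(3:6, 1)
      census$n_scg_multicopy[i] <- multi[[parent]] + sample(1:2, 1)
    }
  }
  writeTsv(census[order(census$genome_id), ], file.path(outDir, "census.tsv"))
  writeTsv(metadata, file.path(outDir, "metadata.tsv"))

  ## viruses
  globalTrans <- matrix(0.25, 64, 4)
  virusTruth <- list()
  viralSeqs <- character(0)
  if (config@nViruses > 0) {
    hosts <- sample(gids, config@nViruses, replace = TRUE)
    hostSpacers <- split(do.call(rbind, c(list(
      data.frame(genome_id = character(0), spacer = character(0),
                 virus_id = character(0), stringsAsFactors = FALSE)),
      spacerTruth)), ~genome_id)
    for (i in seq_len(config@nViruses)) {
      vid <- sprintf("V%03d", i)
      host <- hosts[i]
      len <- sample(seq(config@virusLengthRange[1],
                        config@virusLengthRange[2]), 1)
      trans <- config@mimicry * transList[[host]] +
        (1 - config@mimicry) * globalTrans
      s <- markovSeq(len, trans)
      hasProto <- FALSE
      if (runif(1) < config@protospacerFraction &&
          host %in% names(hostSpacers) && nrow(hostSpacers[[host]]) > 0) {
        sp <- hostSpacers[[host]]$spacer
        pick <- sample.int(length(sp), 1)
        s <- insertAt(s, sp[pick], sample.int(nchar(s) - 1, 1))
        hasProto <- TRUE
        for (k in seq_along(spacerTruth)) {
          hit <- spacerTruth[[k]]$genome_id == host &
            spacerTruth[[k]]$spacer == sp[pick]
          spacerTruth[[k]]$virus_id[hit] <- vid
        }
      }
      circular <- runif(1) < config@circularFraction
      if (circular) s <- paste0(s, substr(s, 1, 25))
      detected <- runif(1) < config@viralDetectionFraction
      if (detected) addDetection(paste0(vid, "_p1"), vid, 1, 2)
      viralSeqs[[vid]] <- s
      virusTruth[[length(virusTruth) + 1]] <- data.frame(
        virus_id = vid, host_id = host, length = nchar(s),
        circular = circular, detected = detected, protospacer = hasProto,
        stringsAsFactors = FALSE)
    }
  }
  ## short decoy contigs below the 10 kb cut
  for (i in 1:3) {
    viralSeqs[[sprintf("Vshort%02d", i)]] <-
      markovSeq(sample(5000:9000, 1), globalTrans)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(viralSeqs)),
    file.path(outDir, "viruses", "viral_contigs.fna"))

  ## ---- detections + truth on disk
  det <- do.call(rbind, c(list(
    data.frame(protein_id = character(0), genome_ids = character(0),
               unique_peptides = integer(0), spectral_count = integer(0),
               stringsAsFactors = FALSE)), detRows))
  det <- det[order(det$protein_id), , drop = FALSE]
  writeTsv(det, file.path(outDir, "proteomics", "detections.tsv"))

  truth <- new("GroundTruth",
               puls = do.call(rbind, c(list(data.frame(
                 genome_id = character(0), scaffold_id = character(0),
                 susC = character(0), susD = character(0),
                 substrate = character(0), decoy = logical(0),
                 expressed = logical(0), stringsAsFactors = FALSE)),
                 pulTruth)),
               traits = do.call(rbind, c(list(data.frame(
                 genome_id = character(0), trait = character(0),
                 class = character(0), encoded = logical(0),
                 expressed = logical(0), stringsAsFactors = FALSE)),
                 traitTruth)),
               virusHosts = do.call(rbind, c(list(data.frame(
                 virus_id = character(0), host_id = character(0),
                 length = integer(0), circular = logical(0),
                 detected = logical(0), protospacer = logical(0),
                 stringsAsFactors = FALSE)), virusTruth)),
               spacers = do.call(rbind, c(list(data.frame(
                 genome_id = character(0), spacer = character(0),
                 virus_id = character(0), stringsAsFactors = FALSE)),
                 spacerTruth)),
               duplicates = dupTruth)
  groundTruthReport(truth, file.path(outDir, "ground_truth.tsv"))
  invisible(truth)
}

#' Serialize a ground-truth ledger to TSV
#'
#' One long-format table with a \code{record} discriminator column; see
#' \code{\link{readGroundTruthReport}} for the inverse.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param path output TSV.
#' @export
groundTruthReport <- function(truth, path) {
  tag <- function(df, record) {
    if (nrow(df) == 0 && ncol(df) == 0) return(NULL)
    cbind(data.frame(record = rep(record, nrow(df)),
                     stringsAsFactors = FALSE), df)
  }
  tabs <- list(tag(truth@puls, "pul"), tag(truth@traits, "trait"),
               tag(truth@virusHosts, "virus"), tag(truth@spacers, "spacer"),
               tag(truth@duplicates, "duplicate"))
  cols <- unique(unlist(lapply(tabs, names)))
  cols <- c("record", setdiff(cols, "record"))
  wide <- do.call(rbind, lapply(tabs, function(t) {
    if (is.null(t)) return(NULL)
    for (cc in setdiff(cols, names(t))) t[[cc]] <- rep(NA, nrow(t))
    t[, cols, drop = FALSE]
  }))
  if (is.null(wide)) {
    wide <- data.frame(record = character(0), stringsAsFactors = FALSE)
  }
  writeTsv(wide, path)
  invisible(path)
}

#' Read a ground-truth ledger back from TSV
#'
#' @param path TSV written by \code{\link{groundTruthReport}}.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
readGroundTruthReport <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (cc in names(df)) {
    if (is.character(df[[cc]])) df[[cc]][!nzchar(df[[cc]])] <- NA
  }
  pick <- function(record, cols) {
    sub <- df[df$record == record, cols, drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  new("GroundTruth",
      puls = pick("pul", c("genome_id", "scaffold_id", "susC", "susD",
                           "substrate", "decoy", "expressed")),
      traits = pick("trait", c("genome_id", "trait", "class", "encoded",
                               "expressed")),
      virusHosts = pick("virus", c("virus_id", "host_id", "length",
                                   "circular", "detected", "protospacer")),
      spacers = pick("spacer", c("genome_id", "spacer", "virus_id")),
      duplicates = pick("duplicate", c("bin_id", "parent_id")))
}
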