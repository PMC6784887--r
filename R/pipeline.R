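## End-to-end pipeline: simulate -> dereplicate -> puls -> traits ->
## network -> virus, with a manifest of record counts and a config hash.
## All randomness lives in the simulate stage (seeded via the community
## config); every later stage is a deterministic function of the files on
## disk, so rerunning a pipeline reproduces its outputs byte for byte.

#' Serialize / deserialize a community configuration
#'
#' A configuration round-trips through YAML unchanged, and its file hash is
#' recorded in the pipeline manifest.
#'
#' @param config a \code{\linkS4class{CommunityConfig}}.
#' @param path YAML file path.
#' @return \code{readCommunityConfig} returns a \code{CommunityConfig}.
#' @export
writeCommunityConfig <- function(config, path) {
  slots <- methods::slotNames("CommunityConfig")
  lst <- lapply(slots, function(s) slot(config, s))
  names(lst) <- slots
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeCommunityConfig
#' @export
readCommunityConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(communityConfig, lst)
}

pipelineStages <- c("simulate", "dereplicate", "puls", "traits", "network",
                    "virus")

needFile <- function(path, stage) {
  if (!file.exists(path))
    stop(stage, " stage: required input not found: ", path, call. = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages against one community directory.  \code{simulate}
#' writes the synthetic community under \code{outDir/community}; the analysis
#' stages read those files back through the package's own readers and write
#' reports under \code{outDir/results}, plus a \code{manifest.json} with
#' per-stage record counts and the config hash.
#'
#' @param config a \code{\linkS4class{CommunityConfig}}; its seed drives all
#'   randomness.
#' @param outDir pipeline directory.
#' @param stages subset of
#'   \code{c("simulate","dereplicate","puls","traits","network","virus")}.
#' @param dMax,margin TNF host-link thresholds
#'   (see \code{\link{predictHostsTNF}}).
#' @param hubMin hub connectivity threshold (default 6).
#' @return invisibly, a list with the per-stage results.
#' @export
runPipeline <- function(config = communityConfig(), outDir,
                        stages = pipelineStages, dMax = 0.03,
                        margin = 0.002, hubMin = 6) {
  stages <- match.arg(stages, pipelineStages, several.ok = TRUE)
  simDir <- file.path(outDir, "community")
  resDir <- file.path(outDir, "results")
  dir.create(resDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = stages, counts = list())
  out <- list()

  if ("simulate" %in% stages) {
    ruminetMessage("[simulate] generating community under ", simDir)
    out$truth <- generateCommunity(config, simDir)
    writeCommunityConfig(config, file.path(simDir, "config.yaml"))
  }
  cfgPath <- file.path(simDir, "config.yaml")
  if (file.exists(cfgPath)) {
    manifest$config_md5 <- unname(tools::md5sum(cfgPath))
  }

  metaPath <- file.path(simDir, "metadata.tsv")
  metadata <- NULL
  if (file.exists(metaPath)) {
    metadata <- read.delim(metaPath, stringsAsFactors = FALSE)
  }

  representatives <- NULL
  if ("dereplicate" %in% stages) {
    ruminetMessage("[dereplicate] grouping genome bins")
    censusPath <- needFile(file.path(simDir, "census.tsv"), "dereplicate")
    census <- readSCGCensus(censusPath)
    binFiles <- sort(list.files(file.path(simDir, "bins"),
                                pattern = "\\.fna$", full.names = TRUE))
    if (!length(binFiles)) stop("dereplicate stage: no bin FASTA found")
    seqs <- lapply(binFiles, Biostrings::readDNAStringSet)
    names(seqs) <- sub("\\.fna$", "", basename(binFiles))
    derep <- dereplicateGenomes(seqs, census)
    groupsDf <- do.call(rbind, lapply(seq_along(derep$groups), function(i) {
      data.frame(group = i, bin = sort(derep$groups[[i]]),
                 representative = selectRepresentative(derep$groups[[i]],
                                                       census),
                 stringsAsFactors = FALSE)
    }))
    writeTsv(groupsDf, file.path(resDir, "dereplication_groups.tsv"))
    representatives <- derep$representatives
    manifest$counts$bins <- length(seqs)
    manifest$counts$unique_genomes <- length(representatives)
    out$dereplication <- derep
  }
  if (is.null(representatives)) {
    if (!is.null(metadata)) {
      representatives <- metadata$genome_id
    } else {
      gffs <- list.files(file.path(simDir, "genomes"),
                         pattern = "\\.gff3?$")
      representatives <- sort(sub("\\.gff3?$", "", gffs))
    }
  }

  detections <- NULL
  detPath <- file.path(simDir, "proteomics", "detections.tsv")
  loadDetections <- function(stage) {
    if (is.null(detections)) {
      detections <<- readProteinDetections(needFile(detPath, stage))
    }
    detections
  }
  loadAnnotation <- function(gid, stage) {
    gff <- needFile(file.path(simDir, "genomes", paste0(gid, ".gff3")),
                    stage)
    ann <- file.path(simDir, "genomes", paste0(gid, "_annotation.tsv"))
    meta <- if (!is.null(metadata) && gid %in% metadata$genome_id) {
      metadata[metadata$genome_id == gid, ]
    } else {
      data.frame(taxonomy = NA_character_, completeness = 100, coverage = 1)
    }
    readGenomeAnnotations(gff, if (file.exists(ann)) ann else NULL,
                          genomeId = gid, taxonomy = meta$taxonomy,
                          completeness = meta$completeness,
                          coverage = meta$coverage)
  }

  pulSet <- NULL
  annotations <- NULL
  if (any(c("puls", "traits", "network") %in% stages)) {
    annotations <- lapply(representatives, loadAnnotation, stage = "puls")
    names(annotations) <- representatives
  }
  if (any(c("puls", "traits") %in% stages)) {
    ruminetMessage("[puls] detecting polysaccharide utilization loci")
    det <- loadDetections("puls")
    perGenome <- lapply(annotations, function(ann)
      flagExpression(callPULs(ann), det))
    calls <- do.call(rbind, c(list(emptyPULTable()),
                              lapply(perGenome, pulCalls)))
    rownames(calls) <- NULL
    pulSet <- new("PULCallSet", calls = calls)
    out$puls <- pulSet
    out$pulsPerGenome <- perGenome
    manifest$counts$puls <- nrow(calls)
    manifest$counts$puls_expressed <- sum(calls$expressed)
  }

  profiles <- NULL
  if ("traits" %in% stages) {
    ruminetMessage("[traits] reconstructing genomic potential + expression")
    det <- loadDetections("traits")
    profiles <- lapply(representatives, function(gid)
      traitProfile(annotations[[gid]], out$pulsPerGenome[[gid]], det))
    names(profiles) <- representatives
    out$profiles <- profiles
    manifest$counts$traits_encoded <-
      sum(vapply(profiles, function(p) sum(p@encoded), numeric(1)))
    manifest$counts$traits_expressed <-
      sum(vapply(profiles, function(p) sum(p@expressed), numeric(1)))
  }

  network <- NULL
  panel <- NULL
  if ("network" %in% stages) {
    if (is.null(profiles))
      stop("network stage: run the traits stage first")
    ruminetMessage("[network] building the trophic network")
    compp <- readCoMPP(needFile(file.path(simDir, "metabolites",
                                          "compp_raw.csv"), "network"))
    panel <- normalizeCoMPP(compp)
    sugarPanel <- readSugarPanel(needFile(file.path(simDir, "metabolites",
                                                    "sugars.csv"),
                                          "network"))
    cov <- setNames(vapply(annotations, function(a) a@coverage, numeric(1)),
                    names(annotations))
    tax <- setNames(vapply(annotations, function(a) a@taxonomy,
                           character(1)), names(annotations))
    network <- buildNetwork(profiles, panel, sugarPanel, coverage = cov,
                            taxonomy = tax)
    network <- annotateNetwork(network, profiles, minConnections = hubMin)
    out$network <- network
    out$panel <- panel
    manifest$counts$network_edges <-
      igraph::ecount(networkGraph(network))
    manifest$counts$hubs <- length(findHubs(network, hubMin))
    writeTsv(polymerSugarConcordance(panel, sugarPanel,
                                     defaultMonomerMap()),
             file.path(resDir, "polymer_sugar_concordance.tsv"))
  }

  hostLinks <- NULL
  if ("virus" %in% stages) {
    ruminetMessage("[virus] filtering contigs and predicting hosts")
    contigPath <- needFile(file.path(simDir, "viruses",
                                     "viral_contigs.fna"), "virus")
    contigs <- Biostrings::readDNAStringSet(contigPath)
    det <- loadDetections("virus")
    vstats <- filterViralContigs(contigs, det)
    kept <- contigs[vstats$contig_id]
    writeTsv(vstats, file.path(resDir, "viral_contigs.tsv"))

    binFiles <- file.path(simDir, "bins",
                          paste0(representatives, ".fna"))
    genomeSeqs <- lapply(binFiles, function(f)
      Biostrings::readDNAStringSet(needFile(f, "virus")))
    names(genomeSeqs) <- representatives
    gProfiles <- lapply(genomeSeqs, tnfProfile)
    vProfiles <- lapply(seq_along(kept), function(i) tnfProfile(kept[i]))
    names(vProfiles) <- names(kept)
    tnfLinks <- predictHostsTNF(vProfiles, gProfiles, dMax = dMax,
                                margin = margin)

    allGenome <- Biostrings::DNAStringSet(vapply(genomeSeqs, function(s)
      as.character(s[[1]]), character(1)))
    arrays <- detectCrisprArrays(allGenome)
    writeTsv(arrays, file.path(resDir, "crispr_spacers.tsv"))
    crisprLinks <- matchProtospacers(arrays, kept)
    hostLinks <- mergeHostLinks(crisprLinks, tnfLinks)
    out$hostLinks <- hostLinks
    out$viralContigs <- vstats
    out$crisprArrays <- arrays
    manifest$counts$viral_contigs <- nrow(vstats)
    manifest$counts$host_links <- nrow(hostLinks)
    manifest$counts$crispr_links <- sum(hostLinks$method == "CRISPR")
  }

  writeOutputs(pulSet, profiles, network, hostLinks, resDir)
  if (length(manifest$counts)) {
    manifest$counts <- manifest$counts[order(names(manifest$counts))]
  }
  jsonlite::write_json(manifest, file.path(resDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Default polymer-to-monomer map for the concordance screen
#'
#' @return named character vector, polymer substrate to monomeric sugar.
#' @export
defaultMonomerMap <- function() {
  c("mannan" = "mannose", "xylan" = "xylose", "starch" = "glucose",
    "mixed-linked glucan" = "glucose", "beta-1,4-glucan" = "glucose",
    "cellulose" = "glucose", "xyloglucan" = "xylose",
    "arabinan" = "arabinose", "pectin" = "galactose")
}
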