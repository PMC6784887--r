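#' GenomeAnnotation: one annotated genome
#'
#' Holds the called genes of one (draft) genome together with bin-level
#' metadata.  Genes live in a data.frame with one row per gene and
#' list-columns for the annotation sets (\code{pfam}, \code{cazy}, \code{ec},
#' \code{flags}).  Coordinates are 1-based inclusive; the \code{ordinal}
#' column ranks genes along their scaffold by start coordinate and is 0-based
#' and dense, so "within six open reading frames" is a plain ordinal
#' difference.
#'
#' @slot genomeId single genome/bin identifier.
#' @slot taxonomy free-text taxonomy label.
#' @slot completeness estimated completeness, percent in [0, 100].
#' @slot coverage mean read coverage (>= 0); used to size network nodes.
#' @slot genes data.frame of gene records (see Details).
#' @slot scaffoldLengths named numeric, scaffold id to length in bp.
#'
#' @export
setClass("GenomeAnnotation",
  slots = c(genomeId = "character", taxonomy = "character",
            completeness = "numeric", coverage = "numeric",
            genes = "data.frame", scaffoldLengths = "numeric"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  g <- object@genes
  if (length(object@genomeId) != 1L) msg <- c(msg, "genomeId must be length 1")
  if (length(object@completeness) == 1L &&
      (object@completeness < 0 || object@completeness > 100))
    msg <- c(msg, "completeness must be in [0, 100]")
  if (nrow(g) > 0) {
    need <- c("gene_id", "scaffold_id", "start", "end", "strand", "ordinal",
              "product", "pfam", "cazy", "ec", "flags")
    miss <- setdiff(need, names(g))
    if (length(miss))
      msg <- c(msg, paste("genes is missing columns:",
                          paste(miss, collapse = ", ")))
    else {
      if (anyDuplicated(g$gene_id))
        msg <- c(msg, "duplicate gene_id within genome")
      if (any(g$start > g$end)) msg <- c(msg, "gene with start > end")
      if (!all(g$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
      bad <- !g$scaffold_id %in% names(object@scaffoldLengths)
      if (any(bad))
        msg <- c(msg, "gene scaffold_id absent from scaffoldLengths")
      for (sc in unique(g$scaffold_id)) {
        o <- sort(g$ordinal[g$scaffold_id == sc])
        if (!identical(as.integer(o), seq_along(o) - 1L)) {
          msg <- c(msg, paste0("ordinals not dense on scaffold ", sc))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PULCallSet: detected polysaccharide utilization loci
#'
#' One row per locus call.  \code{members} (gene ids in ordinal order),
#' \code{cazy_order} (original CAZy labels in gene order), \code{families}
#' (normalized family set), \code{peptidases} and \code{detected_proteins}
#' are list-columns.  \code{substrate} is a rulebook label, \code{"unknown"},
#' or \code{"susCD-only"} for loci with no CAZyme and no peptidase member.
#'
#' @slot calls data.frame of locus calls.
#' @export
setClass("PULCallSet", slots = c(calls = "data.frame"))

setValidity("PULCallSet", function(object) {
  df <- object@calls
  msg <- character(0)
  need <- c("pul_id", "genome_id", "scaffold_id", "susC", "susD", "strand",
            "substrate", "expressed", "members", "cazy_order", "families",
            "peptidases", "detected_proteins")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("calls is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) > 0) {
    noCat <- lengths(df$cazy_order) == 0 & lengths(df$peptidases) == 0
    bad <- xor(noCat, df$substrate == "susCD-only")
    if (any(bad))
      msg <- c(msg, "substrate is 'susCD-only' iff no CAZyme/peptidase member")
    if (anyDuplicated(df$pul_id)) msg <- c(msg, "duplicate pul_id")
  }
  if (length(msg)) msg else TRUE
})

#' TraitProfile: encoded and expressed traits of one genome
#'
#' @slot genomeId genome identifier.
#' @slot encoded named logical: trait encoded in the genome.
#' @slot expressed named logical: trait supported by genome-unique proteomic
#'   detections.
#' @slot evidence named list of gene/protein ids backing each expressed trait.
#' @slot traitClass named character: trait category
#'   (\code{polymer}, \code{sugar}, \code{scfa}, \code{respiration}).
#' @export
setClass("TraitProfile",
  slots = c(genomeId = "character", encoded = "logical",
            expressed = "logical", evidence = "list",
            traitClass = "character"))

setValidity("TraitProfile", function(object) {
  msg <- character(0)
  expressedOn <- names(object@expressed)[object@expressed]
  noEv <- vapply(expressedOn,
                 function(t) length(object@evidence[[t]]) == 0, logical(1))
  if (any(noEv))
    msg <- c(msg, paste("expressed trait without evidence:",
                        paste(expressedOn[noEv], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' TrophicNetwork: bipartite genome-substrate network
#'
#' Wraps an igraph bipartite graph: genome vertices (\code{type = FALSE})
#' carry coverage, taxonomy, tier, hub and SCFA-star attributes; substrate
#' vertices (\code{type = TRUE}) carry class (polymer/sugar), recalcitrance
#' and measured-abundance attributes.  Every edge records its evidence
#' protein ids.
#'
#' @slot graph an igraph object.
#' @export
setClass("TrophicNetwork", slots = c(graph = "ANY"))

setValidity("TrophicNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::ecount(g) > 0 && !igraph::is_bipartite(g))
    return("graph must be bipartite")
  TRUE
})

#' CommunityConfig: synthetic community plan
#'
#' Parameters of the synthetic rumen community generator.  Counts are
#' non-negative, fractions live in [0, 1], and the same seed always
#' reproduces the same community byte for byte.
#'
#' @slot nGenomes number of unique genomes.
#' @slot genesPerGenome genes per genome scaffold.
#' @slot nPULs total planted PULs across the community.
#' @slot pulSubstrates substrate labels to draw planted PULs from.
#' @slot decoysPerGenome SusCD pairs planted with no CAZyme/peptidase within
#'   six ORFs (must be recovered as "susCD-only").
#' @slot expressionFraction fraction of planted features given proteomic
#'   detections passing the two-unique-peptide, genome-unique gate.
#' @slot sharedProteinFraction fraction of detection rows duplicated onto a
#'   second genome (noise; such rows must never drive an expression call).
#' @slot onePeptideFraction fraction of extra 1-unique-peptide detections
#'   (noise below the microbial threshold).
#' @slot sugarTraitsPerGenome,scfaTraitsPerGenome planted trait counts.
#' @slot celluloseFraction fraction of genomes given a full cellulosome.
#' @slot nViruses,virusLengthRange viral contig plan.
#' @slot mimicry host-composition mimicry in [0, 1] (1 = viral sequence drawn
#'   from the host's order-3 Markov model).
#' @slot protospacerFraction fraction of viruses carrying an exact copy of a
#'   host CRISPR spacer.
#' @slot circularFraction fraction of viruses with a terminal direct repeat.
#' @slot viralDetectionFraction fraction of viruses with a 1-peptide
#'   proteomic detection.
#' @slot crisprArraysPerGenome,spacersPerArray CRISPR plan.
#' @slot nDuplicateBins redundant genome bins emitted for dereplication.
#' @slot duplicateMutationRate per-base substitution rate of duplicate bins.
#' @slot genomeSeqLength length (bp) of each genome's sequence scaffold.
#' @slot seed RNG seed.
#' @export
setClass("CommunityConfig",
  slots = c(nGenomes = "numeric", genesPerGenome = "numeric",
            nPULs = "numeric", pulSubstrates = "character",
            decoysPerGenome = "numeric", expressionFraction = "numeric",
            sharedProteinFraction = "numeric", onePeptideFraction = "numeric",
            sugarTraitsPerGenome = "numeric", scfaTraitsPerGenome = "numeric",
            celluloseFraction = "numeric", nViruses = "numeric",
            virusLengthRange = "numeric", mimicry = "numeric",
            protospacerFraction = "numeric", circularFraction = "numeric",
            viralDetectionFraction = "numeric",
            crisprArraysPerGenome = "numeric", spacersPerArray = "numeric",
            nDuplicateBins = "numeric", duplicateMutationRate = "numeric",
            genomeSeqLength = "numeric", seed = "numeric"))

setValidity("CommunityConfig", function(object) {
  msg <- character(0)
  counts <- c(nGenomes = object@nGenomes,
              genesPerGenome = object@genesPerGenome, nPULs = object@nPULs,
              decoysPerGenome = object@decoysPerGenome,
              nViruses = object@nViruses,
              crisprArraysPerGenome = object@crisprArraysPerGenome,
              spacersPerArray = object@spacersPerArray,
              nDuplicateBins = object@nDuplicateBins,
              genomeSeqLength = object@genomeSeqLength)
  if (any(counts < 0)) msg <- c(msg, "all counts must be >= 0")
  fr <- c(object@expressionFraction, object@sharedProteinFraction,
          object@onePeptideFraction, object@celluloseFraction,
          object@mimicry, object@protospacerFraction,
          object@circularFraction, object@viralDetectionFraction,
          object@duplicateMutationRate)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must be in [0, 1]")
  if (length(object@virusLengthRange) != 2 ||
      object@virusLengthRange[1] > object@virusLengthRange[2])
    msg <- c(msg, "virusLengthRange must be c(min, max)")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted features of a synthetic community
#'
#' Truth ledger written alongside every simulated community so downstream
#' recovery can be scored exactly.
#'
#' @slot puls data.frame of planted loci (genome, scaffold, ordinal span,
#'   substrate, decoy flag, expressed flag).
#' @slot traits data.frame of planted traits (genome, trait, class,
#'   encoded, expressed).
#' @slot virusHosts data.frame of planted virus-host assignments.
#' @slot spacers data.frame of planted CRISPR spacers and the virus (if any)
#'   carrying each protospacer.
#' @slot duplicates data.frame mapping duplicate bins to their parents.
#' @export
setClass("GroundTruth",
  slots = c(puls = "data.frame", traits = "data.frame",
            virusHosts = "data.frame", spacers = "data.frame",
            duplicates = "data.frame"))

## ------------------------------------------------------------------ show

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation ", object@genomeId, "\n",
      "  ", nrow(object@genes), " genes on ",
      length(object@scaffoldLengths), " scaffold(s); completeness ",
      object@completeness, "%\n", sep = "")
})

setMethod("show", "PULCallSet", function(object) {
  df <- object@calls
  cat("PULCallSet with ", nrow(df), " locus call(s)\n", sep = "")
  if (nrow(df)) {
    tab <- sort(table(df$substrate), decreasing = TRUE)
    cat("  substrates: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n",
        "  expressed: ", sum(df$expressed), "\n", sep = "")
  }
})

setMethod("show", "TraitProfile", function(object) {
  cat("TraitProfile ", object@genomeId, ": ",
      sum(object@encoded), " encoded, ", sum(object@expressed),
      " expressed trait(s)\n", sep = "")
})

setMethod("show", "TrophicNetwork", function(object) {
  g <- object@graph
  cat("TrophicNetwork: ",
      sum(!igraph::V(g)$type), " genomes, ",
      sum(igraph::V(g)$type), " substrates, ",
      igraph::ecount(g), " edges\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", nrow(object@puls), " planted loci, ",
      nrow(object@traits), " traits, ", nrow(object@virusHosts),
      " viruses, ", nrow(object@spacers), " spacers\n", sep = "")
})

## ------------------------------------------------------------- accessors

#' @rdname GenomeAnnotation-class
#' @param object a \code{GenomeAnnotation}.
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("genomeId", "GenomeAnnotation", function(object) object@genomeId)

#' @rdname TraitProfile-class
#' @param object a \code{TraitProfile}.
#' @export
setMethod("genomeId", "TraitProfile", function(object) object@genomeId)

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("genes", "GenomeAnnotation", function(object) object@genes)

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("scaffoldLengths", function(object)
  standardGeneric("scaffoldLengths"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("scaffoldLengths", "GenomeAnnotation",
          function(object) object@scaffoldLengths)

#' @rdname PULCallSet-class
#' @param object a \code{PULCallSet}.
#' @export
setGeneric("pulCalls", function(object) standardGeneric("pulCalls"))

#' @rdname PULCallSet-class
#' @export
setMethod("pulCalls", "PULCallSet", function(object) object@calls)

#' @rdname TraitProfile-class
#' @export
setGeneric("encodedTraits", function(object) standardGeneric("encodedTraits"))

#' @rdname TraitProfile-class
#' @export
setMethod("encodedTraits", "TraitProfile", function(object)
  names(object@encoded)[object@encoded])

#' @rdname TraitProfile-class
#' @export
setGeneric("expressedTraits", function(object)
  standardGeneric("expressedTraits"))

#' @rdname TraitProfile-class
#' @export
setMethod("expressedTraits", "TraitProfile", function(object)
  names(object@expressed)[object@expressed])

#' @rdname TraitProfile-class
#' @export
setGeneric("traitEvidence", function(object) standardGeneric("traitEvidence"))

#' @rdname TraitProfile-class
#' @export
setMethod("traitEvidence", "TraitProfile", function(object) object@evidence)

#' @rdname TrophicNetwork-class
#' @param object a \code{TrophicNetwork}.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname TrophicNetwork-class
#' @export
setMethod("networkGraph", "TrophicNetwork", function(object) object@graph)

#' Construct a GenomeAnnotation
#'
#' @param genomeId genome identifier.
#' @param genes gene table (see \code{\linkS4class{GenomeAnnotation}}).
#' @param scaffoldLengths named numeric of scaffold lengths (bp); inferred
#'   from gene ends when omitted.
#' @param taxonomy,completeness,coverage bin metadata.
#' @return a validated \code{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genomeId, genes = emptyGeneTable(),
                             scaffoldLengths = NULL, taxonomy = NA_character_,
                             completeness = 100, coverage = 1) {
  if (is.null(scaffoldLengths)) {
    if (nrow(genes)) {
      scaffoldLengths <- vapply(split(genes$end, genes$scaffold_id), max,
                                numeric(1))
    } else {
      scaffoldLengths <- setNames(numeric(0), character(0))
    }
  }
  new("GenomeAnnotation", genomeId = genomeId, taxonomy = taxonomy,
      completeness = completeness, coverage = coverage, genes = genes,
      scaffoldLengths = scaffoldLengths)
}
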