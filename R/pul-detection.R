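## SusCD-anchored polysaccharide utilization locus (PUL) detection, substrate
## classification and proteomic expression gating.
##
## A PUL is anchored on a SusD-like gene (recognized by Pfam) co-localized
## with a SusC-like / TonB-dependent receptor gene on the same strand.  Genes
## within six open reading frames of the pair, in the same orientation, are
## locus members; a locus with no CAZyme and no peptidase member is reported
## as "susCD-only" rather than given a substrate.

#' Find co-localized SusC/SusD gene pairs
#'
#' Every susD-flagged gene that has a susC/TonB-receptor-flagged gene within
#' \code{gap} ordinals on the same scaffold and strand yields one pair.  A
#' susD gene with several candidates takes the nearest; on a distance tie the
#' upstream (lower-ordinal) candidate wins.
#'
#' @param genes a gene table (from a \code{\linkS4class{GenomeAnnotation}}).
#' @param gap maximum ordinal separation between SusC and SusD (default 2).
#' @return data.frame with one row per pair: susC, susD, scaffold_id, strand,
#'   ordinal_lo, ordinal_hi.
#' @export
findSusCDPairs <- function(genes, gap = 2) {
  empty <- data.frame(susC = character(0), susD = character(0),
                      scaffold_id = character(0), strand = character(0),
                      ordinal_lo = integer(0), ordinal_hi = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  isD <- hasFlag(genes, "susD")
  isC <- hasFlag(genes, "susC") | hasFlag(genes, "tonB_receptor")
  if (!any(isD) || !any(isC)) return(empty)
  rows <- lapply(which(isD), function(i) {
    cand <- which(isC &
                    genes$scaffold_id == genes$scaffold_id[i] &
                    genes$strand == genes$strand[i] &
                    abs(genes$ordinal - genes$ordinal[i]) <= gap &
                    seq_len(nrow(genes)) != i)
    if (!length(cand)) return(NULL)
    d <- abs(genes$ordinal[cand] - genes$ordinal[i])
    best <- cand[d == min(d)]
    if (length(best) > 1) best <- best[which.min(genes$ordinal[best])]
    data.frame(susC = genes$gene_id[best], susD = genes$gene_id[i],
               scaffold_id = genes$scaffold_id[i],
               strand = genes$strand[i],
               ordinal_lo = min(genes$ordinal[c(best, i)]),
               ordinal_hi = max(genes$ordinal[c(best, i)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out[order(out$scaffold_id, out$ordinal_lo, out$susD), , drop = FALSE]
}

#' Call PULs around SusCD pairs
#'
#' For each pair, genes whose ordinal lies within \code{window} of the pair's
#' ordinal span (both directions, measured from the nearer pair member) and
#' that share the pair's orientation become locus members.  Loci from
#' distinct pairs on the same strand whose member sets intersect are merged.
#' A locus with at least one CAZyme or peptidase member is classified with
#' the rulebook; otherwise its substrate is \code{"susCD-only"}.
#'
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param pairs output of \code{\link{findSusCDPairs}}; computed when NULL.
#' @param window ordinal window, default 6 open reading frames.
#' @param gap SusC/SusD pairing gap (used when \code{pairs} is NULL).
#' @param includeDivergent also absorb opposite-strand genes inside the
#'   window (divergent-operon extension; off by default to honor the
#'   same-orientation rule).
#' @param rulebook substrate rulebook, see \code{\link{readPULRulebook}}.
#' @return a \code{\linkS4class{PULCallSet}}.
#' @export
callPULs <- function(annotation, pairs = NULL, window = 6, gap = 2,
                     includeDivergent = FALSE,
                     rulebook = readPULRulebook()) {
  if (window < 1) stop("window must be >= 1")
  genes <- genes(annotation)
  gid <- genomeId(annotation)
  if (is.null(pairs)) pairs <- findSusCDPairs(genes, gap = gap)
  if (nrow(pairs) == 0)
    return(new("PULCallSet", calls = emptyPULTable()))

  memberSets <- lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs[k, ]
    sel <- genes$scaffold_id == p$scaffold_id &
      genes$ordinal >= p$ordinal_lo - window &
      genes$ordinal <= p$ordinal_hi + window
    if (!includeDivergent) sel <- sel & genes$strand == p$strand
    which(sel)
  })

  ## merge pairs on the same scaffold+strand with intersecting member sets
  n <- length(memberSets)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (pairs$scaffold_id[i] == pairs$scaffold_id[j] &&
            pairs$strand[i] == pairs$strand[j] &&
            length(intersect(memberSets[[i]], memberSets[[j]])) > 0) {
          parent[findRoot(j)] <- findRoot(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), findRoot, integer(1))

  calls <- lapply(unique(comp), function(cc) {
    ks <- which(comp == cc)
    idx <- sort(unique(unlist(memberSets[ks])))
    idx <- idx[order(genes$ordinal[idx])]
    mem <- genes$gene_id[idx]
    cazyPerGene <- genes$cazy[idx]
    cazyOrder <- unlist(cazyPerGene, use.names = FALSE)
    fams <- unique(normalizeCazy(cazyOrder))
    pept <- genes$gene_id[idx][hasFlag(genes[idx, , drop = FALSE],
                                       "peptidase")]
    substrate <- if (length(cazyOrder) == 0 && length(pept) == 0) {
      "susCD-only"
    } else {
      classifySubstrate(fams, peptidaseCount = length(pept),
                        rulebook = rulebook)
    }
    df <- data.frame(pul_id = NA_character_, genome_id = gid,
                     scaffold_id = pairs$scaffold_id[ks[1]],
                     susC = paste(pairs$susC[ks], collapse = ";"),
                     susD = paste(pairs$susD[ks], collapse = ";"),
                     strand = pairs$strand[ks[1]],
                     ordinal_start = min(genes$ordinal[idx]),
                     ordinal_end = max(genes$ordinal[idx]),
                     start = min(genes$start[idx]),
                     end = max(genes$end[idx]),
                     substrate = substrate, expressed = FALSE,
                     stringsAsFactors = FALSE)
    df$members <- list(mem)
    df$cazy_order <- list(cazyOrder)
    df$families <- list(fams)
    df$peptidases <- list(pept)
    df$detected_proteins <- list(character(0))
    df
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$scaffold_id, out$ordinal_start), , drop = FALSE]
  out$pul_id <- sprintf("%s_PUL%03d", gid, seq_len(nrow(out)))
  rownames(out) <- NULL
  new("PULCallSet", calls = out)
}

#' Read the PUL substrate rulebook
#'
#' @param path YAML rulebook path; the shipped default when NULL.
#' @return list of rules sorted by priority.
#' @export
readPULRulebook <- function(path = NULL) {
  path <- path %||% ruminetExtdata("pul_rules.yaml")
  raw <- yaml::read_yaml(path)$rules
  prio <- vapply(raw, function(r) as.numeric(r$priority), numeric(1))
  if (anyDuplicated(prio)) stop("rulebook with duplicate priorities")
  raw[order(prio)]
}

#' Classify a PUL's substrate from its CAZy family set
#'
#' Rules are tried in priority order; the first whose required family groups
#' are all represented and whose forbidden set is absent wins.  The label
#' \code{"cellulose"} is unreachable by construction: no rule assigns it.
#'
#' @param families normalized CAZy family set of the locus.
#' @param peptidaseCount number of peptidase members.
#' @param rulebook from \code{\link{readPULRulebook}}.
#' @return substrate label, or \code{"unknown"} when no rule matches.
#' @export
classifySubstrate <- function(families, peptidaseCount = 0,
                              rulebook = readPULRulebook()) {
  for (rule in rulebook) {
    if (isTRUE(rule$peptidase_only)) {
      if (peptidaseCount > 0 && length(families) == 0)
        return(rule$substrate)
      next
    }
    groups <- rule$require
    okReq <- all(vapply(groups, function(g)
      length(intersect(unlist(g), families)) > 0, logical(1)))
    okForb <- length(intersect(unlist(rule$forbid), families)) == 0
    if (okReq && okForb) return(rule$substrate)
  }
  "unknown"
}

## detections passing the microbial gate: >= minUnique unique peptides AND
## peptides mapping to exactly one genome (optionally a specific genome)
gatedDetections <- function(detections, minUnique = 2, genome = NULL) {
  if (is.null(detections) || nrow(detections) == 0) {
    return(character(0))
  }
  ok <- detections$unique_peptides >= minUnique &
    lengths(detections$genome_ids) == 1
  if (!is.null(genome)) {
    ok <- ok & vapply(detections$genome_ids,
                      function(g) identical(g, genome), logical(1))
  }
  unique(detections$protein_id[ok])
}

#' Flag proteomically expressed PULs
#'
#' A locus is expressed when at least one member gene has a proteomic
#' detection with \code{minUnique} (default two) or more unique peptides
#' whose peptides map to exactly one genome -- the locus's own.
#'
#' @param pulSet a \code{\linkS4class{PULCallSet}}.
#' @param detections detection table from
#'   \code{\link{readProteinDetections}}.
#' @param minUnique unique-peptide threshold (microbial default 2).
#' @return the \code{PULCallSet} with \code{expressed} and
#'   \code{detected_proteins} populated.
#' @export
flagExpression <- function(pulSet, detections, minUnique = 2) {
  df <- pulCalls(pulSet)
  if (nrow(df) == 0) return(pulSet)
  for (i in seq_len(nrow(df))) {
    gate <- gatedDetections(detections, minUnique = minUnique,
                            genome = df$genome_id[i])
    hit <- intersect(df$members[[i]], gate)
    df$detected_proteins[[i]] <- sort(hit)
    df$expressed[i] <- length(hit) > 0
  }
  new("PULCallSet", calls = df)
}
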