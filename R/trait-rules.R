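## Rule engine for genomic potential and proteomically expressed traits.
##
## Genomic potential:
##   * generic pathways (incl. respiration): present at >= 60% completeness
##   * rare 6C sugars (fucose, mannose, rhamnose): full monomer pathway AND
##     >= 6 of 9 EMP glycolysis members
##   * 5C sugars: specific isomerase AND epimerase AND full PPP
##   * fermentation end products: >= ceil(2/3 n) members of any one
##     alternative pathway
##   * cellulose: a full cellulosome (cohesin AND dockerin AND >= 1 cellulase
##     family)
## Expression requires genome-unique proteomic detections with two or more
## unique peptides (see gatedDetections in pul-detection.R).

#' Read the pathway rulebook
#'
#' @param path YAML rulebook path; the shipped default when NULL.
#' @return a named list (thresholds, pathways, sugars, fermentation,
#'   respiration, cellulose).
#' @export
readPathwayRulebook <- function(path = NULL) {
  path <- path %||% ruminetExtdata("pathways.yaml")
  rb <- yaml::read_yaml(path)
  if (is.null(rb$pathways$EMP) || is.null(rb$pathways$PPP))
    stop("pathway rulebook must define EMP and PPP")
  rb
}

#' Pathway completeness of a genome
#'
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param members character vector of pathway members
#'   (\code{"EC:"}/\code{"flag:"}/\code{"cazy:"} syntax).
#' @param threshold completeness fraction required for presence
#'   (default 0.60).
#' @return list with \code{fraction}, \code{present}, and the
#'   \code{found} member labels.
#' @export
pathwayCompleteness <- function(annotation, members, threshold = 0.60) {
  if (length(members) == 0) stop("empty pathway")
  g <- genes(annotation)
  found <- vapply(members, function(m) any(geneMatchesMember(g, m)),
                  logical(1))
  fraction <- sum(found) / length(members)
  list(fraction = fraction,
       present = fraction >= threshold - 1e-9,
       found = members[found])
}

## count of EMP members present plus per-member gene evidence
empCensus <- function(annotation, rulebook) {
  g <- genes(annotation)
  members <- rulebook$pathways$EMP$members
  present <- vapply(members, function(m) any(geneMatchesMember(g, m)),
                    logical(1))
  list(members = members, present = present, n = sum(present))
}

#' Encoded sugar-utilization traits of a genome
#'
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param rulebook from \code{\link{readPathwayRulebook}}.
#' @return character vector of encoded sugar traits.
#' @export
encodedSugarTraits <- function(annotation, rulebook = readPathwayRulebook()) {
  g <- genes(annotation)
  th <- rulebook$thresholds
  emp <- empCensus(annotation, rulebook)
  empOk <- emp$n >= (th$emp_min_present %||% 6)
  pppOk <- pathwayCompleteness(annotation, rulebook$pathways$PPP$members,
                               th$ppp_fraction %||% 1)$present
  out <- character(0)
  for (sugar in names(rulebook$sugars)) {
    def <- rulebook$sugars[[sugar]]
    enc <- switch(def$class,
      "6C_rare" = {
        mono <- rulebook$pathways[[def$monomer_pathway]]
        if (is.null(mono)) stop("unknown monomer pathway for ", sugar)
        pathwayCompleteness(annotation, mono$members,
                            th$rare_6c_fraction %||% 1)$present && empOk
      },
      "5C" = {
        any(geneMatchesMember(g, def$isomerase)) &&
          any(geneMatchesMember(g, def$epimerase)) && pppOk
      },
      "6C_common" = {
        any(geneMatchesMember(g, def$entry)) && empOk
      },
      stop("unknown sugar class: ", def$class))
    if (enc) out <- c(out, sugar)
  }
  out
}

#' Encoded fermentation end products of a genome
#'
#' A product is encoded when any one of its alternative pathways has at
#' least \eqn{\lceil 2n/3 \rceil} of its \eqn{n} members present.
#'
#' @inheritParams encodedSugarTraits
#' @return character vector of encoded SCFA/product traits.
#' @export
encodedFermentation <- function(annotation,
                                rulebook = readPathwayRulebook()) {
  g <- genes(annotation)
  out <- character(0)
  for (product in names(rulebook$fermentation)) {
    alts <- rulebook$fermentation[[product]]
    enc <- any(vapply(alts, function(members) {
      members <- unlist(members)
      nPresent <- sum(vapply(members, function(m)
        any(geneMatchesMember(g, m)), logical(1)))
      nPresent >= ceiling(2 * length(members) / 3 - 1e-9)
    }, logical(1)))
    if (enc) out <- c(out, product)
  }
  out
}

#' Encoded respiratory traits of a genome (generic 60% rule)
#'
#' @inheritParams encodedSugarTraits
#' @return character vector of encoded respiration traits.
#' @export
encodedRespiration <- function(annotation,
                               rulebook = readPathwayRulebook()) {
  th <- rulebook$thresholds$generic %||% 0.60
  names(which(vapply(rulebook$respiration, function(members)
    pathwayCompleteness(annotation, unlist(members), th)$present,
    logical(1))))
}

## free genes = genes outside every PUL call
freeGenes <- function(annotation, pulSet) {
  g <- genes(annotation)
  inPul <- unique(unlist(pulCalls(pulSet)$members))
  g[!g$gene_id %in% inPul, , drop = FALSE]
}

## do a gene set's normalized families satisfy a PUL substrate rule?
familiesSatisfyRule <- function(families, rule) {
  if (isTRUE(rule$peptidase_only)) return(FALSE)
  all(vapply(rule$require, function(grp)
    length(intersect(unlist(grp), families)) > 0, logical(1))) &&
    length(intersect(unlist(rule$forbid), families)) == 0
}

#' Encoded polymer-degradation traits of a genome
#'
#' A polymer is encoded when a PUL with that substrate label exists or when
#' the genome's free CAZymes (outside every PUL) satisfy the polymer's family
#' rule.  Cellulose requires a full cellulosome: cohesin and dockerin modules
#' plus at least one cellulase family.
#'
#' @inheritParams encodedSugarTraits
#' @param pulSet a \code{\linkS4class{PULCallSet}} for this genome.
#' @param pulRulebook from \code{\link{readPULRulebook}}.
#' @return character vector of encoded polymer traits.
#' @export
encodedPolymerTraits <- function(annotation, pulSet,
                                 pulRulebook = readPULRulebook(),
                                 rulebook = readPathwayRulebook()) {
  calls <- pulCalls(pulSet)
  g <- genes(annotation)
  free <- freeGenes(annotation, pulSet)
  freeFams <- unique(normalizeCazy(unlist(free$cazy)))
  out <- character(0)
  for (rule in pulRulebook) {
    if (isTRUE(rule$peptidase_only)) {
      if (rule$substrate %in% calls$substrate) out <- c(out, rule$substrate)
      next
    }
    if (rule$substrate %in% calls$substrate ||
        familiesSatisfyRule(freeFams, rule)) {
      out <- c(out, rule$substrate)
    }
  }
  celluFams <- rulebook$cellulose$cellulase_families %||%
    c("GH48", "GH9", "GH5")
  allFams <- unique(normalizeCazy(unlist(g$cazy)))
  if (any(hasFlag(g, "cohesin")) && any(hasFlag(g, "dockerin")) &&
      length(intersect(celluFams, allFams)) > 0) {
    out <- c(out, "cellulose")
  }
  out
}

## evidence genes backing one polymer trait: PUL members for that substrate
## plus free genes satisfying the rule; for cellulose, cellulosome modules
## and cellulase genes
polymerEvidenceGenes <- function(annotation, pulSet, substrate, pulRulebook,
                                 rulebook) {
  g <- genes(annotation)
  calls <- pulCalls(pulSet)
  if (substrate == "cellulose") {
    ## expression requires detection of a cellulosome module; free cellulase
    ## families are shared with other glucan mechanisms and are not
    ## cellulosome evidence on their own
    sel <- hasFlag(g, "cohesin") | hasFlag(g, "dockerin")
    return(g$gene_id[sel])
  }
  ev <- unlist(calls$members[calls$substrate == substrate])
  rule <- Filter(function(r) identical(r$substrate, substrate), pulRulebook)
  if (length(rule)) {
    rule <- rule[[1]]
    free <- freeGenes(annotation, pulSet)
    if (isTRUE(rule$peptidase_only)) {
      ev <- c(ev, free$gene_id[hasFlag(free, "peptidase")])
    } else {
      freeFams <- unique(normalizeCazy(unlist(free$cazy)))
      if (familiesSatisfyRule(freeFams, rule)) {
        ruleFams <- unlist(rule$require)
        sel <- vapply(free$cazy, function(cz)
          length(intersect(ruleFams, normalizeCazy(cz))) > 0, logical(1))
        ev <- c(ev, free$gene_id[sel])
      }
    }
  }
  unique(ev)
}

#' Full trait profile (encoded and expressed) for one genome
#'
#' Expression gates: a polymer trait is expressed when its PUL is expressed
#' or a gene of its degradation mechanism is detected; a sugar trait when its
#' specific isomerase/kinase is detected together with at least one
#' downstream EMP member; glucose additionally requires glucokinase or a
#' glucose-specific transporter (galactose enters the EMP pathway at the
#' glucose-6-phosphate isomerase step); an SCFA when any member of an
#' encoded product pathway is detected.  All detections must carry two or
#' more unique peptides mapping uniquely to this genome.
#'
#' @inheritParams encodedPolymerTraits
#' @param detections detection table (see
#'   \code{\link{readProteinDetections}}); NULL for none.
#' @param minUnique microbial unique-peptide threshold (default 2).
#' @return a \code{\linkS4class{TraitProfile}}.
#' @export
traitProfile <- function(annotation, pulSet, detections = NULL,
                         rulebook = readPathwayRulebook(),
                         pulRulebook = readPULRulebook(), minUnique = 2) {
  g <- genes(annotation)
  gid <- genomeId(annotation)
  gate <- gatedDetections(detections, minUnique = minUnique, genome = gid)
  detected <- function(geneIds) intersect(geneIds, gate)

  polymers <- encodedPolymerTraits(annotation, pulSet, pulRulebook, rulebook)
  sugars <- encodedSugarTraits(annotation, rulebook)
  scfa <- encodedFermentation(annotation, rulebook)
  resp <- encodedRespiration(annotation, rulebook)

  allPolymers <- c(vapply(pulRulebook, `[[`, character(1), "substrate"),
                   "cellulose")
  traits <- c(allPolymers, names(rulebook$sugars),
              names(rulebook$fermentation), names(rulebook$respiration))
  traitClass <- setNames(rep(c("polymer", "sugar", "scfa", "respiration"),
                             c(length(allPolymers),
                               length(rulebook$sugars),
                               length(rulebook$fermentation),
                               length(rulebook$respiration))), traits)
  encoded <- setNames(traits %in% c(polymers, sugars, scfa, resp), traits)
  expressed <- setNames(rep(FALSE, length(traits)), traits)
  evidence <- setNames(rep(list(character(0)), length(traits)), traits)

  calls <- pulCalls(pulSet)
  for (p in intersect(allPolymers, polymers)) {
    ev <- detected(polymerEvidenceGenes(annotation, pulSet, p, pulRulebook,
                                        rulebook))
    pulExpr <- any(calls$expressed[calls$substrate == p])
    if (pulExpr) {
      ev <- union(ev, unlist(calls$detected_proteins[calls$substrate == p &
                                                       calls$expressed]))
    }
    if (length(ev)) {
      expressed[p] <- TRUE
      evidence[[p]] <- sort(unique(ev))
    }
  }

  emp <- empCensus(annotation, rulebook)
  for (sugar in names(rulebook$sugars)) {
    def <- rulebook$sugars[[sugar]]
    entryGenes <- genesWithMember(g, def$entry)
    entryHit <- detected(entryGenes)
    if (!length(entryHit)) next
    extra <- def$extra_expressed
    if (!is.null(extra)) {
      extraHit <- detected(unique(unlist(lapply(extra, genesWithMember,
                                                genes = g))))
      if (!length(extraHit)) next
      ev <- c(entryHit, extraHit)
    } else {
      downstream <- setdiff(emp$members, def$entry)
      downHit <- detected(unique(unlist(lapply(downstream, genesWithMember,
                                               genes = g))))
      if (!length(downHit)) next
      ev <- c(entryHit, downHit)
    }
    expressed[sugar] <- TRUE
    evidence[[sugar]] <- sort(unique(ev))
  }

  for (product in intersect(names(rulebook$fermentation), scfa)) {
    alts <- rulebook$fermentation[[product]]
    for (members in alts) {
      members <- unlist(members)
      nPresent <- sum(vapply(members, function(m)
        any(geneMatchesMember(g, m)), logical(1)))
      if (nPresent < ceiling(2 * length(members) / 3 - 1e-9)) next
      hit <- detected(unique(unlist(lapply(members, genesWithMember,
                                           genes = g))))
      if (length(hit)) {
        expressed[product] <- TRUE
        evidence[[product]] <- sort(unique(c(evidence[[product]], hit)))
      }
    }
  }

  new("TraitProfile", genomeId = gid, encoded = encoded,
      expressed = expressed, evidence = evidence, traitClass = traitClass)
}
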