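## Bipartite genome-substrate trophic network: construction from expressed
## traits, hub detection, trophic-tier assignment and SCFA annotation.

#' Build the bipartite genome-substrate network
#'
#' One edge per (genome, expressed substrate trait); every edge carries the
#' evidence protein ids that support it.  Substrate nodes are marked as
#' measured when they appear in the metabolite panels (CoMPP polymers with
#' non-zero signal, sugars with non-zero concentration); an expressed trait
#' naming an unmeasured substrate still yields an edge but triggers a
#' warning and a \code{measured = FALSE} node attribute.
#'
#' @param profiles list of \code{\linkS4class{TraitProfile}} objects.
#' @param panel output of \code{\link{normalizeCoMPP}} (or NULL).
#' @param sugarPanel data.frame from \code{\link{readSugarPanel}} (or NULL).
#' @param coverage named numeric of genome coverages (node size).
#' @param taxonomy named character of genome taxonomy labels.
#' @param dropIsolated drop genomes with no expressed substrate (default
#'   TRUE).
#' @return a \code{\linkS4class{TrophicNetwork}}.
#' @export
buildNetwork <- function(profiles, panel = NULL, sugarPanel = NULL,
                         coverage = NULL, taxonomy = NULL,
                         dropIsolated = TRUE) {
  measuredPolymers <- character(0)
  if (!is.null(panel) && nrow(panel$values)) {
    measuredPolymers <- unique(panel$values$substrate[panel$values$signal > 0])
  }
  measuredSugars <- character(0)
  if (!is.null(sugarPanel) && nrow(sugarPanel)) {
    measuredSugars <- unique(sugarPanel$sugar[sugarPanel$concentration > 0])
  }
  measured <- c(measuredPolymers, measuredSugars)

  edges <- do.call(rbind, c(list(
    data.frame(genome = character(0), substrate = character(0),
               class = character(0), evidence = character(0),
               stringsAsFactors = FALSE)),
    lapply(profiles, function(p) {
      traits <- expressedTraits(p)
      traits <- traits[p@traitClass[traits] %in% c("polymer", "sugar")]
      if (!length(traits)) return(NULL)
      data.frame(genome = genomeId(p), substrate = traits,
                 class = unname(p@traitClass[traits]),
                 evidence = vapply(traits, function(t)
                   paste(p@evidence[[t]], collapse = ";"), character(1)),
                 stringsAsFactors = FALSE)
    })))

  unmeasured <- setdiff(unique(edges$substrate), measured)
  if (length(unmeasured) && length(measured)) {
    warning("expressed substrate(s) absent from metabolite panels: ",
            paste(unmeasured, collapse = ", "))
  }

  genomes <- vapply(profiles, genomeId, character(1))
  if (dropIsolated) genomes <- intersect(genomes, edges$genome)
  substrates <- sort(unique(edges$substrate))
  subClass <- setNames(edges$class[!duplicated(edges$substrate)],
                       edges$substrate[!duplicated(edges$substrate)])

  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(genomes), name = genomes,
                            type = FALSE)
  g <- igraph::add_vertices(g, length(substrates), name = substrates,
                            type = TRUE)
  v <- igraph::V(g)
  cov <- rep(NA_real_, length(v))
  tax <- rep(NA_character_, length(v))
  if (!is.null(coverage)) cov[match(genomes, v$name)] <- coverage[genomes]
  if (!is.null(taxonomy)) tax[match(genomes, v$name)] <- taxonomy[genomes]
  g <- igraph::set_vertex_attr(g, "coverage", value = cov)
  g <- igraph::set_vertex_attr(g, "taxonomy", value = tax)
  cls <- rep(NA_character_, length(v))
  cls[match(substrates, v$name)] <- unname(subClass[substrates])
  g <- igraph::set_vertex_attr(g, "class", value = cls)
  meas <- rep(NA, length(v))
  meas[match(substrates, v$name)] <- substrates %in% measured
  g <- igraph::set_vertex_attr(g, "measured", value = meas)

  edges <- edges[edges$genome %in% genomes, , drop = FALSE]
  edges <- edges[order(edges$genome, edges$substrate), , drop = FALSE]
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$genome, edges$substrate),
                           evidence = edges$evidence)
  }
  net <- new("TrophicNetwork", graph = g)
  validObject(net)
  net
}

#' Metabolic hub genomes
#'
#' Hubs are genome nodes co-expressing utilization of \code{minConnections}
#' (default six) or more substrates, i.e. with network degree at or above the
#' threshold.
#'
#' @param network a \code{\linkS4class{TrophicNetwork}}.
#' @param minConnections hub threshold (default 6).
#' @return character vector of hub genome ids.
#' @export
findHubs <- function(network, minConnections = 6) {
  g <- networkGraph(network)
  v <- igraph::V(g)
  deg <- igraph::degree(g)
  sort(v$name[!v$type & deg >= minConnections])
}

#' Assign trophic tiers to genome nodes
#'
#' Tier 1: all incident substrates are recalcitrant polymers; tier 3: all
#' incident substrates are sugars (exclusive sugar fermentation); tier 2:
#' everything else (mixed polymer degradation and sugar fermentation,
#' including non-recalcitrant polymer use).  Isolated genomes are left
#' unassigned.
#'
#' @param network a \code{\linkS4class{TrophicNetwork}}.
#' @param recalcitrant substrate names counted as recalcitrant polymers
#'   (default cellulose and xyloglucan).
#' @return named integer vector, genome id to tier in \{1, 2, 3\}.
#' @export
assignTrophicTiers <- function(network,
                               recalcitrant = c("cellulose", "xyloglucan")) {
  g <- networkGraph(network)
  v <- igraph::V(g)
  genomes <- v$name[!v$type]
  tiers <- integer(0)
  for (gn in genomes) {
    nb <- igraph::neighbors(g, gn)
    if (length(nb) == 0) next
    classes <- nb$class
    names(classes) <- nb$name
    tier <- if (all(classes == "polymer" & names(classes) %in% recalcitrant)) {
      1L
    } else if (all(classes == "sugar")) {
      3L
    } else {
      2L
    }
    tiers[gn] <- tier
  }
  tiers
}

#' Annotate a network with hub, tier and SCFA-star attributes
#'
#' The SCFA star marks genomes with proteomic evidence for short-chain fatty
#' acid production (any expressed fermentation trait).
#'
#' @param network a \code{\linkS4class{TrophicNetwork}}.
#' @param profiles list of \code{\linkS4class{TraitProfile}} objects.
#' @param minConnections hub threshold (default 6).
#' @param recalcitrant see \code{\link{assignTrophicTiers}}.
#' @return the annotated \code{TrophicNetwork}.
#' @export
annotateNetwork <- function(network, profiles, minConnections = 6,
                            recalcitrant = c("cellulose", "xyloglucan")) {
  g <- networkGraph(network)
  v <- igraph::V(g)
  hubs <- findHubs(network, minConnections)
  tiers <- assignTrophicTiers(network, recalcitrant)
  scfaOn <- vapply(profiles, function(p)
    any(p@expressed[names(p@traitClass)[p@traitClass == "scfa"]],
        na.rm = TRUE), logical(1))
  names(scfaOn) <- vapply(profiles, genomeId, character(1))

  hub <- ifelse(v$type, NA, v$name %in% hubs)
  tier <- rep(NA_integer_, length(v))
  tier[match(names(tiers), v$name)] <- tiers
  star <- rep(NA, length(v))
  idx <- match(intersect(names(scfaOn), v$name[!v$type]), v$name)
  star[idx] <- unname(scfaOn[v$name[idx]])
  g <- igraph::set_vertex_attr(g, "hub", value = hub)
  g <- igraph::set_vertex_attr(g, "tier", value = tier)
  g <- igraph::set_vertex_attr(g, "scfa_star", value = star)
  rec <- ifelse(v$type, v$name %in% recalcitrant, NA)
  g <- igraph::set_vertex_attr(g, "recalcitrant", value = rec)
  new("TrophicNetwork", graph = g)
}
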