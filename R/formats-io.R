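## Readers and writers for every external representation the pipeline
## touches: GFF3 + annotation TSV, proteomic detection TSV, metabolite CSVs,
## and the deterministic report files (TSV, GraphML).

#' Default derived-flag configuration
#'
#' Controls how annotation keywords are derived from Pfam accessions and
#' product strings when gene tables are read.  SusD-like genes are recognized
#' by the four dedicated Pfam families; SusC has no dedicated Pfam in common
#' annotation practice, so it is recognized as a TonB-dependent receptor by
#' product keyword or by the plug/barrel Pfams PF07715/PF00593 (configurable).
#' Peptidase, cohesin and dockerin default to keyword matches; sugar-specific
#' transporters are flagged \code{transporter:<sugar>} from the product.
#'
#' @return a named list of character vectors / regular expressions.
#' @export
defaultFlagConfig <- function() {
  list(susD_pfams = c("PF07980", "PF12741", "PF12771", "PF14322"),
       susC_pfams = c("PF00593", "PF07715"),
       susC_keywords = "susc|tonb-dependent receptor",
       peptidase_keywords = "peptidase|protease",
       peptidase_pfams = character(0),
       cohesin_keywords = "cohesin", cohesin_pfams = "PF00963",
       dockerin_keywords = "dockerin", dockerin_pfams = "PF00404",
       transporter_sugars = c("glucose", "galactose", "xylose", "arabinose",
                              "mannose", "fucose", "rhamnose"))
}

#' Derive controlled annotation flags from Pfam sets and product labels
#'
#' Pure function of (pfam, product); reapplying it never changes the result.
#'
#' @param pfam list of character vectors of Pfam accessions (one per gene).
#' @param product character vector of product labels.
#' @param config see \code{\link{defaultFlagConfig}}.
#' @return list of character vectors of flags, one per gene.
#' @export
deriveFlags <- function(pfam, product, config = defaultFlagConfig()) {
  product <- ifelse(is.na(product), "", product)
  prodLow <- tolower(product)
  mapply(function(pf, pl) {
    flags <- character(0)
    if (any(pf %in% config$susD_pfams)) flags <- c(flags, "susD")
    if (any(pf %in% config$susC_pfams) || grepl(config$susC_keywords, pl)) {
      flags <- c(flags, "susC", "tonB_receptor")
    }
    if (any(pf %in% config$peptidase_pfams) ||
        grepl(config$peptidase_keywords, pl)) {
      flags <- c(flags, "peptidase")
    }
    if (any(pf %in% config$cohesin_pfams) ||
        grepl(config$cohesin_keywords, pl)) {
      flags <- c(flags, "cohesin")
    }
    if (any(pf %in% config$dockerin_pfams) ||
        grepl(config$dockerin_keywords, pl)) {
      flags <- c(flags, "dockerin")
    }
    for (sugar in config$transporter_sugars) {
      if (grepl(paste0(sugar, "[ -]specific transporter|",
                       sugar, " transporter"), pl)) {
        flags <- c(flags, paste0("transporter:", sugar))
      }
    }
    unique(flags)
  }, pfam, prodLow, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Assign 0-based dense ordinals per scaffold
#'
#' Genes are ranked along each scaffold by (start, end, gene_id); the
#' operation is idempotent and row order in the result follows the ordinals.
#'
#' @param genes a gene table.
#' @return the gene table, sorted, with a dense 0-based \code{ordinal}.
#' @export
assignOrdinals <- function(genes) {
  if (nrow(genes) == 0) {
    genes$ordinal <- integer(0)
    return(genes)
  }
  ord <- order(genes$scaffold_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- as.integer(stats::ave(genes$start, genes$scaffold_id,
                                         FUN = function(x) seq_along(x) - 1L))
  rownames(genes) <- NULL
  genes
}

#' Read one genome's GFF3 gene calls plus its functional annotation table
#'
#' CDS features are taken from the GFF3 (the \code{ID} attribute is the gene
#' id); the annotation table is a TSV keyed by \code{gene_id} with
#' \code{;}-separated \code{pfam}, \code{cazy} and \code{ec} columns and a
#' free-text \code{product}.  Genes with no annotation row get empty sets.
#' Controlled flags (susC/susD/peptidase/cohesin/dockerin/transporter) are
#' derived at read time and are a pure function of (pfam, product).
#'
#' @param gffFile path to a GFF3 file with CDS features.
#' @param annotationFile path to the annotation TSV (NULL for none).
#' @param genomeId genome id; defaults to the GFF3 file stem.
#' @param taxonomy,completeness,coverage bin metadata.
#' @param flagConfig see \code{\link{defaultFlagConfig}}.
#' @return a \code{\linkS4class{GenomeAnnotation}}.
#' @export
readGenomeAnnotations <- function(gffFile, annotationFile = NULL,
                                  genomeId = NULL, taxonomy = NA_character_,
                                  completeness = 100, coverage = 1,
                                  flagConfig = defaultFlagConfig()) {
  if (is.null(genomeId)) {
    genomeId <- sub("\\.(gff3?|gff)$", "", basename(gffFile))
  }
  gr <- rtracklayer::import(gffFile, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr)) {
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(!nzchar(ids)))
      stop("CDS feature without an ID attribute in ", gffFile)
    if (anyDuplicated(ids))
      stop("duplicate gene id in ", gffFile, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    genes <- data.frame(gene_id = ids, genome_id = genomeId,
                        scaffold_id = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  } else {
    genes <- emptyGeneTable()
  }
  ## scaffold lengths come from the ##sequence-region pragma when present,
  ## else fall back to the rightmost gene end
  pragma <- grep("^##sequence-region", readLines(gffFile), value = TRUE)
  scaffoldLengths <- numeric(0)
  if (length(pragma)) {
    parts <- strsplit(trimws(pragma), "[ \t]+")
    scaffoldLengths <- vapply(parts, function(p) as.numeric(p[4]),
                              numeric(1))
    names(scaffoldLengths) <- vapply(parts, `[`, character(1), 2)
  }
  if (nrow(genes)) {
    missing <- setdiff(unique(genes$scaffold_id), names(scaffoldLengths))
    if (length(missing)) {
      inferred <- vapply(missing, function(sc)
        max(genes$end[genes$scaffold_id == sc]), numeric(1))
      scaffoldLengths <- c(scaffoldLengths, inferred)
    }
  }

  ann <- NULL
  if (!is.null(annotationFile)) {
    ann <- read.delim(annotationFile, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("gene_id", "pfam", "cazy", "ec", "product")
    miss <- setdiff(need, names(ann))
    if (length(miss))
      stop("annotation table missing column(s): ",
           paste(miss, collapse = ", "))
    unknown <- !ann$gene_id %in% genes$gene_id
    if (any(unknown)) {
      warning(sum(unknown), " annotation row(s) with unknown gene id dropped")
      ann <- ann[!unknown, , drop = FALSE]
    }
  }
  n <- nrow(genes)
  genes$product <- rep(NA_character_, n)
  genes$pfam <- rep(list(character(0)), n)
  genes$cazy <- rep(list(character(0)), n)
  genes$ec <- rep(list(character(0)), n)
  if (!is.null(ann) && nrow(ann)) {
    idx <- match(ann$gene_id, genes$gene_id)
    genes$product[idx] <- ifelse(nzchar(ann$product), ann$product,
                                 NA_character_)
    genes$pfam[idx] <- splitSemi(ann$pfam)
    genes$cazy[idx] <- splitSemi(ann$cazy)
    genes$ec[idx] <- splitSemi(ann$ec)
  }
  genes <- assignOrdinals(genes)
  genes$flags <- deriveFlags(genes$pfam, genes$product, flagConfig)
  GenomeAnnotation(genomeId = genomeId, genes = genes,
                   scaffoldLengths = scaffoldLengths, taxonomy = taxonomy,
                   completeness = completeness, coverage = coverage)
}

#' Write a gene table as GFF3 plus its annotation TSV
#'
#' Inverse of \code{\link{readGenomeAnnotations}}; used by the synthetic
#' community generator and for round-trip testing.
#'
#' @param annotation a \code{GenomeAnnotation}.
#' @param gffFile,annotationFile output paths.
#' @export
writeGenomeAnnotations <- function(annotation, gffFile, annotationFile) {
  genes <- genes(annotation)
  sl <- scaffoldLengths(annotation)
  if (nrow(genes)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$scaffold_id,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      strand = genes$strand)
    gr$type <- "CDS"
    gr$ID <- genes$gene_id
    gr$phase <- 0L
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- as.integer(sl)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gffFile, format = "gff3")
  ann <- data.frame(gene_id = genes$gene_id,
                    pfam = joinSemi(genes$pfam),
                    cazy = joinSemi(genes$cazy),
                    ec = joinSemi(genes$ec),
                    product = ifelse(is.na(genes$product), "",
                                     genes$product),
                    stringsAsFactors = FALSE)
  writeTsv(ann, annotationFile)
  invisible(annotation)
}

#' Read a metaproteomic detection table
#'
#' TSV with columns \code{protein_id}, \code{genome_ids} (\code{;}-separated
#' genome ids the detected peptides map to), \code{unique_peptides} and
#' \code{spectral_count}.
#'
#' @param path input TSV path.
#' @return data.frame with a list-column \code{genome_ids}.
#' @export
readProteinDetections <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "genome_ids", "unique_peptides", "spectral_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("detection table missing column(s): ", paste(miss, collapse = ", "))
  df$unique_peptides <- as.integer(df$unique_peptides)
  df$spectral_count <- as.integer(df$spectral_count)
  if (anyNA(df$unique_peptides) || any(df$unique_peptides < 0))
    stop("unique_peptides must be a non-negative integer")
  if (anyNA(df$spectral_count) || any(df$spectral_count < 0))
    stop("spectral_count must be a non-negative integer")
  df$genome_ids <- splitSemi(as.character(df$genome_ids))
  if (any(lengths(df$genome_ids) == 0))
    stop("detection row with empty genome_ids")
  df
}

#' @rdname readProteinDetections
#' @param detections a detection data.frame.
#' @export
writeProteinDetections <- function(detections, path) {
  out <- data.frame(protein_id = detections$protein_id,
                    genome_ids = joinSemi(detections$genome_ids),
                    unique_peptides = detections$unique_peptides,
                    spectral_count = detections$spectral_count,
                    stringsAsFactors = FALSE)
  writeTsv(out, path)
}

#' Read raw CoMPP microarray signals
#'
#' CSV with columns \code{probe}, \code{substrate}, \code{extraction}
#' (CDTA or NaOH), \code{sample}, \code{replicate}, \code{signal}.
#'
#' @param path input CSV path.
#' @return data.frame of raw signals.
#' @export
readCoMPP <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe", "substrate", "extraction", "sample", "replicate",
            "signal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CoMPP table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a sugar concentration panel
#'
#' CSV with columns \code{sugar}, \code{class} (5C or 6C) and
#' \code{concentration} (mM, >= 0).
#'
#' @param path input CSV path.
#' @return data.frame of sugar concentrations.
#' @export
readSugarPanel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sugar", "class", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sugar table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$concentration < 0)) stop("negative sugar concentration")
  df
}

## ------------------------------------------------------------- reports

#' Serialize PUL calls to the standard report table
#'
#' One row per locus: genome, scaffold, gene span, CAZy gene order, substrate
#' call, and the identity of locus proteins detected in the metaproteome.
#'
#' @param pulSet a \code{\linkS4class{PULCallSet}}.
#' @return data.frame in stable order (genome, scaffold, pul id).
#' @export
pulReportTable <- function(pulSet) {
  df <- pulCalls(pulSet)
  out <- data.frame(pul_id = df$pul_id, genome = df$genome_id,
                    scaffold = df$scaffold_id,
                    gene_span = if (nrow(df))
                      paste0(df$start, "-", df$end) else character(0),
                    strand = df$strand,
                    n_genes = lengths(df$members),
                    cazy_gene_order = joinSemi(df$cazy_order),
                    substrate = df$substrate,
                    expressed = df$expressed,
                    n_detected = lengths(df$detected_proteins),
                    detected_proteins = joinSemi(df$detected_proteins),
                    stringsAsFactors = FALSE)
  out[order(out$genome, out$scaffold, out$pul_id), , drop = FALSE]
}

#' Serialize trait profiles to a long table
#'
#' @param profiles list of \code{\linkS4class{TraitProfile}} objects.
#' @return data.frame (genome_id, trait, class, encoded, expressed, evidence).
#' @export
traitReportTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    traits <- union(names(p@encoded), names(p@expressed))
    if (!length(traits)) return(NULL)
    data.frame(genome_id = p@genomeId, trait = traits,
               class = unname(p@traitClass[traits]),
               encoded = unname(p@encoded[traits]),
               expressed = ifelse(is.na(p@expressed[traits]), FALSE,
                                  unname(p@expressed[traits])),
               evidence = vapply(traits, function(t)
                 paste(p@evidence[[t]], collapse = ";"), character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(genome_id = character(0), trait = character(0),
               class = character(0), encoded = logical(0),
               expressed = logical(0), evidence = character(0),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out[order(out$genome_id, out$trait), , drop = FALSE]
}

#' Serialize a trophic network to node and edge tables
#'
#' @param network a \code{\linkS4class{TrophicNetwork}}.
#' @return list with \code{nodes} and \code{edges} data.frames
#'   (Cytoscape-compatible).
#' @export
networkTables <- function(network) {
  g <- networkGraph(network)
  v <- igraph::V(g)
  if (length(v) == 0) {
    return(list(
      nodes = data.frame(node = character(0), kind = character(0),
                         class = character(0), coverage = numeric(0),
                         taxonomy = character(0), tier = integer(0),
                         hub = logical(0), scfa_star = logical(0),
                         recalcitrant = logical(0), measured = logical(0),
                         degree = numeric(0), stringsAsFactors = FALSE),
      edges = data.frame(genome = character(0), substrate = character(0),
                         evidence = character(0),
                         stringsAsFactors = FALSE)))
  }
  nodes <- data.frame(
    node = v$name,
    kind = ifelse(v$type, "substrate", "genome"),
    class = v$class %||% rep(NA_character_, length(v)),
    coverage = v$coverage %||% rep(NA_real_, length(v)),
    taxonomy = v$taxonomy %||% rep(NA_character_, length(v)),
    tier = v$tier %||% rep(NA_integer_, length(v)),
    hub = v$hub %||% rep(NA, length(v)),
    scfa_star = v$scfa_star %||% rep(NA, length(v)),
    recalcitrant = v$recalcitrant %||% rep(NA, length(v)),
    measured = v$measured %||% rep(NA, length(v)),
    degree = igraph::degree(g),
    stringsAsFactors = FALSE)
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(genome = el[, 1], substrate = el[, 2],
                        evidence = igraph::E(g)$evidence,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(genome = character(0), substrate = character(0),
                        evidence = character(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$kind, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$genome, edges$substrate), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Write all pipeline reports to a directory
#'
#' Emits deterministic TSV reports (PULs, traits, network nodes/edges, host
#' links) plus a GraphML rendering of the trophic network.  Any input may be
#' NULL or empty, producing headers-only files; writing the same inputs twice
#' yields byte-identical files.
#'
#' @param pulSet a \code{PULCallSet} or NULL.
#' @param profiles list of \code{TraitProfile} or NULL.
#' @param network a \code{TrophicNetwork} or NULL.
#' @param hostLinks host-link data.frame or NULL.
#' @param outDir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeOutputs <- function(pulSet = NULL, profiles = NULL, network = NULL,
                         hostLinks = NULL, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  files <- character(0)
  pulSet <- pulSet %||% new("PULCallSet", calls = emptyPULTable())
  f <- file.path(outDir, "puls.tsv")
  writeTsv(pulReportTable(pulSet), f)
  files <- c(files, f)

  f <- file.path(outDir, "traits.tsv")
  writeTsv(traitReportTable(profiles %||% list()), f)
  files <- c(files, f)

  if (is.null(network)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::set_vertex_attr(g, "type", value = logical(0))
    network <- new("TrophicNetwork", graph = g)
  }
  tabs <- networkTables(network)
  f1 <- file.path(outDir, "network_nodes.tsv")
  f2 <- file.path(outDir, "network_edges.tsv")
  writeTsv(tabs$nodes, f1)
  writeTsv(tabs$edges, f2)
  f3 <- file.path(outDir, "network.graphml")
  igraph::write_graph(networkGraph(network), f3, format = "graphml")
  files <- c(files, f1, f2, f3)

  hostLinks <- hostLinks %||% emptyHostLinkTable()
  hostLinks <- hostLinks[order(hostLinks$virus_id, hostLinks$genome_id), ,
                         drop = FALSE]
  f <- file.path(outDir, "host_links.tsv")
  writeTsv(hostLinks, f)
  files <- c(files, f)
  invisible(files)
}
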