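options(ruminet.quiet = TRUE)

## Fixture builders and independent brute-force oracles used across the
## suite.  Oracles are deliberately written as plain loops, independent of
## the implementation they check.

## build a gene table from per-gene annotations; positions are 1-based gene
## indices (gene i sits at ordinal i - 1)
buildGenes <- function(strand, susC = integer(0), susD = integer(0),
                       cazy = list(), pept = integer(0), ec = list(),
                       product = NULL, genome = "G1", scaffold = "s1") {
  n <- length(strand)
  prod <- rep("hypothetical protein", n)
  pfam <- rep(list(character(0)), n)
  czy <- rep(list(character(0)), n)
  ecs <- rep(list(character(0)), n)
  prod[susC] <- "TonB-dependent receptor"
  for (i in susD) pfam[[i]] <- "PF07980"
  for (nm in names(cazy)) czy[[as.integer(nm)]] <- cazy[[nm]]
  prod[pept] <- "peptidase family protein"
  for (nm in names(ec)) ecs[[as.integer(nm)]] <- ec[[nm]]
  if (!is.null(product)) {
    for (nm in names(product)) prod[as.integer(nm)] <- product[[nm]]
  }
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                   genome_id = genome, scaffold_id = scaffold,
                   start = (seq_len(n) - 1L) * 1000L + 1L,
                   end = (seq_len(n) - 1L) * 1000L + 901L,
                   strand = strand, ordinal = seq_len(n) - 1L,
                   product = prod, stringsAsFactors = FALSE)
  df$pfam <- pfam
  df$cazy <- czy
  df$ec <- ecs
  df$flags <- deriveFlags(pfam, prod)
  df
}

annotationFromGenes <- function(genes, genome = "G1", coverage = 1) {
  GenomeAnnotation(genome, genes, coverage = coverage)
}

## detection row constructor
makeDetections <- function(protein_id, genome_ids, unique_peptides,
                           spectral_count = unique_peptides * 2) {
  df <- data.frame(protein_id = protein_id,
                   unique_peptides = unique_peptides,
                   spectral_count = spectral_count,
                   stringsAsFactors = FALSE)
  df$genome_ids <- if (is.list(genome_ids)) genome_ids else
    as.list(genome_ids)
  df
}

## random annotated scaffold for property tests
randomGeneTable <- function(n, pSusD = 0.06, pSusC = 0.1, pCazy = 0.15,
                            pPept = 0.04, genome = "G1") {
  strand <- sample(c("+", "-"), n, replace = TRUE)
  susD <- which(runif(n) < pSusD)
  susC <- setdiff(which(runif(n) < pSusC), susD)
  pool <- setdiff(seq_len(n), c(susD, susC))
  cazyIdx <- pool[runif(length(pool)) < pCazy]
  fams <- c("GH5", "GH3", "GH13", "GH26", "GH43", "GH10", "GH16", "GH30",
            "GH97", "GH130", "PL1", "CE7", "GH5_4")
  cazy <- setNames(lapply(cazyIdx, function(i)
    sample(fams, sample(1:2, 1))), cazyIdx)
  peptIdx <- setdiff(pool, cazyIdx)
  pept <- peptIdx[runif(length(peptIdx)) < pPept]
  buildGenes(strand, susC = susC, susD = susD, cazy = cazy, pept = pept,
             genome = genome)
}

## ---- oracle: SusC/SusD pairing by exhaustive scan
oraclePairs <- function(genes, gap = 2) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    if (!"susD" %in% genes$flags[[i]]) next
    best <- NULL
    bestD <- Inf
    for (j in seq_len(nrow(genes))) {
      if (j == i) next
      fl <- genes$flags[[j]]
      if (!any(c("susC", "tonB_receptor") %in% fl)) next
      if (genes$scaffold_id[j] != genes$scaffold_id[i]) next
      if (genes$strand[j] != genes$strand[i]) next
      d <- abs(genes$ordinal[j] - genes$ordinal[i])
      if (d > gap) next
      if (d < bestD ||
          (d == bestD && genes$ordinal[j] < genes$ordinal[best])) {
        best <- j
        bestD <- d
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- c(susC = genes$gene_id[best],
                                  susD = genes$gene_id[i])
    }
  }
  out
}

## ---- oracle: full locus calling by exhaustive window scan + merging;
## returns a list of sorted member gene-id vectors, one per merged locus
oraclePULMembers <- function(genes, gap = 2, window = 6) {
  pairs <- oraclePairs(genes, gap)
  if (!length(pairs)) return(list())
  sets <- lapply(pairs, function(p) {
    i <- which(genes$gene_id == p[["susD"]])
    j <- which(genes$gene_id == p[["susC"]])
    lo <- min(genes$ordinal[c(i, j)])
    hi <- max(genes$ordinal[c(i, j)])
    members <- character(0)
    for (k in seq_len(nrow(genes))) {
      if (genes$scaffold_id[k] != genes$scaffold_id[i]) next
      if (genes$strand[k] != genes$strand[i]) next
      if (genes$ordinal[k] >= lo - window && genes$ordinal[k] <= hi + window)
        members <- c(members, genes$gene_id[k])
    }
    list(strand = genes$strand[i], scaffold = genes$scaffold_id[i],
         members = members)
  })
  ## merge intersecting same-strand/scaffold member sets to a fixed point
  absorbed <- rep(FALSE, length(sets))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (x in seq_along(sets)) {
      if (absorbed[x]) next
      for (y in seq_along(sets)) {
        if (y == x || absorbed[y]) next
        if (sets[[x]]$strand == sets[[y]]$strand &&
            sets[[x]]$scaffold == sets[[y]]$scaffold &&
            length(intersect(sets[[x]]$members, sets[[y]]$members))) {
          sets[[x]]$members <- union(sets[[x]]$members, sets[[y]]$members)
          absorbed[y] <- TRUE
          changed <- TRUE
        }
      }
    }
  }
  sets <- sets[!absorbed]
  out <- lapply(sets, function(s) sort(s$members))
  out[order(vapply(out, `[`, character(1), 1))]
}

## ---- oracle: connected components by BFS
bfsComponents <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    comp <- integer(0)
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (w in which(adj[v, ])) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(rownames(adj)[comp])
  }
  comps[order(vapply(comps, min, character(1)))]
}

## ---- oracle: naive 4-mer counting
naiveTNF <- function(seqChr, collapse = TRUE) {
  n <- nchar(seqChr)
  counts <- new.env()
  for (i in seq_len(n - 3)) {
    w <- substr(seqChr, i, i + 3)
    if (grepl("[^ACGT]", w)) next
    counts[[w]] <- (counts[[w]] %||% 0) + 1
  }
  v <- unlist(as.list(counts))
  if (collapse) {
    rcMap <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(
      x, "")[[1]]), collapse = ""))
    canon <- vapply(names(v), function(k) min(k, rcMap(k)), character(1))
    v <- vapply(split(v, canon), sum, numeric(1))
  }
  v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- oracle: naive protospacer scan (both strands, positionwise)
naiveSpacerHits <- function(spacer, contigChr, maxMismatch = 1) {
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(spacer, "")[[1]]), collapse = ""))
  best <- Inf
  for (pat in c(spacer, rc)) {
    pl <- nchar(pat)
    pChars <- utf8ToInt(pat)
    for (i in seq_len(nchar(contigChr) - pl + 1)) {
      mm <- sum(utf8ToInt(substr(contigChr, i, i + pl - 1)) != pChars)
      if (mm < best) best <- mm
      if (best == 0) break
    }
    if (best == 0) break
  }
  if (best <= maxMismatch) best else NA_real_
}

## ---- shared synthetic community (noise-free study conditions), generated
## once per test session
sharedCommunity <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$dir)) {
      dir <- file.path(tempdir(), "ruminet-shared-community")
      cfg <- communityConfig(sharedProteinFraction = 0,
                             onePeptideFraction = 0, seed = 42)
      truth <- generateCommunity(cfg, dir)
      cache$dir <- dir
      cache$truth <- truth
      cache$config <- cfg
    }
    list(dir = cache$dir, truth = cache$truth, config = cache$config)
  }
})

## analysis products on the shared community, computed once
sharedAnalysis <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$res)) {
      comm <- sharedCommunity()
      det <- readProteinDetections(file.path(comm$dir, "proteomics",
                                             "detections.tsv"))
      meta <- read.delim(file.path(comm$dir, "metadata.tsv"),
                         stringsAsFactors = FALSE)
      annotations <- lapply(meta$genome_id, function(g)
        readGenomeAnnotations(
          file.path(comm$dir, "genomes", paste0(g, ".gff3")),
          file.path(comm$dir, "genomes", paste0(g, "_annotation.tsv")),
          genomeId = g, coverage =
            meta$coverage[meta$genome_id == g]))
      names(annotations) <- meta$genome_id
      pulSets <- lapply(annotations, function(a)
        flagExpression(callPULs(a), det))
      profiles <- lapply(meta$genome_id, function(g)
        traitProfile(annotations[[g]], pulSets[[g]], det))
      names(profiles) <- meta$genome_id
      cache$res <- list(detections = det, meta = meta,
                        annotations = annotations, pulSets = pulSets,
                        profiles = profiles)
    }
    cache$res
  }
})
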