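## Genome bin dereplication: anchored k-mer similarity, single-linkage
## grouping at >50% similarity, and single-copy-gene scoring of
## representatives.

#' Pairwise genome similarity (aligned fraction at >= 98% identity)
#'
#' The query genome is tiled into windows; each window is anchored in the
#' subject by exact k-mer seeds and extended gaplessly at the anchored
#' offset.  A window counts as aligned when its best anchored identity is at
#' least \code{minIdentity}.  The returned value is the fraction of the
#' query's total scaffold length covered by aligned windows ("similarity
#' level"); \code{symmetric = TRUE} returns the maximum of the two
#' directions.
#'
#' @param a,b \code{DNAStringSet} scaffold sets of the two genomes.
#' @param minIdentity identity cut for a window to count (default 0.98).
#' @param window window size in bp (default 500).
#' @param seedLen exact seed length (default 21).
#' @param seedsPerWindow anchors attempted per window (default 5).
#' @param symmetric return \code{max(a->b, b->a)} (default FALSE).
#' @return aligned fraction in [0, 1].
#' @export
pairwiseSimilarity <- function(a, b, minIdentity = 0.98, window = 500,
                               seedLen = 21, seedsPerWindow = 5,
                               symmetric = FALSE) {
  if (symmetric) {
    return(max(pairwiseSimilarity(a, b, minIdentity, window, seedLen,
                                  seedsPerWindow, symmetric = FALSE),
               pairwiseSimilarity(b, a, minIdentity, window, seedLen,
                                  seedsPerWindow, symmetric = FALSE)))
  }
  if (length(a) == 0 || sum(Biostrings::width(a)) == 0)
    stop("empty query genome")
  if (is.list(b) && !is.null(b$subjKmers)) {
    idx <- b
  } else {
    if (length(b) == 0 || sum(Biostrings::width(b)) == 0)
      stop("empty subject genome")
    idx <- subjectIndex(b, seedLen)
  }
  simCore(a, idx, minIdentity, window, seedLen, seedsPerWindow)
}

## concatenate a subject genome with N separators (so alignments cannot span
## scaffold boundaries) and index its exact k-mers for seed lookup
subjectIndex <- function(b, seedLen = 21) {
  subj <- paste(vapply(as.character(b), identity, character(1)),
                collapse = strrep("N", seedLen))
  nSubj <- nchar(subj)
  list(subjChars = utf8ToInt(subj), nSubj = nSubj,
       subjKmers = substring(subj, seq_len(nSubj - seedLen + 1),
                             seq_len(nSubj - seedLen + 1) + seedLen - 1))
}

simCore <- function(a, idx, minIdentity, window, seedLen, seedsPerWindow) {
  subjChars <- idx$subjChars
  subjKmers <- idx$subjKmers
  nSubj <- idx$nSubj
  totalLen <- 0
  alignedLen <- 0
  for (seqChr in as.character(a)) {
    L <- nchar(seqChr)
    totalLen <- totalLen + L
    for (s in seq(1, L, by = window)) {
      e <- min(s + window - 1, L)
      wlen <- e - s + 1
      if (wlen < seedLen) next
      wChars <- utf8ToInt(substr(seqChr, s, e))
      offs <- unique(round(seq(1, wlen - seedLen + 1,
                               length.out = min(seedsPerWindow,
                                                wlen - seedLen + 1))))
      seeds <- substring(seqChr, s + offs - 1, s + offs + seedLen - 2)
      hits <- match(seeds, subjKmers)
      best <- 0
      for (k in seq_along(offs)) {
        h <- hits[k]
        if (is.na(h)) next
        alnStart <- h - (offs[k] - 1)
        if (alnStart < 1 || alnStart + wlen - 1 > nSubj) next
        mism <- sum(wChars != subjChars[alnStart:(alnStart + wlen - 1)])
        ident <- 1 - mism / wlen
        if (ident > best) best <- ident
        if (best >= minIdentity) break
      }
      if (best >= minIdentity - 1e-12) alignedLen <- alignedLen + wlen
    }
  }
  alignedLen / totalLen
}

#' Group genomes by single linkage over a similarity matrix
#'
#' Connected components of the graph whose edges join genome pairs with
#' similarity strictly greater than \code{threshold}.
#'
#' @param similarity square symmetric numeric matrix with genome ids as
#'   dimnames.
#' @param threshold grouping cut (default 0.5, i.e. ">50% similarity").
#' @return list of character vectors, one per group.
#' @export
groupGenomes <- function(similarity, threshold = 0.5) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity))
    stop("similarity must be a square matrix")
  if (is.null(rownames(similarity)))
    rownames(similarity) <- colnames(similarity) <-
      paste0("G", seq_len(nrow(similarity)))
  adj <- similarity > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  out <- split(names(comp), comp)
  names(out) <- NULL
  out[order(vapply(out, min, character(1)))]
}

#' Single-copy-gene score of genome bins
#'
#' Score = (number of single-copy marker genes present) minus two times the
#' number of markers found in more than one copy; multicopy markers signal
#' bin contamination and are penalized.
#'
#' @param census data.frame with columns \code{genome_id},
#'   \code{n_scg_present}, \code{n_scg_multicopy}, \code{total_length}.
#' @return named integer vector of scores.
#' @export
scoreGenome <- function(census) {
  if (any(census$n_scg_multicopy > census$n_scg_present))
    stop("n_scg_multicopy cannot exceed n_scg_present")
  setNames(as.integer(census$n_scg_present - 2L * census$n_scg_multicopy),
           census$genome_id)
}

#' Select the representative genome of a dereplication group
#'
#' Highest single-copy-gene score wins; ties are broken by greater total
#' length (most nucleotide information), remaining ties lexicographically by
#' genome id.
#'
#' @param group character vector of genome ids.
#' @param census see \code{\link{scoreGenome}}.
#' @return the representative genome id.
#' @export
selectRepresentative <- function(group, census) {
  if (length(group) == 0) stop("empty group")
  sub <- census[match(group, census$genome_id), , drop = FALSE]
  if (anyNA(sub$genome_id))
    stop("census missing genome(s): ",
         paste(setdiff(group, census$genome_id), collapse = ", "))
  score <- scoreGenome(sub)
  ord <- order(-score, -sub$total_length, sub$genome_id)
  sub$genome_id[ord[1]]
}

#' Read a single-copy-gene census table
#'
#' @param path TSV with columns genome_id, n_scg_present, n_scg_multicopy,
#'   total_length.
#' @return census data.frame.
#' @export
readSCGCensus <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "n_scg_present", "n_scg_multicopy", "total_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("census missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$total_length <= 0)) stop("total_length must be > 0")
  df
}

#' Dereplicate a set of genome bins
#'
#' Computes all pairwise symmetric similarities, groups at
#' \code{> threshold}, and picks one representative per group by
#' single-copy-gene score.
#'
#' @param sequences named list of \code{DNAStringSet}, one per bin.
#' @param census see \code{\link{scoreGenome}}.
#' @param threshold grouping cut (default 0.5).
#' @param ... passed to \code{\link{pairwiseSimilarity}}.
#' @return list with \code{similarity} matrix, \code{groups} and
#'   \code{representatives}.
#' @export
dereplicateGenomes <- function(sequences, census, threshold = 0.5, ...) {
  ids <- names(sequences)
  n <- length(ids)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(sim) <- 1
  if (n > 1) {
    idx <- lapply(sequences, subjectIndex)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sim[i, j] <- sim[j, i] <-
          max(pairwiseSimilarity(sequences[[i]], idx[[j]], ...),
              pairwiseSimilarity(sequences[[j]], idx[[i]], ...))
      }
    }
  }
  groups <- groupGenomes(sim, threshold)
  reps <- vapply(groups, selectRepresentative, character(1), census = census)
  list(similarity = sim, groups = groups, representatives = sort(reps))
}
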