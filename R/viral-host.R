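## Viral contig filtering, tetranucleotide-frequency (TNF) host prediction,
## CRISPR array detection and protospacer matching.

#' Filter viral contigs and flag circularity and proteomic detection
#'
#' Contigs at or below \code{minLen} are dropped (the pipeline considers
#' only contigs longer than 10 kb).  A contig is circular when its two ends
#' share an exact terminal direct repeat of at least \code{repeatLen} bp.  A
#' contig is detected when any of its proteins has at least \code{minUnique}
#' unique peptides -- one for viruses, more sensitive than the microbial
#' two-peptide rule.
#'
#' @param contigs a \code{DNAStringSet} of viral contigs.
#' @param detections detection table (protein genome_ids name the contig a
#'   protein belongs to); NULL for none.
#' @param minLen length cut in bp (default 10000; strictly greater passes).
#' @param repeatLen minimum terminal direct repeat for circularity
#'   (default 20).
#' @param minUnique viral unique-peptide threshold (default 1).
#' @return data.frame (contig_id, length, circular, detected).
#' @export
filterViralContigs <- function(contigs, detections = NULL, minLen = 10000,
                               repeatLen = 20, minUnique = 1) {
  if (length(contigs) == 0) {
    return(data.frame(contig_id = character(0), length = integer(0),
                      circular = logical(0), detected = logical(0),
                      stringsAsFactors = FALSE))
  }
  keep <- Biostrings::width(contigs) > minLen
  contigs <- contigs[keep]
  detectedContigs <- character(0)
  if (!is.null(detections) && nrow(detections)) {
    ok <- detections$unique_peptides >= minUnique
    detectedContigs <- unique(unlist(detections$genome_ids[ok]))
  }
  circ <- vapply(as.character(contigs), hasTerminalRepeat, logical(1),
                 repeatLen = repeatLen, USE.NAMES = FALSE)
  data.frame(contig_id = names(contigs),
             length = Biostrings::width(contigs),
             circular = circ,
             detected = names(contigs) %in% detectedContigs,
             stringsAsFactors = FALSE)
}

## exact terminal direct repeat of >= repeatLen bp?
hasTerminalRepeat <- function(seqChr, repeatLen = 20, maxRepeat = 1000) {
  n <- nchar(seqChr)
  lim <- min(maxRepeat, floor(n / 2))
  if (lim < repeatLen) return(FALSE)
  prefix <- substr(seqChr, 1, repeatLen)
  tail <- substr(seqChr, n - lim + 1, n)
  hits <- Biostrings::matchPattern(prefix, Biostrings::DNAString(tail))
  for (h in Biostrings::start(hits)) {
    L <- lim - h + 1
    if (L < repeatLen || L > lim) next
    if (substr(seqChr, 1, L) == substr(seqChr, n - L + 1, n)) return(TRUE)
  }
  FALSE
}

## the 136 canonical 4-mers (lexicographic minimum of k-mer and its
## reverse complement)
canonicalTetramers <- function() {
  all4 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all4)))
  sort(unique(pmin(all4, rc)))
}

#' Tetranucleotide frequency profile
#'
#' Sliding 4-mer counts normalized to frequencies.  Windows containing
#' ambiguous bases are skipped.  With \code{strandCollapse} each 4-mer is
#' pooled with its reverse complement, giving 136 canonical components, so a
#' sequence and its reverse complement share one profile.
#'
#' @param sequence a \code{DNAString}, \code{DNAStringSet} (counts pooled
#'   over elements) or character.
#' @param strandCollapse pool with reverse complements (default TRUE).
#' @return named numeric frequency vector summing to 1.
#' @export
tnfProfile <- function(sequence, strandCollapse = TRUE) {
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  if (is(sequence, "DNAString")) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  if (sum(Biostrings::width(sequence)) < 4) stop("sequence shorter than 4 bp")
  counts <- colSums(Biostrings::oligonucleotideFrequency(sequence, width = 4))
  if (strandCollapse) {
    kmers <- names(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rc)
    counts <- vapply(split(counts, canon), sum, numeric(1))
    counts <- counts[canonicalTetramers()]
  }
  total <- sum(counts)
  if (total == 0) stop("no unambiguous 4-mer window in sequence")
  counts / total
}

#' Predict viral hosts by TNF similarity
#'
#' Each virus is assigned the genome minimizing the Euclidean distance
#' between their TNF profiles; the link is emitted only when that distance is
#' at most \code{dMax} and the runner-up genome is at least \code{margin}
#' farther (ambiguous nearest neighbors are suppressed).
#'
#' @param viralProfiles named list (or matrix rows) of viral TNF profiles.
#' @param genomeProfiles named list of genome TNF profiles computed with the
#'   same \code{strandCollapse} setting.
#' @param dMax maximum link distance (default 0.03, calibrated on synthetic
#'   communities; see the methods vignette).
#' @param margin minimum runner-up separation (default 0.002).
#' @return host-link data.frame (virus_id, genome_id, method = "TNF",
#'   score = distance).
#' @export
predictHostsTNF <- function(viralProfiles, genomeProfiles, dMax = 0.03,
                            margin = 0.002) {
  if (length(genomeProfiles) == 0 || length(viralProfiles) == 0)
    return(emptyHostLinkTable())
  gm <- do.call(rbind, genomeProfiles)
  rows <- lapply(names(viralProfiles), function(v) {
    d <- sqrt(rowSums(sweep(gm, 2, viralProfiles[[v]])^2))
    ord <- order(d, names(d))
    best <- d[ord[1]]
    second <- if (length(d) > 1) d[ord[2]] else Inf
    if (best <= dMax && (second - best) >= margin) {
      data.frame(virus_id = v, genome_id = names(d)[ord[1]],
                 method = "TNF", score = unname(best),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, c(list(emptyHostLinkTable()), rows))
  rownames(out) <- NULL
  out
}

#' Detect CRISPR arrays in genome sequences
#'
#' Minimal repeat-finder with CRT-like bounds: maximal runs of at least
#' \code{minCopies} near-identical repeats (length \code{repeatRange},
#' at most one mismatch between copies) separated by spacers of length
#' \code{spacerRange}.  Candidate arrays are seeded by exact
#' \code{seedLen}-mers recurring at compatible distances.  This is a spacer
#' extractor, not a Cas-locus annotator.
#'
#' @param sequences named \code{DNAStringSet} of genome scaffolds (names are
#'   genome or scaffold ids).
#' @param minCopies minimum repeat copies (default 3).
#' @param repeatRange repeat length bounds in bp (default c(23, 47)).
#' @param spacerRange spacer length bounds in bp (default c(20, 50)).
#' @param seedLen exact seed length; also the minimum repeat length scanned.
#' @return data.frame (genome_id, scaffold, array_id, repeat_consensus,
#'   spacer_id, spacer, start) with one row per spacer.
#' @export
detectCrisprArrays <- function(sequences, minCopies = 3,
                               repeatRange = c(23, 47),
                               spacerRange = c(20, 50), seedLen = 23) {
  empty <- data.frame(genome_id = character(0), scaffold = character(0),
                      array_id = character(0),
                      repeat_consensus = character(0),
                      spacer_id = character(0), spacer = character(0),
                      start = integer(0), stringsAsFactors = FALSE)
  rows <- list(empty)
  minGap <- repeatRange[1] + spacerRange[1]
  maxGap <- repeatRange[2] + spacerRange[2]
  for (nm in names(sequences)) {
    seqChr <- as.character(sequences[[nm]])
    L <- nchar(seqChr)
    if (L < minCopies * repeatRange[1] + (minCopies - 1) * spacerRange[1])
      next
    starts <- seq_len(L - seedLen + 1)
    seeds <- substring(seqChr, starts, starts + seedLen - 1)
    tab <- split(starts, seeds)
    tab <- tab[lengths(tab) >= minCopies]
    used <- rep(FALSE, L)
    arrayN <- 0
    ## richest seeds first: a boundary-shifted seed matching only a subset
    ## of the repeat copies must not shadow the full run
    seedOrder <- order(-lengths(tab), vapply(tab, min, numeric(1)))
    for (seed in names(tab)[seedOrder]) {
      pos <- sort(tab[[seed]])
      pos <- pos[!used[pos]]
      if (length(pos) < minCopies) next
      ## maximal runs with consecutive start-to-start gaps in [minGap, maxGap]
      runStart <- 1
      k <- 1
      while (k <= length(pos)) {
        if (k == length(pos) ||
            pos[k + 1] - pos[k] < minGap || pos[k + 1] - pos[k] > maxGap) {
          run <- pos[runStart:k]
          runStart <- k + 1
          if (length(run) >= minCopies) {
            arr <- buildCrisprArray(seqChr, run, seedLen, repeatRange,
                                    spacerRange)
            if (!is.null(arr) && length(arr$spacers) >= 1) {
              arrayN <- arrayN + 1
              ## mask the whole array (one seed length of flank included) so
              ## boundary-shifted seeds cannot re-report it
              lo <- max(1, run[1] - seedLen)
              hi <- min(L, run[length(run)] + arr$repeatLen + seedLen)
              used[lo:hi] <- TRUE
              rows[[length(rows) + 1]] <- data.frame(
                genome_id = nm, scaffold = nm,
                array_id = sprintf("%s_CRISPR%02d", nm, arrayN),
                repeat_consensus = arr$consensus,
                spacer_id = sprintf("%s_CRISPR%02d_sp%02d", nm, arrayN,
                                    seq_along(arr$spacers)),
                spacer = arr$spacers, start = arr$spacerStarts,
                stringsAsFactors = FALSE)
            }
          }
        }
        k <- k + 1
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## extend a seeded repeat run to the full repeat and cut out the spacers
buildCrisprArray <- function(seqChr, run, seedLen, repeatRange, spacerRange) {
  L <- nchar(seqChr)
  ## extend repeat to the right while all copies still agree with <= 1
  ## mismatch against the first copy, up to the max repeat length
  repLen <- seedLen
  maxLen <- min(repeatRange[2], min(diff(run)) - spacerRange[1])
  while (repLen < maxLen && max(run) + repLen <= L) {
    cand <- substring(seqChr, run, run + repLen)
    ref <- cand[1]
    mism <- vapply(cand, function(x)
      sum(utf8ToInt(x) != utf8ToInt(ref)), numeric(1))
    if (any(mism > 1)) break
    repLen <- repLen + 1
  }
  ## trim trailing columns where the copies disagree, so repeat boundaries
  ## do not creep into the spacers
  while (repLen > seedLen) {
    col <- substring(seqChr, run + repLen - 1, run + repLen - 1)
    if (length(unique(col)) == 1) break
    repLen <- repLen - 1
  }
  if (repLen < repeatRange[1]) return(NULL)
  spacerStarts <- run[-length(run)] + repLen
  spacerEnds <- run[-1] - 1
  sLens <- spacerEnds - spacerStarts + 1
  ok <- sLens >= spacerRange[1] & sLens <= spacerRange[2]
  if (!any(ok)) return(NULL)
  list(consensus = substr(seqChr, run[1], run[1] + repLen - 1),
       repeatLen = repLen,
       spacers = substring(seqChr, spacerStarts[ok], spacerEnds[ok]),
       spacerStarts = spacerStarts[ok])
}

#' Match CRISPR spacers against viral contigs (protospacers)
#'
#' A link from the array's genome to a virus is emitted when a spacer
#' matches the viral sequence on either strand with at most
#' \code{maxMismatch} mismatches; the score is the smallest mismatch count.
#'
#' @param arrays spacer table from \code{\link{detectCrisprArrays}}.
#' @param contigs \code{DNAStringSet} of viral contigs.
#' @param maxMismatch mismatch tolerance (default 1).
#' @return host-link data.frame (virus_id, genome_id, method = "CRISPR",
#'   score = mismatches).
#' @export
matchProtospacers <- function(arrays, contigs, maxMismatch = 1) {
  if (nrow(arrays) == 0 || length(contigs) == 0)
    return(emptyHostLinkTable())
  short <- nchar(arrays$spacer) < 20
  arrays <- arrays[!short, , drop = FALSE]
  rows <- list(emptyHostLinkTable())
  for (i in seq_len(nrow(arrays))) {
    sp <- Biostrings::DNAString(arrays$spacer[i])
    rc <- Biostrings::reverseComplement(sp)
    for (v in names(contigs)) {
      best <- Inf
      for (pat in list(sp, rc)) {
        for (m in 0:maxMismatch) {
          if (m >= best) break
          n <- Biostrings::countPattern(pat, contigs[[v]], max.mismatch = m)
          if (n > 0) {
            best <- m
            break
          }
        }
      }
      if (is.finite(best)) {
        rows[[length(rows) + 1]] <- data.frame(
          virus_id = v, genome_id = arrays$genome_id[i], method = "CRISPR",
          score = best, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (nrow(out)) {
    out <- out[order(out$virus_id, out$genome_id, out$score), , drop = FALSE]
    out <- out[!duplicated(out[, c("virus_id", "genome_id")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Merge TNF and CRISPR host links
#'
#' Links from both methods for the same virus-genome pair collapse to one
#' edge keeping \code{method = "CRISPR"} (direct protospacer evidence
#' dominates compositional inference).
#'
#' @param ... host-link data.frames.
#' @return merged host-link data.frame.
#' @export
mergeHostLinks <- function(...) {
  links <- do.call(rbind, c(list(emptyHostLinkTable()), list(...)))
  if (nrow(links) == 0) return(links)
  prio <- ifelse(links$method == "CRISPR", 0, 1)
  links <- links[order(links$virus_id, links$genome_id, prio), , drop = FALSE]
  links <- links[!duplicated(links[, c("virus_id", "genome_id")]), ,
                 drop = FALSE]
  rownames(links) <- NULL
  links
}
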