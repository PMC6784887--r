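#' @import methods
#' @importFrom stats runif rgamma quantile median setNames
#' @importFrom utils read.delim read.csv write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize CAZy subfamily labels to their family
#'
#' Subfamily suffixes are dropped for rule matching ("GH5_4" becomes "GH5");
#' the original label is retained wherever gene order is reported.
#'
#' @param x character vector of CAZy labels.
#' @return character vector of family-level labels.
#' @examples
#' normalizeCazy(c("GH5_4", "GH13_18", "PL1", "CE7"))
#' @export
normalizeCazy <- function(x) {
  sub("_[0-9]+$", "", x)
}

## split a ";"-separated field into a trimmed character vector
splitSemi <- function(x) {
  out <- lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
                function(v) {
                  v <- trimws(v)
                  v[nzchar(v)]
                })
  out
}

joinSemi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

## deterministic TSV writer: fixed separator, no quoting, "." decimal, LF eol
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n")
  invisible(path)
}

## format numbers for file output without scientific notation drift
numChr <- function(x, digits = 6) {
  formatC(x, format = "fg", digits = digits, flag = "#")
}

ruminetMessage <- function(...) {
  if (!isTRUE(getOption("ruminet.quiet", FALSE))) {
    message(...)
  }
}

## does each gene (row of a gene table) carry a given flag?
hasFlag <- function(genes, flag) {
  vapply(genes$flags, function(f) flag %in% f, logical(1))
}

## membership helpers against the "EC:" / "flag:" / "cazy:" member syntax
geneMatchesMember <- function(genes, member) {
  if (startsWith(member, "EC:")) {
    ec <- sub("^EC:", "", member)
    vapply(genes$ec, function(e) ec %in% e, logical(1))
  } else if (startsWith(member, "flag:")) {
    hasFlag(genes, sub("^flag:", "", member))
  } else if (startsWith(member, "cazy:")) {
    fam <- sub("^cazy:", "", member)
    vapply(genes$cazy, function(cz) fam %in% normalizeCazy(cz), logical(1))
  } else {
    stop("unknown member syntax: ", member)
  }
}

genesWithMember <- function(genes, member) {
  genes$gene_id[geneMatchesMember(genes, member)]
}

## empty prototypes used by readers, writers and the generator
emptyGeneTable <- function() {
  df <- data.frame(gene_id = character(0), genome_id = character(0),
                   scaffold_id = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   ordinal = integer(0), product = character(0),
                   stringsAsFactors = FALSE)
  df$pfam <- list()
  df$cazy <- list()
  df$ec <- list()
  df$flags <- list()
  df
}

emptyPULTable <- function() {
  df <- data.frame(pul_id = character(0), genome_id = character(0),
                   scaffold_id = character(0), susC = character(0),
                   susD = character(0), strand = character(0),
                   ordinal_start = integer(0), ordinal_end = integer(0),
                   start = integer(0), end = integer(0),
                   substrate = character(0), expressed = logical(0),
                   stringsAsFactors = FALSE)
  df$members <- list()
  df$cazy_order <- list()
  df$families <- list()
  df$peptidases <- list()
  df$detected_proteins <- list()
  df
}

emptyHostLinkTable <- function() {
  data.frame(virus_id = character(0), genome_id = character(0),
             method = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

## path to a shipped rulebook
ruminetExtdata <- function(file) {
  path <- system.file("extdata", file, package = "ruminet")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}
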