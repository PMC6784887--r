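writeMiniGFF <- function(path, rows,
                         header = "##gff-version 3\n##sequence-region s1 1 50000") {
  writeLines(c(header, rows), path)
}

gffRow <- function(id, start, end, strand = "+", seqid = "s1",
                   type = "CDS") {
  sprintf("%s\truminet\t%s\t%d\t%d\t.\t%s\t0\tID=%s", seqid, type, start,
          end, strand, id)
}

test_that("GFF3 + annotation table reading derives flags and ordinals", {
  gff <- tempfile(fileext = ".gff3")
  ann <- tempfile(fileext = ".tsv")
  ## deliberately out of coordinate order: ordinals must follow start
  writeMiniGFF(gff, c(gffRow("gene2", 2000, 2900),
                      gffRow("gene1", 100, 900),
                      gffRow("gene3", 4000, 4900, strand = "-")))
  writeLines(c("gene_id\tpfam\tcazy\tec\tproduct",
               "gene2\tPF07980\t\t\tSusD homolog",
               "gene3\t\tGH5_4;GH3\t3.2.1.4\tendoglucanase"), ann)
  ga <- readGenomeAnnotations(gff, ann, genomeId = "G1")
  g <- genes(ga)
  expect_equal(g$gene_id, c("gene1", "gene2", "gene3"))
  expect_equal(g$ordinal, 0:2)
  expect_true("susD" %in% g$flags[[2]])
  expect_equal(g$flags[[1]], character(0))
  expect_equal(g$cazy[[3]], c("GH5_4", "GH3"))
  expect_equal(g$ec[[3]], "3.2.1.4")
  expect_equal(unname(scaffoldLengths(ga)["s1"]), 50000)
})

test_that("empty GFF gives an empty annotation without error", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  ga <- readGenomeAnnotations(gff, NULL, genomeId = "G1")
  expect_equal(nrow(genes(ga)), 0)
})

test_that("duplicate gene ids and unknown annotation rows are caught", {
  gff <- tempfile(fileext = ".gff3")
  writeMiniGFF(gff, c(gffRow("geneA", 100, 900),
                      gffRow("geneA", 2000, 2900)))
  expect_error(readGenomeAnnotations(gff, NULL), "duplicate gene id")

  gff2 <- tempfile(fileext = ".gff3")
  ann2 <- tempfile(fileext = ".tsv")
  writeMiniGFF(gff2, gffRow("geneA", 100, 900))
  writeLines(c("gene_id\tpfam\tcazy\tec\tproduct",
               "ghost\tPF07980\t\t\tSusD"), ann2)
  expect_warning(ga <- readGenomeAnnotations(gff2, ann2),
                 "unknown gene id")
  expect_equal(genes(ga)$flags[[1]], character(0))
})

test_that("gene tables round-trip through GFF3 + annotation TSV", {
  genes <- buildGenes(strand = c("+", "+", "-", "+"),
                      susC = 1, susD = 2,
                      cazy = list("3" = c("GH5_4", "GH26")),
                      ec = list("4" = "5.3.1.9"))
  ga <- annotationFromGenes(genes)
  gff <- tempfile(fileext = ".gff3")
  ann <- tempfile(fileext = ".tsv")
  writeGenomeAnnotations(ga, gff, ann)
  back <- readGenomeAnnotations(gff, ann, genomeId = "G1")
  g2 <- genes(back)
  for (col in c("gene_id", "start", "end", "strand", "ordinal")) {
    expect_equal(g2[[col]], genes[[col]])
  }
  expect_equal(g2$cazy, genes$cazy)
  expect_equal(g2$ec, genes$ec)
  expect_equal(g2$flags, genes$flags)
})

test_that("derived flags are a pure, idempotent function of pfam/product", {
  pfam <- list(character(0), "PF12741", c("PF00593", "PF00404"))
  product <- c("glucose-specific transporter", NA, "cohesin protein")
  f1 <- deriveFlags(pfam, product)
  expect_equal(f1, deriveFlags(pfam, product))
  expect_true("transporter:glucose" %in% f1[[1]])
  expect_true("susD" %in% f1[[2]])
  expect_setequal(f1[[3]], c("susC", "tonB_receptor", "dockerin",
                             "cohesin"))
})

test_that("CAZy subfamily labels normalize to their family", {
  expect_equal(normalizeCazy(c("GH5_4", "GH13_18", "PL1", "CBM48")),
               c("GH5", "GH13", "PL1", "CBM48"))
})

test_that("protein detection tables parse, validate and round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgenome_ids\tunique_peptides\tspectral_count",
               "g7\tG1\t3\t11",
               "g8\tG1;G2\t2\t4"), tsv)
  det <- readProteinDetections(tsv)
  expect_equal(det$protein_id, c("g7", "g8"))
  expect_equal(det$genome_ids[[1]], "G1")
  expect_equal(det$genome_ids[[2]], c("G1", "G2"))
  expect_equal(det$unique_peptides, c(3L, 2L))

  out <- tempfile(fileext = ".tsv")
  writeProteinDetections(det, out)
  expect_equal(readProteinDetections(out), det)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgenome_ids\tunique_peptides\tspectral_count",
               "g7\tG1\t-1\t11"), bad)
  expect_error(readProteinDetections(bad), "non-negative")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tunique_peptides", "g7\t2"), bad2)
  expect_error(readProteinDetections(bad2), "missing column")
})

test_that("writeOutputs is deterministic and serializes PUL gene order", {
  genes <- buildGenes(strand = rep("+", 6), susC = 1, susD = 2,
                      cazy = list("3" = "GH5", "5" = "GH5", "6" = "GH26"))
  pulSet <- callPULs(annotationFromGenes(genes))
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  writeOutputs(pulSet, NULL, NULL, NULL, d1)
  writeOutputs(pulSet, NULL, NULL, NULL, d2)
  p1 <- read.delim(file.path(d1, "puls.tsv"))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$cazy_gene_order, "GH5;GH5;GH26")
  expect_identical(readLines(file.path(d1, "puls.tsv")),
                   readLines(file.path(d2, "puls.tsv")))

  empty <- tempfile()
  files <- writeOutputs(NULL, NULL, NULL, NULL, empty)
  for (f in grep("tsv$", files, value = TRUE)) {
    expect_equal(length(readLines(f)), 1)  # header only
  }
})
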