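randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

test_that("single-copy-gene score is n_present - 2 * n_multicopy", {
  census <- data.frame(genome_id = c("A", "B", "C"),
                       n_scg_present = c(38, 0, 10),
                       n_scg_multicopy = c(3, 0, 10),
                       total_length = c(1e6, 1e6, 1e6))
  expect_equal(scoreGenome(census), c(A = 32L, B = 0L, C = -10L))
  bad <- data.frame(genome_id = "X", n_scg_present = 2,
                    n_scg_multicopy = 3, total_length = 1)
  expect_error(scoreGenome(bad), "exceed")
})

test_that("representative: best score, ties by length, order-invariant", {
  census <- data.frame(genome_id = c("A", "B", "C"),
                       n_scg_present = c(35, 37, 37),
                       n_scg_multicopy = c(0, 0, 0),
                       total_length = c(3.0e6, 2.1e6, 2.4e6))
  expect_equal(selectRepresentative(c("A", "B"), census), "B")
  ## B and C tie on score; greater nucleotide information wins
  expect_equal(selectRepresentative(c("B", "C"), census), "C")
  perms <- list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))
  reps <- vapply(perms, selectRepresentative, character(1), census = census)
  expect_equal(unique(reps), "C")
  expect_error(selectRepresentative(character(0), census), "empty")
})

test_that("grouping is single linkage strictly above the threshold", {
  ids <- c("A", "B", "C")
  m0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  diag(m0) <- 1
  expect_equal(groupGenomes(m0), list("A", "B", "C"))

  chain <- m0
  chain["A", "B"] <- chain["B", "A"] <- 0.6
  chain["B", "C"] <- chain["C", "B"] <- 0.6
  chain["A", "C"] <- chain["C", "A"] <- 0.1
  expect_equal(groupGenomes(chain), list(c("A", "B", "C")))
  ## threshold is strict: similarity exactly at the cut does not join
  expect_equal(groupGenomes(chain, threshold = 0.6), list("A", "B", "C"))
  expect_equal(length(groupGenomes(chain, threshold = 1)), 3)
  expect_error(groupGenomes(matrix(0, 2, 3)), "square")
})

test_that("grouping equals a brute-force BFS component oracle", {
  set.seed(77)
  for (rep in 1:15) {
    n <- 8
    m <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    vals <- runif(n * (n - 1) / 2)
    m[upper.tri(m)] <- vals
    m <- pmax(m, t(m))
    diag(m) <- 1
    got <- groupGenomes(m, 0.5)
    adj <- m > 0.5
    diag(adj) <- FALSE
    expect_equal(got, bfsComponents(adj))
  }
})

test_that("similarity is 1 for identical genomes and 0 with no shared seeds", {
  set.seed(88)
  a <- Biostrings::DNAStringSet(c(s1 = randSeq(6000)))
  expect_equal(pairwiseSimilarity(a, a), 1)
  b <- Biostrings::DNAStringSet(c(s1 = randSeq(6000)))
  expect_equal(pairwiseSimilarity(a, b), 0)
  expect_error(pairwiseSimilarity(Biostrings::DNAStringSet(), a), "empty")
})

test_that("similarity on a mutated copy tracks the window-identity oracle", {
  set.seed(99)
  for (rate in c(0.003, 0.01, 0.05)) {
    sq <- randSeq(10000)
    mutated <- strsplit(sq, "")[[1]]
    pos <- sample.int(10000, round(10000 * rate))
    mutated[pos] <- vapply(mutated[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    mutated <- paste(mutated, collapse = "")
    a <- Biostrings::DNAStringSet(c(s1 = sq))
    b <- Biostrings::DNAStringSet(c(s1 = mutated))
    got <- pairwiseSimilarity(a, b)
    ## oracle: coordinates are preserved by point mutation, so window
    ## identity can be read off the aligned strings directly
    starts <- seq(1, 10000, by = 500)
    ident <- vapply(starts, function(s) {
      w1 <- utf8ToInt(substr(sq, s, s + 499))
      w2 <- utf8ToInt(substr(mutated, s, s + 499))
      mean(w1 == w2)
    }, numeric(1))
    want <- sum(500 * (ident >= 0.98)) / 10000
    expect_lte(abs(got - want), 0.05)
  }
})

test_that("dereplication collapses near-identical bins to the best genotype", {
  set.seed(110)
  parent <- randSeq(8000)
  child <- strsplit(parent, "")[[1]]
  pos <- sample.int(8000, 40)  # 0.5% divergence, well above 98% identity
  child[pos] <- vapply(child[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  seqs <- list(P = Biostrings::DNAStringSet(c(s1 = parent)),
               Pdup = Biostrings::DNAStringSet(
                 c(s1 = paste(child, collapse = ""))),
               Q = Biostrings::DNAStringSet(c(s1 = randSeq(8000))))
  census <- data.frame(genome_id = c("P", "Pdup", "Q"),
                       n_scg_present = c(38, 33, 36),
                       n_scg_multicopy = c(0, 2, 1),
                       total_length = c(8000, 8000, 8000))
  d <- dereplicateGenomes(seqs, census)
  expect_equal(length(d$groups), 2)
  expect_setequal(d$representatives, c("P", "Q"))
  expect_gt(d$similarity["P", "Pdup"], 0.5)
  expect_equal(d$similarity["P", "Q"], 0)
})
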