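randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("reciprocal best hits: identity, length filter, one-to-one", {
  s <- randomSeq(400, seed = 31)
  a <- Biostrings::DNAStringSet(c(x1 = s))
  b <- Biostrings::DNAStringSet(c(y1 = s))
  rbh <- reciprocalBestHits(a, b)
  expect_equal(nrow(rbh), 1)
  expect_equal(rbh$id_a, "x1")
  # a 150 bp perfect match is excluded by the length filter
  short <- Biostrings::DNAStringSet(c(z = substr(s, 1, 150)))
  expect_error(reciprocalBestHits(short, short), "length >= 200")
  expect_error(reciprocalBestHits(Biostrings::DNAStringSet(), a), "empty")
})

test_that("RBH pairs match an exhaustive all-pairs alignment oracle", {
  set.seed(32)
  n <- 5
  base <- replicate(n, randomSeq(300))
  mut <- vapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < 0.02)
    ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  a <- Biostrings::DNAStringSet(setNames(base, paste0("a", 1:n)))
  b <- Biostrings::DNAStringSet(setNames(sample(mut), paste0("b", 1:n)))
  rbh <- reciprocalBestHits(a, b, prescreen = TRUE, maxCandidates = 2)
  # independent exhaustive oracle: score every pair, demand mutual best
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  sc <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n)
    sc[i, j] <- Biostrings::pairwiseAlignment(
      a[[i]], b[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  expected <- list()
  for (i in 1:n) {
    j <- which.max(sc[i, ])
    if (which.max(sc[, j]) == i && sc[i, j] >= 100)
      expected[[length(expected) + 1]] <- c(names(a)[i], names(b)[j])
  }
  expected <- do.call(rbind, expected)
  got <- as.matrix(rbh[, c("id_a", "id_b")])
  expect_equal(got[order(got[, 1]), ], expected[order(expected[, 1]), ],
               ignore_attr = TRUE)
  expect_equal(nrow(rbh), n)     # planted one-to-one structure is recovered
})

test_that("identical alleles concatenate without trimming", {
  seqs <- setNames(lapply(1:3, function(i)
    Biostrings::DNAStringSet(c(o1 = "ACGTACGTACGT", o2 = "GGGCCCAAATTT"))),
    c("s1", "s2", "s3"))
  linked <- trimAndLink(seqs, minCore = 5)
  expect_equal(as.character(linkedSequences(linked)[["s1"]]),
               "ACGTACGTACGTGGGCCCAAATTT")
  expect_equal(linkedSegments(linked)$start, c(1L, 13L))
  expect_equal(linkedSegments(linked)$end, c(12L, 24L))
})

test_that("a 5' overhang is trimmed from every sample", {
  core <- randomSeq(150, seed = 33)
  ext <- paste0(randomSeq(10), core)
  seqs <- list(s1 = Biostrings::DNAStringSet(c(o1 = core)),
               s2 = Biostrings::DNAStringSet(c(o1 = ext)),
               s3 = Biostrings::DNAStringSet(c(o1 = core)))
  linked <- trimAndLink(seqs, minCore = 100)
  expect_equal(unique(Biostrings::width(linkedSequences(linked))), 150L)
  expect_equal(as.character(linkedSequences(linked)[["s2"]]), core)
})

test_that("linked sequences from simulated eight-sample sets are equal length", {
  seqs <- simulateOrthologSequences(10, length_range = c(300, 600),
                                    divergence = 0.02, seed = 34,
                                    end_extension = list(prob = 0.4,
                                                         bp = c(5, 25)))
  linked <- trimAndLink(seqs)
  expect_equal(length(linkedSequences(linked)), 8)
  expect_equal(length(unique(Biostrings::width(linkedSequences(linked)))), 1)
})

test_that("identity matrix matches a position-by-position loop", {
  expect_equal(identityMatrix(Biostrings::DNAStringSet(
    c(a = "ACGT", b = "ACGA")))["a", "b"], 0.75)
  ident <- Biostrings::DNAStringSet(c(a = "ACGTAC", b = "ACGTAC"))
  expect_equal(identityMatrix(ident)["a", "b"], 1.0)
  # N positions are excluded from numerator and denominator
  withN <- Biostrings::DNAStringSet(c(a = "ANGT", b = "ACGA"))
  expect_equal(identityMatrix(withN)["a", "b"], 2 / 3)
  expect_error(identityMatrix(Biostrings::DNAStringSet(
    c(a = "NNN", b = "ACG"))), "comparable")
  expect_error(identityMatrix(Biostrings::DNAStringSet(c(a = "ACG"))),
               "two samples")
  # 1 kb random fixture vs an explicit character loop
  set.seed(35)
  s1 <- strsplit(randomSeq(1000), "")[[1]]
  s2 <- s1
  flip <- sample(1000, 40)
  s2[flip] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  m <- identityMatrix(Biostrings::DNAStringSet(
    c(x = paste(s1, collapse = ""), y = paste(s2, collapse = ""))))
  loop <- sum(s1 == s2) / 1000
  expect_equal(m["x", "y"], loop)
  expect_equal(m, t(m))
})

test_that("base composition sums to 100 and reflects content", {
  comp <- baseComposition(Biostrings::DNAStringSet(
    c(a = "ACGT", b = "AAAA")))
  expect_equal(comp$at_pct[1], 50)
  expect_equal(comp$gc_pct[1], 50)
  expect_equal(comp$at_pct[2], 100)
  expect_equal(comp$at_pct + comp$gc_pct, c(100, 100))
})

test_that("GC-biased paternal substitutions pull hybrids toward their source", {
  seqs <- simulateOrthologSequences(20, divergence = 0.05, seed = 36,
                                    gc_bias = c(YB = 0.95),
                                    hybrid_source = c("2nBY" = "YB",
                                                      "3nBY" = "BSB"))
  comp <- baseComposition(trimAndLink(seqs))
  gc <- setNames(comp$gc_pct, comp$sample)
  expect_lt(abs(gc[["2nBY_1"]] - gc[["YB"]]), abs(gc[["2nBY_1"]] - gc[["BSB"]]))
  expect_lt(abs(gc[["3nBY_1"]] - gc[["BSB"]]), abs(gc[["3nBY_1"]] - gc[["YB"]]))
})

test_that("NJ recovers the generating topology of an additive matrix", {
  expect_error(njTree(diag(2)), "three samples")
  # tree ((A,B),(C,D)) with additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.02
  d["C", "D"] <- d["D", "C"] <- 0.02
  for (i in c("A", "B")) for (j in c("C", "D"))
    d[i, j] <- d[j, i] <- 0.06
  tr <- njTree(1 - d)
  expect_true(ape::is.monophyletic(ape::unroot(tr$tree), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::unroot(tr$tree), c("C", "D")))
  expect_true(all(tr$tree$edge.length >= 0))
  expect_match(tr$newick, "^\\(.*\\);$")
})

test_that("hybrids cluster with their source parent in the NJ tree", {
  seqs <- simulateOrthologSequences(15, divergence = 0.03, seed = 37,
                                    hybrid_source = c("2nBY" = "YB",
                                                      "3nBY" = "BSB"))
  linked <- trimAndLink(seqs)
  idm <- identityMatrix(linked)
  tr <- njTree(idm)
  coph <- ape::cophenetic.phylo(tr$tree)
  for (r in 1:3) {
    expect_lt(coph[paste0("3nBY_", r), "BSB"], coph[paste0("3nBY_", r), "YB"])
    expect_lt(coph[paste0("2nBY_", r), "YB"], coph[paste0("2nBY_", r), "BSB"])
  }
})
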