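.NUC_MAT <- NULL
.nucMat <- function() {
  m <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  m
}

# Shared-kmer prescreen: for each query, the indices of the top `n`
# candidate subjects by k-mer profile dot product.
.kmerCandidates <- function(a, b, k = 6, n = 5) {
  fa <- oligonucleotideFrequency(a, width = k)
  fb <- oligonucleotideFrequency(b, width = k)
  sim <- fa %*% t(fb)
  t(apply(sim, 1, function(r) order(r, decreasing = TRUE)[seq_len(min(n, length(r)))]))
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Identifies one-to-one ortholog pairs between two sequence sets by local
#' alignment score (match +1, mismatch -1, gap open 5, gap extend 2).
#' Sequences shorter than `minLen` (default 200 bp) are removed first.  A
#' pair (a, b) is kept when b is a's highest-scoring hit, a is b's, and the
#' alignment score reaches `minScore` (a raw-score stand-in for a BLAST
#' e-value cutoff).  With `prescreen = TRUE` only the top `maxCandidates`
#' subjects by shared 6-mer content are aligned per query, which keeps the
#' all-vs-all search at desk scale.
#'
#' @param setA,setB [Biostrings::DNAStringSet] objects with unique names.
#' @param minLen minimum sequence length in bp (default 200).
#' @param minScore minimum local alignment score (default 100).
#' @param prescreen logical; use the k-mer prescreen (default `TRUE`).
#' @param maxCandidates candidates per query under the prescreen.
#' @return data.frame `id_a`, `id_b`, `score` of the reciprocal best hits.
#' @export
reciprocalBestHits <- function(setA, setB, minLen = 200, minScore = 100,
                               prescreen = TRUE, maxCandidates = 5) {
  if (!length(setA) || !length(setB)) stop("empty sequence set")
  setA <- setA[width(setA) >= minLen]
  setB <- setB[width(setB) >= minLen]
  if (!length(setA) || !length(setB))
    stop("no sequence of length >= ", minLen, " bp remains")
  mat <- .nucMat()
  scores <- matrix(-Inf, length(setA), length(setB),
                   dimnames = list(names(setA), names(setB)))
  if (prescreen && length(setB) > maxCandidates) {
    cand <- .kmerCandidates(setA, setB, n = maxCandidates)
    candB <- .kmerCandidates(setB, setA, n = maxCandidates)
    for (i in seq_len(nrow(cand)))
      for (j in cand[i, ])
        scores[i, j] <- NA        # mark as to-score
    for (j in seq_len(nrow(candB)))
      for (i in candB[j, ])
        scores[i, j] <- NA
    for (j in seq_len(ncol(scores))) {
      todo <- which(is.na(scores[, j]))
      if (!length(todo)) next
      scores[todo, j] <- pairwiseAlignment(
        setA[todo], setB[[j]], type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    }
  } else {
    for (j in seq_along(setB))
      scores[, j] <- pairwiseAlignment(
        setA, setB[[j]], type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  }
  bestB <- apply(scores, 1, which.max)   # best subject per query
  bestA <- apply(scores, 2, which.max)   # best query per subject
  keep <- which(bestA[bestB] == seq_along(bestB) &
                  scores[cbind(seq_along(bestB), bestB)] >= minScore)
  data.frame(id_a = names(setA)[keep], id_b = names(setB)[bestB[keep]],
             score = scores[cbind(keep, bestB[keep])], row.names = NULL)
}

#' Group orthologs across samples through a reference sample
#'
#' Convenience wrapper running [reciprocalBestHits()] of every non-reference
#' sample against the reference and keeping the orthologs recovered in all
#' samples.  Sequences are renamed to the reference ortholog id so the
#' result can be passed to [trimAndLink()].
#'
#' @param sets named list of [Biostrings::DNAStringSet], one per sample.
#' @param reference name of the reference sample (default the first).
#' @param ... passed to [reciprocalBestHits()].
#' @return Named list of `DNAStringSet`s, one per sample, each named by the
#'   shared reference ortholog ids.
#' @export
orthologGroups <- function(sets, reference = names(sets)[1], ...) {
  ref <- sets[[reference]]
  maps <- list()
  shared <- names(ref)
  for (nm in setdiff(names(sets), reference)) {
    rbh <- reciprocalBestHits(ref, sets[[nm]], ...)
    maps[[nm]] <- setNames(rbh$id_b, rbh$id_a)
    shared <- intersect(shared, rbh$id_a)
  }
  if (!length(shared)) stop("no ortholog shared by every sample")
  out <- list()
  out[[reference]] <- ref[shared]
  for (nm in setdiff(names(sets), reference)) {
    s <- sets[[nm]][maps[[nm]][shared]]
    names(s) <- shared
    out[[nm]] <- s
  }
  out[names(sets)]
}

# Center-star multiple alignment of near-identical alleles: the longest
# allele is the star; every other allele is globally aligned to it and the
# pairwise alignments are merged into common columns by taking, between
# consecutive star positions, the maximum insertion length seen.
.centerStarMsa <- function(alleles) {
  chars <- lapply(alleles, function(s) strsplit(as.character(s), "")[[1]])
  star <- which.max(lengths(chars))
  L <- length(chars[[star]])
  mat <- .nucMat()
  aligned <- vector("list", length(chars))
  ins <- matrix(0L, length(chars), L + 1L)     # insertions before pos j+1
  for (i in seq_along(chars)) {
    if (i == star) next
    aln <- pairwiseAlignment(DNAStringSet(paste(chars[[i]], collapse = "")),
                             paste(chars[[star]], collapse = ""),
                             type = "global", substitutionMatrix = mat,
                             gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
    aligned[[i]] <- list(p = pa, s = sa)
    pos <- 0L; run <- 0L
    for (k in seq_along(sa)) {
      if (sa[k] == "-") run <- run + 1L
      else {
        ins[i, pos + 1L] <- run; run <- 0L; pos <- pos + 1L
      }
    }
    ins[i, L + 1L] <- run
  }
  gmax <- apply(ins, 2, max)
  ncol_total <- L + sum(gmax)
  out <- matrix("-", length(chars), ncol_total)
  # star row
  col <- 0L
  starcols <- integer(L)
  for (j in seq_len(L)) {
    col <- col + gmax[j]
    col <- col + 1L
    starcols[j] <- col
    out[star, col] <- chars[[star]][j]
  }
  for (i in seq_along(chars)) {
    if (i == star) next
    pa <- aligned[[i]]$p; sa <- aligned[[i]]$s
    row <- rep("-", ncol_total)
    pos <- 0L                                  # star positions consumed
    pending <- character(0)                    # insertion run before next pos
    place <- function(row, pos, pending) {
      # right-align the insertion run against the slot before star pos+1
      slotw <- gmax[pos + 1L]
      startcol <- if (pos == 0L) 0L else starcols[pos]
      if (length(pending))
        row[startcol + slotw - length(pending) + seq_along(pending)] <- pending
      row
    }
    for (k in seq_along(sa)) {
      if (sa[k] == "-") pending <- c(pending, pa[k])
      else {
        row <- place(row, pos, pending)
        pending <- character(0)
        pos <- pos + 1L
        row[starcols[pos]] <- pa[k]
      }
    }
    row <- place(row, pos, pending)
    out[i, ] <- row
  }
  rownames(out) <- names(alleles)
  out
}

#' Trim alleles to their collinear core and concatenate
#'
#' For each ortholog, aligns the per-sample alleles (a center-star
#' progressive alignment; skipped when all alleles have equal length and
#' are treated as positionally aligned), removes the terminal columns in
#' which any sample has an end gap -- the non-collinear overhangs -- and
#' drops any remaining gap-containing columns so the retained core is pure
#' nucleotide in every sample.  Orthologs whose core is shorter than
#' `minCore` bp are dropped, as are orthologs missing from any sample.
#' Survivors are concatenated in lexicographic ortholog-id order into one
#' long sequence per sample.
#'
#' @param groups named list of [Biostrings::DNAStringSet], one per sample,
#'   each named by shared ortholog ids (see [orthologGroups()]).
#' @param minCore minimum trimmed core length in bp (default 100).
#' @return A [LinkedOrthologs].
#' @export
trimAndLink <- function(groups, minCore = 100) {
  samples <- names(groups)
  ids <- sort(Reduce(intersect, lapply(groups, names)))
  dropped <- setdiff(unique(unlist(lapply(groups, names))), ids)
  if (length(dropped))
    message(length(dropped), " ortholog(s) missing from some sample; dropped")
  pieces <- setNames(vector("list", length(samples)), samples)
  for (s in samples) pieces[[s]] <- character(0)
  seg <- list()
  offset <- 0L
  for (id in ids) {
    alleles <- setNames(lapply(groups, function(g) g[[id]]), samples)
    widths <- vapply(alleles, length, integer(1))
    if (length(unique(widths)) == 1L) {
      block <- do.call(rbind, lapply(alleles, function(s)
        strsplit(as.character(s), "")[[1]]))
    } else {
      block <- .centerStarMsa(alleles)
    }
    isgap <- block == "-"
    firsts <- apply(isgap, 1, function(g) match(FALSE, g))
    if (anyNA(firsts)) next                    # an allele aligned to nothing
    first <- max(firsts)
    last <- min(apply(isgap, 1, function(g) max(which(!g))))
    if (last < first) next
    core <- block[, first:last, drop = FALSE]
    core <- core[, colSums(core == "-") == 0, drop = FALSE]
    if (ncol(core) < minCore) next
    for (s in samples)
      pieces[[s]] <- c(pieces[[s]], paste(core[s, ], collapse = ""))
    seg[[id]] <- data.frame(ortholog_id = id, start = offset + 1L,
                            end = offset + ncol(core))
    offset <- offset + ncol(core)
  }
  if (!length(seg)) stop("no ortholog survived trimming")
  linked <- DNAStringSet(vapply(pieces, paste, character(1), collapse = ""))
  names(linked) <- samples
  new("LinkedOrthologs", sequences = linked,
      segments = do.call(rbind, c(seg, list(make.row.names = FALSE))))
}

#' Pairwise identity matrix of linked sequences
#'
#' Fraction of positions with equal non-N bases among positions where both
#' sequences have a non-N base.  Diagonal 1, symmetric.
#'
#' @param linked a [LinkedOrthologs], or a [Biostrings::DNAStringSet] of
#'   equal-width sequences.
#' @return Symmetric numeric matrix of identities in \\[0, 1\\].
#' @export
identityMatrix <- function(linked) {
  seqs <- if (is(linked, "LinkedOrthologs")) linkedSequences(linked) else linked
  if (length(seqs) < 2) stop("at least two samples are required")
  if (length(unique(width(seqs))) != 1)
    stop("sequences must have equal length")
  chars <- lapply(as.character(seqs), charToRaw)
  ok <- lapply(chars, function(x) x != charToRaw("N"))
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[[i]] & ok[[j]]
    if (!any(both)) stop("no comparable (non-N) position between ",
                         names(seqs)[i], " and ", names(seqs)[j])
    id <- sum(chars[[i]][both] == chars[[j]][both]) / sum(both)
    m[i, j] <- m[j, i] <- id
  }
  m
}

#' Base composition of linked sequences
#'
#' Percentages of A+T and G+C bases per sample, over non-N positions
#' (the two always sum to 100).
#'
#' @param linked a [LinkedOrthologs] or [Biostrings::DNAStringSet].
#' @return data.frame `sample`, `at_pct`, `gc_pct`.
#' @export
baseComposition <- function(linked) {
  seqs <- if (is(linked, "LinkedOrthologs")) linkedSequences(linked) else linked
  freq <- letterFrequency(seqs, letters = c("A", "T", "G", "C"))
  tot <- rowSums(freq)
  data.frame(sample = names(seqs),
             at_pct = 100 * (freq[, "A"] + freq[, "T"]) / tot,
             gc_pct = 100 * (freq[, "G"] + freq[, "C"]) / tot,
             row.names = NULL)
}

#' Neighbor-joining tree from an identity matrix
#'
#' Builds a neighbor-joining tree on the p-distance `d = 1 - identity`.
#' Negative branch lengths (an NJ artifact on near-identical taxa) are
#' clamped to zero.  Tie-breaking is deterministic in the sample order of
#' the matrix.
#'
#' @param m a symmetric identity matrix (see [identityMatrix()]).
#' @return list with `tree` (an [ape::phylo]) and `newick` (character).
#' @export
njTree <- function(m) {
  if (nrow(m) < 3) stop("at least three samples are required")
  d <- as.dist(1 - m)
  tree <- nj(d)
  tree$edge.length <- pmax(tree$edge.length, 0)
  list(tree = tree, newick = write.tree(tree))
}
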