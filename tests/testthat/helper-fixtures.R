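# Small in-code fixtures shared across test files.

# A tiny HybridExperiment with fully controlled counts.
makeTinyExperiment <- function(counts, lengths = NULL) {
  counts <- as.matrix(counts)
  groups <- sub("_[^_]*$", "", colnames(counts))
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  HybridExperiment(counts, lengths = lengths, groups = groups)
}

# 12 samples, 3 per group, deterministic counts.
makeFourGroupCounts <- function(n_genes = 10, seed = 101, base = 50) {
  set.seed(seed)
  groups <- rep(c("BSB", "YB", "2nBY", "3nBY"), each = 3)
  k <- matrix(rpois(n_genes * 12, base), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              paste(groups, rep(1:3, 4), sep = "_")))
  k
}

# Independent brute-force two-sided Fisher p by hypergeometric enumeration.
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  pr <- dhyper(x, r1, n - r1, c1)
  pobs <- dhyper(a, r1, n - r1, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Independent step-up BH oracle.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}
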