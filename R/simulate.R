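# Expression "levels" (multiplicative steps of 2^effect_log2fc) defining
# each category's true means for (maternal A, paternal B, hybrid H).
# Adjacent distinct levels differ by the full effect size, so every nonzero
# pairwise contrast clears a calling threshold smaller than the effect.
.CATEGORY_LEVELS <- list(
  I    = c(A = 1, B = 0, H = 1),   # hybrid = maternal, maternal high
  II   = c(A = 0, B = 1, H = 0),   # hybrid = maternal, maternal low
  III  = c(A = 0, B = 1, H = 1),   # hybrid = paternal, paternal high
  IV   = c(A = 1, B = 0, H = 0),   # hybrid = paternal, paternal low
  V    = c(A = 2, B = 0, H = 1),   # additive, maternal high
  VI   = c(A = 0, B = 2, H = 1),   # additive, paternal high
  VII  = c(A = 1, B = 0, H = 2),   # transgressive up, parents differ
  VIII = c(A = 0, B = 0, H = 1),   # transgressive up, parents equal
  IX   = c(A = 0, B = 1, H = 2),   # transgressive up, parents differ
  X    = c(A = 1, B = 0, H = -1),  # transgressive down, parents differ
  XI   = c(A = 0, B = 0, H = -1),  # transgressive down, parents equal
  XII  = c(A = 0, B = 1, H = -1),  # transgressive down, parents differ
  NO_CHANGE = c(A = 0, B = 0, H = 0))

.CATEGORY_NAMES <- names(.CATEGORY_LEVELS)

# Default category mixture: mostly unchanged genes, a parental-ELD block
# whose maternal/paternal split is governed by maternal_bias, a smaller
# additive block, and rare transgressive genes -- the mixture structure a
# testis transcriptome of this cross displays.
.defaultCategoryProbs <- function() {
  c(I = 0.06, II = 0.06, III = 0.06, IV = 0.06,
    V = 0.035, VI = 0.035,
    VII = 0.006, VIII = 0.006, IX = 0.006,
    X = 0.004, XI = 0.004, XII = 0.004,
    NO_CHANGE = 0.66)
}

#' Simulation configuration
#'
#' Parameters of the synthetic count generator.  Counts are drawn from a
#' negative binomial with variance = mean + alpha * mean^2; true group means
#' are placed on a multiplicative grid of step `2^effect_log2fc` according to
#' each gene's category, so that noise-free classification recovers the
#' category exactly.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per group (default 3, as in a typical design
#'   with three biological repeats per group).
#' @param category_probs named probability vector over the twelve categories
#'   plus `NO_CHANGE`, summing to 1.  Defaults to a mixture dominated by
#'   unchanged genes with a parental-ELD block and rare transgressives.
#' @param maternal_bias ratio >= 1; the default mixture's parental-ELD mass
#'   is split maternal : paternal in this ratio (maternal-biased ELD,
#'   default 3).  An explicitly supplied `category_probs` is used verbatim.
#' @param baseline_mean_log `c(meanlog, sdlog)` of the log-normal baseline
#'   expression mean (default `c(5, 1)`, i.e. a median mean count of ~148).
#' @param effect_log2fc minimum true |log2 fold change| of every non-null
#'   contrast; must exceed 1 (the calling threshold), default 2.
#' @param nb_dispersion either a single positive alpha used for all genes,
#'   or `c(meanlog, sdlog)` of a per-gene log-normal draw (default
#'   `c(log(0.05), 0.5)`).
#' @param triploid_dosage `"compensated"` (triploid mean equals the diploid
#'   hybrid mean) or `"additive"` (1.5x the diploid hybrid mean, the naive
#'   three-genome dose).
#' @param gene_length_range bp interval for uniform gene lengths.
#' @param size_factor_range per-sample library-size factors are drawn
#'   uniformly from this interval (default `c(0.7, 1.3)`) so normalization
#'   is exercised.
#' @param independent_3n draw the triploid's category independently instead
#'   of inheriting the diploid's (default `FALSE`: truth shared between the
#'   hybrids).
#' @param seed integer seed.
#' @return A validated `simConfig` list.
#' @export
simConfig <- function(n_genes, n_reps = 3, category_probs = NULL,
                      maternal_bias = 3,
                      baseline_mean_log = c(5, 1),
                      effect_log2fc = 2,
                      nb_dispersion = c(log(0.05), 0.5),
                      triploid_dosage = c("compensated", "additive"),
                      gene_length_range = c(300, 3000),
                      size_factor_range = c(0.7, 1.3),
                      independent_3n = FALSE,
                      seed = 1) {
  if (maternal_bias < 1) stop("maternal_bias must be >= 1")
  explicit <- !is.null(category_probs)
  if (!explicit) category_probs <- .defaultCategoryProbs()
  if (!all(names(category_probs) %in% .CATEGORY_NAMES))
    stop("unknown category names: ",
         paste(setdiff(names(category_probs), .CATEGORY_NAMES), collapse = ", "))
  probs <- setNames(numeric(length(.CATEGORY_NAMES)), .CATEGORY_NAMES)
  probs[names(category_probs)] <- category_probs
  if (abs(sum(probs) - 1) > 1e-12)
    stop("category_probs must sum to 1 (got ", format(sum(probs)), ")")
  # the maternal:paternal split of the ELD mass shapes the default mixture;
  # an explicitly supplied category_probs is honoured verbatim
  eldMass <- sum(probs[c("I", "II", "III", "IV")])
  if (!explicit && eldMass > 0) {
    probs[c("I", "II")] <- eldMass * maternal_bias / (maternal_bias + 1) / 2
    probs[c("III", "IV")] <- eldMass / (maternal_bias + 1) / 2
  }
  if (effect_log2fc <= 1)
    stop("effect_log2fc must exceed 1, the calling threshold")
  if (n_genes < 1 || n_reps < 1) stop("n_genes and n_reps must be positive")
  disp <- as.numeric(nb_dispersion)
  if (length(disp) == 1 && disp <= 0) stop("nb_dispersion must be positive")
  structure(list(
    n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
    category_probs = probs, maternal_bias = maternal_bias,
    baseline_mean_log = as.numeric(baseline_mean_log),
    effect_log2fc = effect_log2fc, nb_dispersion = disp,
    triploid_dosage = match.arg(triploid_dosage),
    gene_length_range = as.numeric(gene_length_range),
    size_factor_range = as.numeric(size_factor_range),
    independent_3n = isTRUE(independent_3n),
    seed = as.integer(seed)), class = "simConfig")
}

.categoryMeans <- function(categories, baseline, effect) {
  lev <- do.call(rbind, .CATEGORY_LEVELS[categories])
  baseline * 2^(effect * lev)                 # columns A, B, H
}

#' Simulate parent/hybrid count matrices with known truth
#'
#' Draws a category for every gene, places true group means on the category's
#' multiplicative grid, applies the triploid dosage rule, and samples
#' negative-binomial counts under per-sample library-size factors.
#'
#' @param config a [simConfig()].
#' @return A list with `experiment` (a [HybridExperiment] of counts),
#'   `truth` (data.frame: `gene_id`, `category` of the diploid hybrid,
#'   `category_3n`, true group means, `length_bp`, `dispersion`) and
#'   `size_factors` (the known per-sample library-size factors).
#' @examples
#' sim <- simulateCounts(simConfig(n_genes = 100, seed = 42))
#' table(sim$truth$category)
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withr_seed <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(withr_seed), add = TRUE)
  ng <- config$n_genes; nr <- config$n_reps
  cats <- sample(.CATEGORY_NAMES, ng, replace = TRUE,
                 prob = config$category_probs)
  cats3 <- if (config$independent_3n)
    sample(.CATEGORY_NAMES, ng, replace = TRUE, prob = config$category_probs)
  else cats
  base <- rlnorm(ng, config$baseline_mean_log[1], config$baseline_mean_log[2])
  m2 <- .categoryMeans(cats, base, config$effect_log2fc)
  m3 <- .categoryMeans(cats3, base, config$effect_log2fc)
  dosage <- if (config$triploid_dosage == "additive") 1.5 else 1.0
  mu <- cbind(BSB = m2[, "A"], YB = m2[, "B"],
              `2nBY` = m2[, "H"], `3nBY` = m3[, "H"] * dosage)
  disp <- config$nb_dispersion
  alpha <- if (length(disp) == 1) rep(disp, ng) else rlnorm(ng, disp[1], disp[2])
  groups <- rep(c("BSB", "YB", "2nBY", "3nBY"), each = nr)
  sf <- runif(length(groups), config$size_factor_range[1],
              config$size_factor_range[2])
  names(sf) <- paste(groups, rep(seq_len(nr), 4), sep = "_")
  k <- matrix(0L, ng, length(groups),
              dimnames = list(sprintf("gene%05d", seq_len(ng)), names(sf)))
  for (j in seq_along(groups))
    k[, j] <- rnbinom(ng, mu = mu[, groups[j]] * sf[j], size = 1 / alpha)
  len <- round(runif(ng, config$gene_length_range[1],
                     config$gene_length_range[2]))
  he <- HybridExperiment(k, lengths = len, groups = groups)
  truth <- data.frame(gene_id = rownames(k), category = cats,
                      category_3n = cats3,
                      mean_BSB = mu[, "BSB"], mean_YB = mu[, "YB"],
                      mean_2nBY = mu[, "2nBY"], mean_3nBY = mu[, "3nBY"],
                      length_bp = len, dispersion = alpha, row.names = NULL)
  list(experiment = he, truth = truth, size_factors = sf)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(saved) {
  if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
}

#' Sign classification of noise-free means
#'
#' Threshold classifier used to verify simulation truth: the sign of each
#' pairwise contrast of true means is +1/-1 when the |log2 ratio| exceeds
#' `lfcCutoff`, else 0.  Applying [classifyCategory()] to these signs must
#' reproduce the generating category labels.
#'
#' @param truth the truth table from [simulateCounts()].
#' @param hybrid `"2nBY"` or `"3nBY"`.
#' @param lfcCutoff log2-ratio threshold (default 1).
#' @return data.frame `gene_id`, `d_HA`, `d_HB`, `d_AB`.
#' @export
truthSigns <- function(truth, hybrid = "2nBY", lfcCutoff = 1) {
  h <- truth[[paste0("mean_", hybrid)]]
  sgn <- function(a, b) {
    r <- log2(a / b)
    ifelse(abs(r) > lfcCutoff, sign(r), 0L)
  }
  data.frame(gene_id = truth$gene_id,
             d_HA = sgn(h, truth$mean_BSB),
             d_HB = sgn(h, truth$mean_YB),
             d_AB = sgn(truth$mean_BSB, truth$mean_YB))
}

#' Simulate divergent parental and hybrid transcript sequences
#'
#' Generates a set of ortholog sequences for the maternal parent, derives the
#' paternal alleles by iid point substitutions at the given divergence, and
#' gives each hybrid replicate a copy of its configured parent-of-origin's
#' allele with additional per-replicate substitutions.  Optional 5'/3'
#' extensions on parental alleles exercise the collinear trimming step of
#' [trimAndLink()].
#'
#' @param n_orthologs number of ortholog sequences.
#' @param length_range bp interval for uniform ortholog lengths.
#' @param divergence substitution rate per site between the parents; must be
#'   in \\[0, 0.25) (beyond that the identity signal saturates).
#' @param hybrid_source named map from hybrid group to parent-of-origin
#'   (default: diploid hybrid expresses the paternal alleles, triploid the
#'   maternal -- the reverse-direction homoeolog dominance this cross shows).
#' @param n_hybrid_reps replicates per hybrid (default 3, giving eight
#'   sample sets with the single parents).
#' @param rep_divergence extra substitution rate applied independently to
#'   every hybrid replicate (default 0.002).
#' @param gc_bias probability that a substitution introduces G or C
#'   (default 0.5: unbiased).  A named vector (e.g. `c(YB = 0.8)`) applies
#'   a lineage-specific bias to the named parent's derivation.
#' @param end_extension `NULL`, or `list(prob=, bp=c(min,max))`: probability
#'   that an allele gains a random non-collinear extension at the 5' or 3'
#'   end.
#' @param seed integer seed.
#' @param fasta_dir optional directory; when given, one FASTA per sample is
#'   written there.
#' @return Named list of [Biostrings::DNAStringSet], one per sample
#'   (`BSB`, `YB`, then each hybrid replicate, e.g. `2nBY_1`), sequences
#'   named by ortholog id.
#' @export
simulateOrthologSequences <- function(n_orthologs, length_range = c(300, 1500),
                                      divergence = 0.02,
                                      hybrid_source = c("2nBY" = "YB",
                                                        "3nBY" = "BSB"),
                                      n_hybrid_reps = 3,
                                      rep_divergence = 0.002,
                                      gc_bias = 0.5,
                                      end_extension = NULL,
                                      seed = 1, fasta_dir = NULL) {
  if (divergence < 0 || divergence >= 0.25)
    stop("divergence must lie in [0, 0.25); at 0.25 and beyond the ",
         "identity signal saturates")
  saved <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(saved), add = TRUE)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("ORTH%04d", seq_len(n_orthologs))
  lens <- round(runif(n_orthologs, length_range[1], length_range[2]))
  anc <- lapply(lens, function(L) sample(bases, L, replace = TRUE))
  biasOf <- function(lineage) {
    if (!is.null(names(gc_bias)) && lineage %in% names(gc_bias))
      gc_bias[[lineage]] else if (is.null(names(gc_bias))) gc_bias[1] else 0.5
  }
  mutate <- function(seqchars, rate, bias = 0.5) {
    if (rate <= 0) return(seqchars)
    hit <- which(runif(length(seqchars)) < rate)
    for (i in hit) {
      repeat {
        b <- if (runif(1) < bias) sample(c("G", "C"), 1) else sample(c("A", "T"), 1)
        if (b != seqchars[i]) break
      }
      seqchars[i] <- b
    }
    seqchars
  }
  extend <- function(seqchars) {
    if (is.null(end_extension) || runif(1) >= end_extension$prob)
      return(seqchars)
    n <- sample(seq(end_extension$bp[1], end_extension$bp[2]), 1)
    pad <- sample(bases, n, replace = TRUE)
    if (runif(1) < 0.5) c(pad, seqchars) else c(seqchars, pad)
  }
  bsb <- lapply(anc, extend)
  yb <- lapply(anc, function(s) extend(mutate(s, divergence, biasOf("YB"))))
  samples <- list(BSB = bsb, YB = yb)
  parentOf <- list(BSB = bsb, YB = yb)
  for (h in names(hybrid_source)) {
    src <- parentOf[[hybrid_source[[h]]]]
    for (r in seq_len(n_hybrid_reps)) {
      samples[[paste(h, r, sep = "_")]] <-
        lapply(src, mutate, rate = rep_divergence, bias = biasOf(h))
    }
  }
  out <- lapply(samples, function(sl)
    setNames(DNAStringSet(vapply(sl, paste, character(1), collapse = "")), ids))
  if (!is.null(fasta_dir)) {
    dir.create(fasta_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      writeXStringSet(out[[nm]], file.path(fasta_dir, paste0(nm, ".fasta")))
  }
  out
}
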