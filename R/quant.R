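#' FPKM quantification
#'
#' Converts raw fragment counts to FPKM (fragments per kilobase of transcript
#' per million mapped fragments):
#' `FPKM[g,s] = counts[g,s] * 1e9 / (length_bp[g] * totalCounts[s])`.
#' The result is stored as an `fpkm` assay alongside the counts.
#'
#' @param x a [HybridExperiment].
#' @return `x` with an added `fpkm` assay.
#' @examples
#' he <- simulateCounts(simConfig(n_genes = 50, seed = 1))$experiment
#' he <- computeFpkm(he)
#' fpkm(he)[1:3, 1:3]
#' @export
computeFpkm <- function(x) {
  stopifnot(is(x, "HybridExperiment"))
  k <- assay(x, "counts")
  lib <- colSums(k)
  if (any(lib == 0))
    stop("zero total count in sample(s): ",
         paste(colnames(k)[lib == 0], collapse = ", "))
  f <- sweep(k * 1e9 / geneLengths(x), 2, lib, "/")
  assay(x, "fpkm") <- f
  x
}

#' Coexpression filter
#'
#' Retains the genes expressed in all four groups of the cross: a gene is
#' kept when its group-mean FPKM is greater than zero in the maternal parent,
#' the paternal parent and every hybrid.  This defines the shared
#' ("coexpressed") gene set that all downstream stages (differential
#' expression, ELD classification, dosage comparison) operate on.  With
#' `perSample = TRUE` the stricter rule requiring a nonzero count in every
#' individual library is applied instead.
#'
#' @param x a [HybridExperiment]; the `fpkm` assay is computed if absent.
#' @param perSample logical; require every sample (not just every group mean)
#'   to be nonzero.
#' @return The filtered `HybridExperiment`.  The numbers of retained and
#'   removed genes are recorded in `metadata(x)$coexpression_filter` and
#'   reported via `message()`.
#' @export
filterCoexpressed <- function(x, perSample = FALSE) {
  stopifnot(is(x, "HybridExperiment"))
  if (!"fpkm" %in% assayNames(x)) x <- computeFpkm(x)
  f <- assay(x, "fpkm")
  grp <- sampleGroups(x)
  keep <- rep(TRUE, nrow(x))
  for (g in unique(grp)) {
    fg <- f[, grp == g, drop = FALSE]
    keep <- keep & if (perSample) rowSums(fg > 0) == ncol(fg) else rowMeans(fg) > 0
  }
  out <- x[keep, ]
  metadata(out)$coexpression_filter <-
    list(retained = sum(keep), removed = sum(!keep), per_sample = perSample)
  if (sum(keep) == 0) warning("coexpression filter removed every gene")
  message(sprintf("coexpression filter: %d retained, %d removed",
                  sum(keep), sum(!keep)))
  out
}
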