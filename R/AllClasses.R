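#' HybridExperiment: counts for a parent/hybrid cross
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding gene-level
#' fragment counts for the four groups of a hybrid cross (maternal parent,
#' paternal parent and one or more hybrids), together with per-gene effective
#' lengths (`rowData(x)$length_bp`) and per-sample group labels
#' (`colData(x)$group`).  Group roles (which label is the maternal parent,
#' which the paternal, which are hybrids) live in `metadata(x)$roles` so the
#' same machinery applies to crosses with other naming conventions.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @aliases HybridExperiment-class
#' @exportClass HybridExperiment
setClass("HybridExperiment", contains = "SummarizedExperiment")

setValidity("HybridExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (is.null(rowData(object)$length_bp))
    msg <- c(msg, "rowData(x)$length_bp is required")
  else if (any(rowData(object)$length_bp <= 0))
    msg <- c(msg, "gene lengths must be > 0")
  if (is.null(colData(object)$group))
    msg <- c(msg, "colData(x)$group is required")
  if ("counts" %in% assayNames(object)) {
    k <- assay(object, "counts")
    if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
  }
  roles <- metadata(object)$roles
  if (is.null(roles) || !all(c("maternal", "paternal", "hybrids") %in% names(roles)))
    msg <- c(msg, "metadata(x)$roles must name maternal, paternal and hybrids")
  else {
    need <- c(roles$maternal, roles$paternal, roles$hybrids)
    have <- unique(as.character(colData(object)$group))
    miss <- setdiff(need, have)
    if (length(miss))
      msg <- c(msg, paste0("groups without samples: ", paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HybridExperiment
#'
#' @param counts integer matrix of fragment counts, genes in rows, samples in
#'   columns; `rownames` are gene identifiers, `colnames` sample identifiers.
#' @param lengths numeric vector of effective gene lengths in bp, one per row.
#' @param groups character vector of group labels, one per column.
#' @param maternal,paternal group labels of the maternal and paternal parent.
#' @param hybrids character vector of hybrid group labels.
#'
#' @return A `HybridExperiment`.
#' @examples
#' k <- matrix(rpois(48, 50), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' groups <- rep(c("BSB", "YB", "2nBY", "3nBY"), each = 3)
#' colnames(k) <- paste(groups, rep(1:3, 4), sep = "_")
#' he <- HybridExperiment(k, lengths = rep(1000, 4), groups = groups)
#' @export
HybridExperiment <- function(counts, lengths, groups,
                             maternal = "BSB", paternal = "YB",
                             hybrids = c("2nBY", "3nBY")) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(groups, stats::ave(seq_along(groups), groups,
                                                 FUN = seq_along), sep = "_")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(length_bp = as.numeric(lengths),
                        row.names = rownames(counts)),
    colData = DataFrame(group = as.character(groups),
                        row.names = colnames(counts)))
  metadata(se)$roles <- list(maternal = maternal, paternal = paternal,
                             hybrids = hybrids)
  new("HybridExperiment", se)
}

#' @describeIn HybridExperiment per-gene effective lengths in bp.
#' @param x a `HybridExperiment`.
#' @export
geneLengths <- function(x) rowData(x)$length_bp

#' @describeIn HybridExperiment per-sample group labels.
#' @export
sampleGroups <- function(x) as.character(colData(x)$group)

#' @describeIn HybridExperiment group roles (`maternal`, `paternal`, `hybrids`).
#' @export
groupRoles <- function(x) metadata(x)$roles

#' @describeIn HybridExperiment the FPKM assay (after [computeFpkm()]).
#' @export
fpkm <- function(x) {
  if (!"fpkm" %in% assayNames(x))
    stop("no 'fpkm' assay; run computeFpkm() first")
  assay(x, "fpkm")
}

setMethod("show", "HybridExperiment", function(object) {
  callNextMethod()
  roles <- metadata(object)$roles
  tab <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\nroles: maternal =", roles$maternal, "| paternal =", roles$paternal,
      "| hybrids =", paste(roles$hybrids, collapse = ", "), "\n")
})

#' MpvSet: in-silico mid-parent expression profiles
#'
#' Holds the three dosage-weighted mid-parent profiles built from paired
#' parental replicates r of maternal expression chi_B and paternal chi_Y:
#' MPV1 = chi_B + chi_Y/2 (maternal-doubled triploid BBY),
#' MPV2 = chi_B/2 + chi_Y/2 (diploid BY),
#' MPV3 = chi_B/2 + chi_Y (paternal-doubled triploid BYY).
#' Matrices are genes x replicate pairings.
#'
#' @slot mpv1,mpv2,mpv3 numeric matrices, genes in rows.
#' @slot pairing data.frame recording which maternal replicate was paired with
#'   which paternal replicate.
#' @aliases MpvSet-class
#' @exportClass MpvSet
setClass("MpvSet",
         representation(mpv1 = "matrix", mpv2 = "matrix", mpv3 = "matrix",
                        pairing = "data.frame"))

setValidity("MpvSet", function(object) {
  d1 <- dim(object@mpv1)
  if (!identical(d1, dim(object@mpv2)) || !identical(d1, dim(object@mpv3)))
    return("mpv1, mpv2, mpv3 must share dimensions")
  if (any(object@mpv1 < 0) || any(object@mpv2 < 0) || any(object@mpv3 < 0))
    return("MPV profiles must be non-negative")
  TRUE
})

#' @describeIn MpvSet extract one profile as a matrix.
#' @param x an `MpvSet`.
#' @param profile one of `"MPV1"`, `"MPV2"`, `"MPV3"`.
#' @export
mpvProfile <- function(x, profile = c("MPV1", "MPV2", "MPV3")) {
  profile <- match.arg(profile)
  slot(x, tolower(profile))
}

setMethod("show", "MpvSet", function(object) {
  cat("MpvSet:", nrow(object@mpv1), "genes x", ncol(object@mpv1),
      "replicate pairings (profiles MPV1, MPV2, MPV3)\n")
})

#' LinkedOrthologs: concatenated collinear ortholog alleles
#'
#' One long sequence per sample, built by trimming each ortholog's alleles to
#' their collinear core and concatenating the survivors in a deterministic
#' (lexicographic) ortholog order.  All sequences have equal length; the
#' `segments` table records where each ortholog landed.
#'
#' @slot sequences a [Biostrings::DNAStringSet], one sequence per sample,
#'   all of equal width.
#' @slot segments data.frame with columns `ortholog_id`, `start`, `end`
#'   (1-based, inclusive), rows in concatenation order.
#' @aliases LinkedOrthologs-class
#' @exportClass LinkedOrthologs
setClass("LinkedOrthologs",
         representation(sequences = "DNAStringSet", segments = "data.frame"))

setValidity("LinkedOrthologs", function(object) {
  w <- width(object@sequences)
  if (length(w) && length(unique(w)) != 1L)
    return("linked sequences must all have equal length")
  seg <- object@segments
  if (nrow(seg)) {
    if (is.unsorted(seg$start, strictly = TRUE))
      return("segment starts must be strictly increasing")
    if (sum(seg$end - seg$start + 1L) != w[1])
      return("segment lengths must sum to the total length")
  }
  TRUE
})

#' @describeIn LinkedOrthologs the per-sample concatenated sequences.
#' @param x a `LinkedOrthologs`.
#' @export
linkedSequences <- function(x) x@sequences

#' @describeIn LinkedOrthologs the ortholog segment table.
#' @export
linkedSegments <- function(x) x@segments

setMethod("show", "LinkedOrthologs", function(object) {
  cat("LinkedOrthologs:", length(object@sequences), "samples,",
      nrow(object@segments), "orthologs,",
      if (length(object@sequences)) width(object@sequences)[1] else 0,
      "bp each\n")
})
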