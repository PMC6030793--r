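#' Read a counts TSV into a HybridExperiment
#'
#' Expects a tab-separated file with columns `gene_id`, `length_bp`, then
#' one column per sample named `GROUP_rep` (e.g. `BSB_1`, `2nBY_3`); the
#' group label is everything before the final underscore.  Gene lengths may
#' instead come from a separate two-column TSV (`gene_id`, `length_bp`) via
#' `lengthsFile`.
#'
#' @param path path to the counts TSV.
#' @param lengthsFile optional path to a two-column lengths TSV.
#' @param maternal,paternal,hybrids group role labels (see
#'   [HybridExperiment()]).
#' @return A [HybridExperiment].
#' @export
readCountsTsv <- function(path, lengthsFile = NULL,
                          maternal = "BSB", paternal = "YB",
                          hybrids = c("2nBY", "3nBY")) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("column 'gene_id' is required")
  if (!is.null(lengthsFile)) {
    lt <- read.delim(lengthsFile, check.names = FALSE)
    len <- lt$length_bp[match(tab$gene_id, lt$gene_id)]
  } else {
    if (!"length_bp" %in% names(tab))
      stop("column 'length_bp' or a lengthsFile is required")
    len <- tab$length_bp
  }
  samplecols <- setdiff(names(tab), c("gene_id", "length_bp"))
  k <- as.matrix(tab[, samplecols, drop = FALSE])
  rownames(k) <- tab$gene_id
  groups <- sub("_[^_]*$", "", samplecols)
  HybridExperiment(k, lengths = len, groups = groups,
                   maternal = maternal, paternal = paternal,
                   hybrids = hybrids)
}

#' Write a HybridExperiment's counts (and lengths) as TSV
#'
#' @param x a [HybridExperiment].
#' @param path output file.
#' @param assayName which assay to write (default `"counts"`).
#' @return `path`, invisibly.
#' @export
writeCountsTsv <- function(x, path, assayName = "counts") {
  m <- assay(x, assayName)
  out <- data.frame(gene_id = rownames(m), length_bp = geneLengths(x),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read every FASTA file of a directory as one sequence set per sample
#'
#' @param dir directory containing `<sample>.fasta` files.
#' @param pattern filename pattern (default `"\\.fa(sta)?$"`).
#' @return Named list of [Biostrings::DNAStringSet], keyed by file basename.
#' @export
readFastaDir <- function(dir, pattern = "\\.fa(sta)?$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no FASTA file found in ", dir)
  out <- lapply(files, readDNAStringSet)
  names(out) <- sub(pattern, "", basename(files))
  out
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
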