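#' Build in-silico mid-parent expression profiles
#'
#' Pairs the maternal and paternal replicates by index and forms the three
#' dosage-weighted mid-parent profiles per gene and pairing r:
#' `MPV1 = chiB[,r] + 0.5 * chiY[,r]` (maternal-doubled triploid, BBY),
#' `MPV2 = 0.5 * chiB[,r] + 0.5 * chiY[,r]` (diploid, BY),
#' `MPV3 = 0.5 * chiB[,r] + chiY[,r]` (paternal-doubled triploid, BYY),
#' where chiB and chiY are the parents' expression values (FPKM by default).
#'
#' @param x a [HybridExperiment] with an `fpkm` assay (see [computeFpkm()]),
#'   or a list `list(maternal = matrix, paternal = matrix)` of expression
#'   matrices with equal column counts.
#' @param assayName which assay to use when `x` is a `HybridExperiment`
#'   (default `"fpkm"`).
#' @return An [MpvSet].
#' @export
buildMpv <- function(x, assayName = "fpkm") {
  if (is(x, "HybridExperiment")) {
    roles <- groupRoles(x)
    grp <- sampleGroups(x)
    m <- assay(x, assayName)
    chiB <- m[, grp == roles$maternal, drop = FALSE]
    chiY <- m[, grp == roles$paternal, drop = FALSE]
  } else {
    chiB <- as.matrix(x$maternal)
    chiY <- as.matrix(x$paternal)
  }
  if (ncol(chiB) != ncol(chiY))
    stop("maternal and paternal replicate counts differ (",
         ncol(chiB), " vs ", ncol(chiY), "); replicate pairing is undefined")
  pairing <- data.frame(maternal = colnames(chiB) %||% seq_len(ncol(chiB)),
                        paternal = colnames(chiY) %||% seq_len(ncol(chiY)))
  new("MpvSet",
      mpv1 = chiB + 0.5 * chiY,
      mpv2 = 0.5 * chiB + 0.5 * chiY,
      mpv3 = 0.5 * chiB + chiY,
      pairing = pairing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a hybrid's expression with the mid-parent profiles
#'
#' For every gene and MPV profile, computes the log2 ratio of the hybrid's
#' mean expression over the profile's mean (a pseudocount `eps` guards
#' near-zero genes) and calls the gene upregulated when the ratio exceeds
#' `lfcCutoff`, downregulated below `-lfcCutoff`, else unchanged.
#'
#' Note that expression values normalized within sample (such as FPKM)
#' carry no absolute-dosage information: a ploidy effect scaling every gene
#' equally cancels in the normalization.  Pass absolutely calibrated
#' expression (in simulations, counts divided by the known library-size
#' factors) to resolve additive versus compensated triploid dosage.
#'
#' @param hybridExpr matrix of the hybrid's expression (genes x replicates),
#'   or a vector of per-gene means.
#' @param mpv an [MpvSet] over the same genes.
#' @param lfcCutoff positive log2-ratio threshold (default 1.0).
#' @param eps pseudocount added to both means (default 0.1).
#' @return list with `calls` (data.frame `gene_id`, and per profile the
#'   log2 ratio and call in \{"up","down","unchanged"\}) and `summary`
#'   (data.frame `profile`, `up`, `down`, `unchanged`).
#' @export
compareToMpv <- function(hybridExpr, mpv, lfcCutoff = 1.0, eps = 0.1) {
  stopifnot(is(mpv, "MpvSet"))
  if (lfcCutoff <= 0) stop("lfcCutoff must be positive")
  h <- if (is.matrix(hybridExpr)) rowMeans(hybridExpr) else as.numeric(hybridExpr)
  if (length(h) != nrow(mpv@mpv1))
    stop("hybrid expression and MPV profiles cover different gene sets")
  ids <- rownames(mpv@mpv1) %||% names(h) %||% seq_along(h)
  calls <- data.frame(gene_id = as.character(ids))
  summ <- data.frame(profile = c("MPV1", "MPV2", "MPV3"),
                     up = NA_integer_, down = NA_integer_,
                     unchanged = NA_integer_)
  for (i in 1:3) {
    prof <- c("MPV1", "MPV2", "MPV3")[i]
    m <- rowMeans(slot(mpv, tolower(prof)))
    lfc <- log2(h + eps) - log2(m + eps)
    call <- ifelse(lfc > lfcCutoff, "up",
                   ifelse(lfc < -lfcCutoff, "down", "unchanged"))
    calls[[paste0("lfc_", tolower(prof))]] <- lfc
    calls[[paste0("call_", tolower(prof))]] <- call
    summ$up[i] <- sum(call == "up")
    summ$down[i] <- sum(call == "down")
    summ$unchanged[i] <- sum(call == "unchanged")
  }
  list(calls = calls, summary = summ)
}

#' Dosage-compensation summary across hybrids and profiles
#'
#' Tabulates up/down counts per hybrid and MPV profile, tests each triploid
#' profile's up/down split against the diploid-dose profile MPV2 with
#' Fisher's exact test, and flags a hybrid as biased toward MPV2 when its
#' up/down imbalance against MPV2 is the smallest of the three profiles --
#' the signature of expression at the diploid level (dosage compensation
#' when seen in a triploid).
#'
#' @param calls2n,calls3n results of [compareToMpv()] for the diploid and
#'   triploid hybrid (either may be `NULL`).
#' @return data.frame with one row per hybrid x profile: `hybrid`,
#'   `profile`, `up`, `down`, `unchanged`, `p_vs_mpv2` (NA on the MPV2
#'   rows) and `biased_toward_mpv2` (logical, constant per hybrid).
#' @export
dosageSummary <- function(calls2n = NULL, calls3n = NULL) {
  one <- function(cmp, label) {
    s <- cmp$summary
    ref <- s[s$profile == "MPV2", ]
    p <- vapply(seq_len(nrow(s)), function(i) {
      if (s$profile[i] == "MPV2") return(NA_real_)
      fisherExact2x2(rbind(c(s$up[i], s$down[i]), c(ref$up, ref$down)))
    }, numeric(1))
    imbalance <- abs(s$up - s$down)
    data.frame(hybrid = label, profile = s$profile,
               up = s$up, down = s$down, unchanged = s$unchanged,
               p_vs_mpv2 = p,
               biased_toward_mpv2 =
                 imbalance[s$profile == "MPV2"] == min(imbalance),
               row.names = NULL)
  }
  out <- list()
  if (!is.null(calls2n)) out <- c(out, list(one(calls2n, "2nBY")))
  if (!is.null(calls3n)) out <- c(out, list(one(calls3n, "3nBY")))
  if (!length(out)) stop("at least one hybrid's calls are required")
  do.call(rbind, out)
}
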