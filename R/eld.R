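# Decision table on the sign triple (d_HA, d_HB, d_AB) where
# d_HA = sign(hybrid - maternal A), d_HB = sign(hybrid - paternal B),
# d_AB = sign(A - B).  The 12 named categories plus NO_CHANGE cover 13 of
# the 27 cells; the remaining 14 (e.g. hybrid above one parent and below
# the other while the parents are equal) are internally inconsistent at the
# calling thresholds and reported as AMBIGUOUS, never silently merged.
.ELD_TABLE <- c(
  "0,1,1"    = "I",    "0,-1,-1"  = "II",
  "1,0,-1"   = "III",  "-1,0,1"   = "IV",
  "-1,1,1"   = "V",    "1,-1,-1"  = "VI",
  "1,1,1"    = "VII",  "1,1,0"    = "VIII", "1,1,-1"  = "IX",
  "-1,-1,1"  = "X",    "-1,-1,0"  = "XI",   "-1,-1,-1" = "XII",
  "0,0,0"    = "NO_CHANGE")

.ELD_GROUPS <- c(I = "BSB_ELD", II = "BSB_ELD",
                 III = "YB_ELD", IV = "YB_ELD",
                 V = "ADDITIVITY", VI = "ADDITIVITY",
                 VII = "UP", VIII = "UP", IX = "UP",
                 X = "DOWN", XI = "DOWN", XII = "DOWN",
                 NO_CHANGE = "NO_CHANGE", AMBIGUOUS = "AMBIGUOUS")

#' Twelve-category expression classification of a sign triple
#'
#' Bins a gene by the signs of its three pairwise comparisons: hybrid vs
#' maternal parent (`d_HA`), hybrid vs paternal parent (`d_HB`) and maternal
#' vs paternal (`d_AB`), each in \{-1, 0, +1\}.  Categories I-II are
#' maternal-parent expression level dominance (hybrid indistinguishable from
#' the maternal parent, parents different), III-IV paternal ELD, V-VI
#' additivity (hybrid intermediate), VII-IX transgressive up and X-XII
#' transgressive down; (0,0,0) is NO_CHANGE and the 14 remaining triples are
#' AMBIGUOUS.
#'
#' @param d_HA,d_HB,d_AB integer vectors over \{-1, 0, 1\} (recycled
#'   together).
#' @return data.frame with `category` and its `group_label`
#'   (`BSB_ELD`, `YB_ELD`, `ADDITIVITY`, `UP`, `DOWN`, `NO_CHANGE`,
#'   `AMBIGUOUS`).
#' @examples
#' classifyCategory(0, 1, 1)    # maternal ELD, category I
#' @export
classifyCategory <- function(d_HA, d_HB, d_AB) {
  n <- max(length(d_HA), length(d_HB), length(d_AB))
  d_HA <- rep_len(as.integer(d_HA), n)
  d_HB <- rep_len(as.integer(d_HB), n)
  d_AB <- rep_len(as.integer(d_AB), n)
  if (any(!c(d_HA, d_HB, d_AB) %in% c(-1L, 0L, 1L)))
    stop("sign components must be -1, 0 or +1")
  key <- paste(d_HA, d_HB, d_AB, sep = ",")
  cat <- unname(.ELD_TABLE[key])
  cat[is.na(cat)] <- "AMBIGUOUS"
  data.frame(category = cat, group_label = unname(.ELD_GROUPS[cat]))
}

#' Classify every gene of a hybrid from its three DE call lists
#'
#' Combines the signed calls of the hybrid-vs-maternal, hybrid-vs-paternal
#' and maternal-vs-paternal comparisons (each a [nbExactTest()] result at
#' the category-stage cutoffs) into a per-gene category assignment, and
#' summarises the counts and fractions per group label.
#'
#' @param callsHA calls of hybrid vs maternal parent (sign +1 = hybrid
#'   higher).
#' @param callsHB calls of hybrid vs paternal parent.
#' @param callsAB calls of maternal vs paternal parent (sign +1 = maternal
#'   higher).
#' @return list with `assignments` (data.frame `gene_id`, `d_HA`, `d_HB`,
#'   `d_AB`, `category`, `group_label`) and `summary` (data.frame
#'   `group_label`, `count`, `fraction` of the classified total).
#' @export
classifyTrios <- function(callsHA, callsHB, callsAB) {
  ids <- callsHA$gene_id
  for (other in list(callsHB, callsAB)) {
    bad <- union(setdiff(ids, other$gene_id), setdiff(other$gene_id, ids))
    if (length(bad))
      stop("call lists cover different gene sets; offenders: ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
  }
  hb <- callsHB[match(ids, callsHB$gene_id), ]
  ab <- callsAB[match(ids, callsAB$gene_id), ]
  cls <- classifyCategory(callsHA$sign, hb$sign, ab$sign)
  assignments <- data.frame(gene_id = ids,
                            d_HA = callsHA$sign, d_HB = hb$sign,
                            d_AB = ab$sign,
                            category = cls$category,
                            group_label = cls$group_label,
                            row.names = NULL)
  labs <- c("BSB_ELD", "YB_ELD", "ADDITIVITY", "UP", "DOWN",
            "NO_CHANGE", "AMBIGUOUS")
  counts <- vapply(labs, function(l) sum(assignments$group_label == l),
                   integer(1))
  list(assignments = assignments,
       summary = data.frame(group_label = labs, count = counts,
                            fraction = counts / length(ids),
                            row.names = NULL))
}

#' Fisher's exact tests for ELD and transgressive asymmetries
#'
#' Contrasts two hybrids' classification summaries: maternal-ELD versus
#' paternal-ELD counts, and transgressive-up versus transgressive-down
#' counts, each as a 2x2 table (hybrids x directions) tested with
#' [fisherExact2x2()].
#'
#' @param summary1,summary2 the `summary` component of [classifyTrios()] for
#'   the two hybrids.
#' @param labels names for the two hybrids in the output.
#' @return list with elements `eld` and `updown`, each containing `table`
#'   (2x2) and `p`.
#' @export
eldAsymmetryTest <- function(summary1, summary2,
                             labels = c("hybrid1", "hybrid2")) {
  pick <- function(s, lab) s$count[s$group_label == lab]
  mk <- function(l1, l2) {
    m <- rbind(c(pick(summary1, l1), pick(summary1, l2)),
               c(pick(summary2, l1), pick(summary2, l2)))
    dimnames(m) <- list(labels, c(l1, l2))
    m
  }
  eld <- mk("BSB_ELD", "YB_ELD")
  ud <- mk("UP", "DOWN")
  list(eld = list(table = eld, p = fisherExact2x2(eld)),
       updown = list(table = ud, p = fisherExact2x2(ud)))
}

#' Parental-ELD inheritance between two hybrids
#'
#' Counts how the parental-ELD gene sets of two hybrids overlap: genes that
#' are maternal-ELD in both, paternal-ELD in both, parental-ELD in both but
#' on discordant sides, and parental-ELD in exactly one hybrid.
#'
#' @param assignments1,assignments2 the `assignments` component of
#'   [classifyTrios()] over the same gene universe.
#' @return Named integer vector: `bsb_eld_both`, `yb_eld_both`,
#'   `discordant`, `eld_one_only`.
#' @export
eldInheritanceOverlap <- function(assignments1, assignments2) {
  a2 <- assignments2[match(assignments1$gene_id, assignments2$gene_id), ]
  p1 <- assignments1$group_label %in% c("BSB_ELD", "YB_ELD")
  p2 <- a2$group_label %in% c("BSB_ELD", "YB_ELD")
  both <- p1 & p2
  c(bsb_eld_both = sum(both & assignments1$group_label == "BSB_ELD" &
                         a2$group_label == "BSB_ELD"),
    yb_eld_both = sum(both & assignments1$group_label == "YB_ELD" &
                        a2$group_label == "YB_ELD"),
    discordant = sum(both & assignments1$group_label != a2$group_label),
    eld_one_only = sum(xor(p1, p2)))
}
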