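---
title: "Methods: duplicated-gene expression analysis in hybrid and polyploid transcriptomes"
author: "polyhybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicated-gene expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`polyhybrid` analyses duplicated-gene expression in a four-group
interspecific cross: a maternal parent (label `BSB`), a paternal parent
(`YB`), an allodiploid hybrid (`2nBY`) and an allotriploid hybrid (`3nBY`),
each with replicated bulk RNA-seq libraries.  The entry point is a
gene-by-sample integer count matrix with per-gene effective lengths, held in
a `HybridExperiment` (a `SummarizedExperiment` subclass); the mapping and
assembly steps that produce such a matrix are upstream of this package.
Group roles are metadata, so other crosses can reuse the machinery by
relabelling.

Three questions drive the design:

1. **Expression level dominance (ELD).** For each gene, does the hybrid's
   total expression track the maternal parent, the paternal parent, neither
   (transgressive) or the mid-parent (additive)?
2. **Dosage.** Does the triploid express at the three-genome dose or has it
   reduced expression to the diploid state (dosage compensation)?
3. **Sequence dominance.** Which parental genome's alleles dominate each
   hybrid's expressed transcripts, measured on concatenated ortholog
   sequences?

# Quantification and the coexpression filter

FPKM is computed as `count * 1e9 / (length_bp * library_size)`; the same
formula backs both the "FPKM" and "RPKM" names since the paired/single-end
distinction does not exist at count level.  The *coexpression filter*
retains genes whose group-mean FPKM is positive in all four groups — the
shared gene set on which every downstream stage operates.  A stricter
per-library rule (`perSample = TRUE`) is available because the group-level
wording of such filters is ambiguous in much of the literature; group-mean
is the default since it is the weaker assumption.  Filtering is idempotent
and its retained/removed counts are logged.

# The exact negative-binomial test

The two-group differential expression test is authored in the package in
the style of the classical exact NB test for count data:

* **Normalization** — median-of-ratios size factors: the median over
  all-nonzero genes of a sample's count over the gene's geometric mean,
  rescaled to geometric mean 1.  When no gene is zero-free the total-count
  ratio is used with a warning.  Only the ratio of factors is meaningful.
* **Dispersion** — method of moments per gene on normalized counts
  (`variance = mean + alpha * mean^2`, with a `mean(1/sf)` shot-noise
  correction), floored at `1e-8`.  With three replicates the raw moments
  are unstable, so a running-median trend over up to 20 mean-ranked bins is
  computed and the working dispersion is the *larger* of the gene-wise
  estimate and the trend.
* **Test** — conditioned on the total count of the two groups, the
  two-sided p-value sums the probabilities of all splits no more likely
  than the observed one, with each group's total modelled as NB with mean
  `mu0 * sum(sf)` and variance `mu0 * sum(sf) + alpha * mu0^2 * sum(sf^2)`.
* **Calling** — Benjamini–Hochberg FDR across genes (delegated to
  `p.adjust`), and a signed call under the dual threshold `fdr < cutoff`
  and `|log2fc| > 1`, where `log2fc` compares normalized group means with
  a pseudocount of 1 normalized count (so silent genes produce finite
  ratios).  The DEG stage uses `fdr < 0.001`; the ELD category stage uses
  `fdr < 0.005`.  The category stage's published threshold wording
  ("log 2 ratio <= 1") is read as the exceedance rule `> 1`, consistent
  with every other stated threshold.

**Calibration.**  Taking the max of the gene-wise and trend dispersions
protects against anticonservative calls at the cost of mild conservatism:
under a pure null the p-values are slightly super-uniform.  The test suite
therefore checks exact uniformity (Kolmogorov–Smirnov) with the dispersion
*known* — which isolates the conditional-test machinery — and separately
checks that estimated-dispersion p-values are never anticonservative.
`nbExactTest(..., dispersion = )` exposes the known-dispersion mode.

**Identifiability.**  Median-of-ratios (like any relative normalization)
absorbs a fold change shared by most genes.  Power statements therefore
only make sense against a majority-null background; the simulator's default
mixture provides one.

# Twelve-category classification

Each gene's three sign calls — hybrid vs maternal (`d_HA`), hybrid vs
paternal (`d_HB`), maternal vs paternal (`d_AB`) — form a triple in
`{-1, 0, +1}^3`.  Thirteen of the 27 cells carry names: I/II maternal ELD,
III/IV paternal ELD, V/VI additivity, VII–IX transgressive up, X–XII
transgressive down, and `(0,0,0)` no change.  The within-pair numbering
(which of I vs II is the "parents-high" member) is a package convention;
every reported aggregate is invariant to it.  The remaining 14 cells are
internally inconsistent at the calling thresholds (for example, hybrid
above one parent and below the other while the parents test equal) and are
reported as `AMBIGUOUS` rather than silently merged, since published
category schemes do not state how such genes were handled.  The table is a
total function, exhaustively asserted in the tests, and parent-swapping
permutes it in the expected way (I↔III, II↔IV, V↔VI, VII↔IX, X↔XII).

Asymmetry summaries (maternal-ELD vs paternal-ELD, transgressive up vs
down, between the two hybrids) are 2×2 Fisher exact tests, delegated to
`fisher.test` (two-sided minimum-likelihood rule) and cross-checked in the
suite against a hypergeometric enumeration oracle.

# Mid-parent profiles and dosage

From index-paired parental replicates, three in-silico profiles are formed
per gene: `MPV1 = chiB + chiY/2` (maternal-doubled triploid, genome BBY),
`MPV2 = (chiB + chiY)/2` (diploid, BY) and `MPV3 = chiB/2 + chiY`
(paternal-doubled triploid, BYY).  A hybrid is compared to each profile by
the log2 ratio of means with a pseudocount of 0.1 FPKM; calls use a
fold-change-only threshold (default 1.0) because the published procedure
quotes only a ratio threshold at this stage, unlike the FDR-based DEG
stage.  A config switch through the exact test is not provided: replicate
pairing is preserved in the `MpvSet` so such an extension is
straightforward, but mean-ratio calling is the documented default.

A hybrid is flagged *biased toward MPV2* when its up/down imbalance against
MPV2 is the smallest of the three profiles; in a triploid that is the
dosage-compensation signature.

**What FPKM can and cannot show here.**  Within-sample normalization
divides by the library total, so a ploidy effect that scales *every* gene
by 1.5 cancels exactly; on FPKM an additive triploid and a compensated one
produce the same MPV pattern (the 1.5-dose profiles MPV1/MPV3 sit above the
observable expression scale, so "down" calls dominate against them either
way).  Resolving additive from compensated dosage requires absolutely
calibrated expression — spike-ins or per-cell normalization in real data.
The simulator records its true library-size factors, and the dosage
recovery tests divide counts by them; the pipeline's default remains FPKM,
which reproduces the published comparison on its own scale.  This is a real
limitation of the published design, made explicit here rather than papered
over.

# Ortholog concatenation and the similarity tree

The sequence module replaces a BLAST/ClustalW/PERL/MEGA tool chain with
self-contained, deterministic steps:

* **Reciprocal best hits** — sequences under 200 bp are dropped; all-vs-all
  local alignment (match +1, mismatch −1, gap open 5, gap extend 2, via
  `Biostrings::pairwiseAlignment`) with a raw-score threshold of 100
  standing in for an e-value cutoff; a pair is kept only if each member is
  the other's best hit.  A shared 6-mer prescreen limits alignment to the
  top candidates per query, keeping the search at desk scale; the suite
  compares prescreened results against an exhaustive all-pairs oracle.
* **Collinear trimming** — per ortholog, alleles across samples are
  multiple-aligned (center-star with global pairwise alignments to the
  longest allele; alleles of equal length are treated as already
  positionally aligned, which is exact for substitution-only divergence),
  terminal columns containing any end gap are removed (the non-collinear
  overhangs), remaining gap columns are dropped so the core is pure
  nucleotide, and cores shorter than 100 bp are discarded.
* **Linking** — surviving cores are concatenated in lexicographic ortholog
  order (a determinism convention; the published order is unstated) into
  one long sequence per sample, all of equal length by construction.
* **Identity and composition** — pairwise identity counts equal non-N
  bases over positions where both samples are non-N (N excluded from both
  numerator and denominator, avoiding a penalty for ambiguity); base
  composition reports A+T% and G+C% of non-N positions.
* **Tree** — neighbor joining (`ape::nj`) on the p-distance
  `1 − identity`, negative branch lengths clamped to 0.  NJ replaces
  maximum likelihood deliberately: the conclusion of interest — which
  parent each hybrid clusters with — is topology-level and
  distance-derivable, and ML adds machinery without additional testable
  output.  Identity on near-identical concatenations is an approximation
  to published "similarity" values, whose exact metric is unstated.

# The synthetic-data generator

The generator is first-class, tested code that defines the conditions under
which the pipeline is validated.

**Counts.**  Each gene draws a category (the twelve classes plus
`NO_CHANGE`), a log-normal baseline mean (`meanlog 5`, `sdlog 1`, i.e. a
median mean count of ~148 — a realistic mid-depth bulk library), and a
dispersion (fixed, or log-normal around 0.05 — typical for good-quality
bulk RNA-seq).  True group means sit on a multiplicative grid with step
`2^effect_log2fc`: each category fixes the order pattern of (maternal,
paternal, hybrid) and adjacent distinct levels differ by the full effect
size, so every nonzero contrast clears the calling threshold and
classifying the noise-free means reproduces the labels exactly — the
self-consistency the truth tables are tested against.  `effect_log2fc`
must exceed the threshold 1; the default 2 makes additive genes sit a full
effect from both parents.  Counts are NB with per-sample library-size
factors drawn uniformly from [0.7, 1.3] so normalization is genuinely
exercised; the factors are returned as ground truth.  The triploid shares
the diploid's category by default (published parental-ELD genes are
largely heritable between the hybrids; `independent_3n` overrides) and its
mean is either equal to the diploid's (`compensated`) or 1.5× it
(`additive`).  The default mixture — 24% parental ELD split 3:1
maternal:paternal, 7% additive, 3% transgressive, 66% unchanged — mirrors
the category structure a testis transcriptome of this cross displays; the
maternal bias ratio shapes only the default mixture, an explicit
`category_probs` is honoured verbatim.  `AMBIGUOUS` truth is never
generated.

**Sequences.**  Maternal ortholog sequences are uniform random; paternal
alleles differ by iid substitutions at the configured rate (default 2%,
bounded below 0.25 where the identity signal saturates; the parents' true
per-gene divergence distribution is unknown, so the rate is a free
parameter, not an estimate).  Each hybrid replicate copies its configured
parent-of-origin's allele — by default the diploid carries paternal and the
triploid maternal alleles, the reverse-direction dominance this cross
shows — plus small per-replicate substitutions (default 0.2%).  Optional 5'
or 3' extensions exercise the collinear trimming; an optional GC-biased
substitution spectrum lets composition-based clustering be tested.

**What the simulation does not emulate:** assembly artifacts and chimeric
transcripts, annotation structure, length-dependent count bias, correlated
genes, indels inside alleles, and real library composition.  Passing the
recovery tests therefore demonstrates the pipeline's statistical machinery
under its own model assumptions, not robustness to assembly noise.

# Validation problem sizes and numerical choices

The test suite validates category recovery and null specificity on 2000
genes at effect 3 and dispersion 0.05 with 3 replicates; empirical FDR on
ten 2000-gene 80%-null mixtures; calibration on a 5000-gene null; dosage
recovery on 800–1500-gene simulations in both triploid modes; and the
sequence pipeline on 10–100 ortholog sets — sizes chosen so the whole
suite runs in a couple of minutes while every estimate has usable
precision.  Numerical conventions: pseudocount 1 normalized count in DE
fold changes and 0.1 FPKM in MPV ratios; dispersion floor `1e-8`; p-value
comparisons of outcome probabilities use a `1 + 1e-7` relative guard
against floating-point ties; RBH ties break to the first index; NJ
tie-breaking follows the input sample order.

# Known limitations

* The exact test covers two-group contrasts only — no multi-factor
  designs, shrunken fold changes, or variance-stabilizing transforms.
* Homoeolog-resolved (allele-specific) expression within a hybrid is out
  of scope; ELD here concerns the *total* expression of a duplicate pair.
* Mean-ratio MPV calling ignores replicate variance by design; profiles
  retain replicate pairing should a test-based extension be needed.
* The center-star alignment is built for near-identical alleles; deeply
  diverged or rearranged alleles would need a full MSA tool.
* Identity-based similarity slightly underestimates model-corrected
  distances at higher divergence; immaterial below ~3% divergence.
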