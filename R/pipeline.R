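#' Pipeline configuration
#'
#' Collects inputs, output location, stage toggles and the stage cutoffs:
#' DEG calling at `deg_fdr` (default 0.001), category-stage calling at
#' `category_fdr` (default 0.005), both with `|log2fc| > lfc` (default 1.0),
#' and mid-parent comparisons at `mpv_lfc` (default 1.0, fold-change-only).
#'
#' @param counts a counts TSV path, a [HybridExperiment], or `NULL` to
#'   simulate from `sim`.
#' @param fasta a directory of per-sample FASTA files, a named list of
#'   [Biostrings::DNAStringSet], or `NULL` to skip the ortholog stage.
#' @param out_dir output directory (created if needed).
#' @param sim a [simConfig()] used when `counts` is `NULL`.
#' @param stages character subset of
#'   `c("quant", "detest", "eld", "dosage", "ortho")`.
#' @param deg_fdr,category_fdr,lfc,mpv_lfc stage cutoffs.
#' @param seed integer seed for any randomness (recorded in the report).
#' @param groups group role labels, a list like
#'   `list(maternal = "BSB", paternal = "YB", hybrids = c("2nBY", "3nBY"))`.
#' @return A validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(counts = NULL, fasta = NULL, out_dir = tempfile("polyhybrid_"),
                           sim = NULL,
                           stages = c("quant", "detest", "eld", "dosage", "ortho"),
                           deg_fdr = 0.001, category_fdr = 0.005,
                           lfc = 1.0, mpv_lfc = 1.0, seed = 1,
                           groups = GROUP_DEFAULTS) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (v in c(deg_fdr, category_fdr, lfc, mpv_lfc))
    if (!is.numeric(v) || v <= 0) stop("cutoffs must be positive")
  structure(list(counts = counts, fasta = fasta, out_dir = out_dir,
                 sim = sim, stages = stages, deg_fdr = deg_fdr,
                 category_fdr = category_fdr, lfc = lfc, mpv_lfc = mpv_lfc,
                 seed = as.integer(seed), groups = groups),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [pipelineConfig()] arguments
#' (with `sim:` holding [simConfig()] arguments).
#'
#' @param path YAML file path.
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simConfig, y$sim)
  do.call(pipelineConfig, y)
}

.reSign <- function(calls, fdrCutoff, lfcCutoff) {
  calls$sign <- as.integer(
    ifelse(calls$fdr < fdrCutoff & abs(calls$log2fc) > lfcCutoff,
           sign(calls$log2fc), 0L))
  calls
}

.pct <- function(n, total) round(100 * n / total, 2)

#' Run the full analysis pipeline
#'
#' Executes quantification (FPKM + coexpression filter), differential
#' expression for every hybrid-parent and parent-parent contrast, the
#' twelve-category ELD classification of both hybrids with asymmetry and
#' inheritance summaries, the mid-parent dosage comparison, and (when
#' sequences are supplied) the ortholog concatenation / identity / tree
#' analysis.  Per-stage TSV files, a text report, and a machine-readable
#' `summary.json` are written to `out_dir`; all counts are accompanied by
#' percentages of the coexpressed-gene total.
#'
#' @param config a [pipelineConfig()] (or path to a YAML config).
#' @return The summary list, invisibly; the same content is in
#'   `out_dir/summary.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    writeLines(line, logcon); message(line)
  }
  set.seed(config$seed)
  summary <- list(seed = config$seed,
                  cutoffs = list(deg_fdr = config$deg_fdr,
                                 category_fdr = config$category_fdr,
                                 lfc = config$lfc, mpv_lfc = config$mpv_lfc))
  roles <- config$groups
  stage <- "input"
  result <- try({
    he <- if (is(config$counts, "HybridExperiment")) config$counts
    else if (is.character(config$counts)) readCountsTsv(config$counts)
    else if (!is.null(config$sim)) {
      logmsg("simulating counts: %d genes, seed %d",
             config$sim$n_genes, config$sim$seed)
      sim <- simulateCounts(config$sim)
      .writeTsv(sim$truth, file.path(config$out_dir, "sim_truth.tsv"))
      sim$experiment
    } else if (any(c("quant", "detest", "eld", "dosage") %in% config$stages))
      stop("no counts given and no simulation configured")
    else NULL

    if (!is.null(he) && "quant" %in% config$stages) {
      stage <- "quant"
      he <- computeFpkm(he)
      n0 <- nrow(he)
      he <- filterCoexpressed(he)
      flt <- metadata(he)$coexpression_filter
      logmsg("coexpression filter: %d of %d genes retained, %d removed",
             flt$retained, n0, flt$removed)
      writeCountsTsv(he, file.path(config$out_dir, "fpkm.tsv"), "fpkm")
      summary$coexpressed <- list(retained = flt$retained,
                                  removed = flt$removed)
    }
    total <- if (!is.null(he)) nrow(he) else 0L

    calls <- list()
    if (!is.null(he) && "detest" %in% config$stages) {
      stage <- "detest"
      parents <- c(roles$maternal, roles$paternal)
      contrasts <- c(lapply(roles$hybrids, function(h) c(h, parents[1])),
                     lapply(roles$hybrids, function(h) c(h, parents[2])),
                     list(parents))
      deg <- list()
      for (ct in contrasts) {
        nm <- paste0(ct[1], "_vs_", ct[2])
        cl <- nbExactTest(he, ct[1], ct[2],
                          fdrCutoff = config$deg_fdr, lfcCutoff = config$lfc)
        calls[[nm]] <- cl
        .writeTsv(cl, file.path(config$out_dir, paste0("deg_", nm, ".tsv")))
        up <- sum(cl$sign == 1); down <- sum(cl$sign == -1)
        deg[[nm]] <- list(up = up, up_pct = .pct(up, total),
                          down = down, down_pct = .pct(down, total),
                          total = up + down,
                          total_pct = .pct(up + down, total))
        logmsg("DEG %s: %d up, %d down of %d", nm, up, down, total)
      }
      summary$deg <- deg
    }

    if (length(calls) && "eld" %in% config$stages) {
      stage <- "eld"
      eld <- list(); assignments <- list(); eldSummaries <- list()
      for (h in roles$hybrids) {
        trio <- classifyTrios(
          .reSign(calls[[paste0(h, "_vs_", roles$maternal)]],
                  config$category_fdr, config$lfc),
          .reSign(calls[[paste0(h, "_vs_", roles$paternal)]],
                  config$category_fdr, config$lfc),
          .reSign(calls[[paste0(roles$maternal, "_vs_", roles$paternal)]],
                  config$category_fdr, config$lfc))
        assignments[[h]] <- trio$assignments
        eldSummaries[[h]] <- trio$summary
        .writeTsv(trio$assignments,
                  file.path(config$out_dir, paste0("eld_", h, ".tsv")))
        s <- trio$summary
        s$pct <- .pct(s$count, total)
        .writeTsv(s, file.path(config$out_dir, paste0("eld_summary_", h, ".tsv")))
        eld[[h]] <- setNames(as.list(s$count), s$group_label)
        eld[[h]]$pct <- setNames(as.list(s$pct), s$group_label)
        logmsg("ELD %s: %s", h,
               paste(sprintf("%s=%d", s$group_label, s$count), collapse = " "))
      }
      if (length(roles$hybrids) == 2) {
        asym <- eldAsymmetryTest(eldSummaries[[1]], eldSummaries[[2]],
                                 labels = roles$hybrids)
        summary$eld_asymmetry <- list(eld_p = asym$eld$p,
                                      updown_p = asym$updown$p)
        ov <- eldInheritanceOverlap(assignments[[1]], assignments[[2]])
        summary$eld_inheritance <- as.list(ov)
        logmsg("ELD asymmetry: parental p=%.3g, up/down p=%.3g",
               asym$eld$p, asym$updown$p)
      }
      summary$eld <- eld
    }

    if (!is.null(he) && "dosage" %in% config$stages &&
        "fpkm" %in% assayNames(he)) {
      stage <- "dosage"
      mpv <- buildMpv(he)
      grp <- sampleGroups(he)
      f <- assay(he, "fpkm")
      cmp <- lapply(roles$hybrids, function(h)
        compareToMpv(f[, grp == h, drop = FALSE], mpv,
                     lfcCutoff = config$mpv_lfc))
      names(cmp) <- roles$hybrids
      for (h in roles$hybrids)
        .writeTsv(cmp[[h]]$calls,
                  file.path(config$out_dir, paste0("mpv_", h, ".tsv")))
      ds <- dosageSummary(cmp[[1]], if (length(cmp) > 1) cmp[[2]])
      ds$hybrid <- rep(roles$hybrids, each = 3)[seq_len(nrow(ds))]
      ds$up_pct <- .pct(ds$up, total)
      ds$down_pct <- .pct(ds$down, total)
      .writeTsv(ds, file.path(config$out_dir, "dosage_summary.tsv"))
      summary$dosage <- lapply(seq_len(nrow(ds)), function(i) as.list(ds[i, ]))
      logmsg("dosage: %s",
             paste(sprintf("%s/%s up=%d down=%d", ds$hybrid, ds$profile,
                           ds$up, ds$down), collapse = "; "))
    }

    if (!is.null(config$fasta) && "ortho" %in% config$stages) {
      stage <- "ortho"
      sets <- if (is.character(config$fasta)) readFastaDir(config$fasta)
              else config$fasta
      groups <- orthologGroups(sets)
      linked <- trimAndLink(groups)
      logmsg("ortho: %d orthologs linked into %d bp per sample",
             nrow(linkedSegments(linked)), width(linkedSequences(linked))[1])
      writeXStringSet(linkedSequences(linked),
                      file.path(config$out_dir, "linked_orthologs.fasta"))
      idm <- identityMatrix(linked)
      .writeTsv(cbind(sample = rownames(idm),
                      as.data.frame(round(idm, 4), check.names = FALSE)),
                file.path(config$out_dir, "identity_matrix.tsv"))
      comp <- baseComposition(linked)
      .writeTsv(comp, file.path(config$out_dir, "base_composition.tsv"))
      tr <- njTree(idm)
      writeLines(tr$newick, file.path(config$out_dir, "tree.nwk"))
      summary$ortho <- list(n_orthologs = nrow(linkedSegments(linked)),
                            linked_length = width(linkedSequences(linked))[1],
                            identity = as.list(
                              setNames(as.numeric(idm[lower.tri(idm)]),
                                       outer(rownames(idm), colnames(idm),
                                             paste, sep = "|")[lower.tri(idm)])),
                            newick = tr$newick)
    }
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    logmsg("FAILED at stage '%s': %s", stage, conditionMessage(attr(result, "condition")))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(attr(result, "condition")))
  }
  write_json(summary, file.path(config$out_dir, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done; outputs in %s", config$out_dir)
  invisible(summary)
}

#' Validate a pipeline summary against the shipped schema
#'
#' Structural check of `summary.json` against the schema in
#' `inst/extdata/summary-schema.json`: every required key must be present
#' and of the declared JSON type.
#'
#' @param summary a summary list (from [runPipeline()]) or a path to a
#'   `summary.json`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validateSummary <- function(summary) {
  if (is.character(summary)) summary <- read_json(summary, simplifyVector = FALSE)
  schema <- read_json(system.file("extdata", "summary-schema.json",
                                  package = "polyhybrid"),
                      simplifyVector = FALSE)
  checkType <- function(x, type, where) {
    ok <- switch(type,
                 object = is.list(x),
                 number = is.numeric(x) || (is.list(x) && all(vapply(x, is.numeric, logical(1)))),
                 integer = is.numeric(x),
                 string = is.character(x),
                 TRUE)
    if (!ok) stop("summary field '", where, "' is not of type ", type)
  }
  for (req in schema$required) {
    if (is.null(summary[[req]]))
      stop("summary is missing required field '", req, "'")
    tp <- schema$properties[[req]]$type
    if (!is.null(tp)) checkType(summary[[req]], tp, req)
  }
  invisible(TRUE)
}
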