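# End-to-end orchestration: QC -> normalization -> malignancy rescue ->
# ssGSEA scoring -> temporal modeling -> archetype discovery, with a
# content-hashed run manifest.

.readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  hasSim <- !is.null(config$simulate)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput) {
    stop("config must provide exactly one of 'simulate' or 'input'")
  }
  config
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort loading (from matrix/TSV/GMT paths) or
#' simulation, QC filtering, log-normalization, AUC-gated ploidy rescue,
#' ssGSEA scoring of malignant (aneuploid-labeled) cells, per-patient
#' temporal linear modeling of pathway scores, and archetype discovery (SVD
#' reduction; batch-component removal when more than one patient is present;
#' consensus-PAC K selection; SNN-Louvain clustering; Wilcoxon profiles;
#' per-cycle proportions). Every emitted file is listed, with its MD5
#' content hash, in \code{manifest.json}; re-running with the same config
#' and seed reproduces the hashes. A stage failure aborts with the stage
#' name after writing the partial manifest.
#'
#' All randomness derives from \code{config$seed} through named per-stage
#' substreams.
#'
#' @param config A list or path to a YAML file. Top-level fields: exactly
#'   one of \code{simulate} (arguments to [SimParam()]) or \code{input}
#'   (paths \code{matrix}, \code{genes}, \code{cells}, \code{gmt});
#'   optional \code{qc}, \code{ssgsea}, \code{consensus}, \code{graph},
#'   \code{classifier}, \code{temporal} parameter blocks; \code{seed};
#'   \code{outdir}.
#' @param outdir Output directory (overrides \code{config$outdir}).
#' @param seed Global seed (overrides \code{config$seed}; default 1).
#' @param verbose Emit stage messages.
#' @return The manifest, invisibly: a list with the output paths, hashes,
#'   seed, selected K and proportion table.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL, verbose = TRUE) {
  config <- .readRunConfig(config)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  seed <- as.integer(seed)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed, stages = character(0), files = list())
  emitted <- character(0)
  finishStage <- function(name, paths = character(0)) {
    manifest$stages <<- c(manifest$stages, name)
    emitted <<- c(emitted, paths)
  }
  writeManifest <- function(partial = FALSE) {
    manifest$partial <<- partial
    manifest$files <<- lapply(unname(emitted), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeManifest(partial = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- load or simulate ----
  bundle <- stage("load", {
    if (!is.null(config$simulate)) {
      simArgs <- config$simulate
      if (is.null(simArgs$seed)) simArgs$seed <- .subSeed(seed, "simulate")
      if (!is.null(simArgs$cnaSegments)) {
        simArgs$cnaSegments <- as.data.frame(simArgs$cnaSegments)
      }
      simulateCohort(do.call(SimParam, simArgs), verbose = verbose)
    } else {
      inp <- config$input
      for (f in c("matrix", "genes", "cells", "gmt")) {
        if (is.null(inp[[f]])) stop("input path '", f, "' missing")
        if (!file.exists(inp[[f]])) stop("input file not found: ", inp[[f]])
      }
      list(sce = readCounts(inp$matrix, inp$genes, inp$cells),
           geneSets = readGMT(inp$gmt), truth = NULL)
    }
  })
  finishStage("load")

  # ---- QC ----
  sce <- stage("qc", {
    qc <- do.call(QcParam, as.list(config$qc))
    qcFilter(bundle$sce, qc, verbose = verbose)
  })
  qcPath <- .writeTsv(S4Vectors::metadata(sce)$qcReport,
                      file.path(outdir, "qc_report.tsv"))
  finishStage("qc", qcPath)

  # ---- normalization ----
  sce <- stage("normalize", logNormalize(sce))
  finishStage("normalize")

  # ---- malignancy rescue ----
  sce <- stage("classify", {
    pl <- SummarizedExperiment::colData(sce)$ploidy
    clsArgs <- as.list(config$classifier)
    if (sum(unique(pl) %in% c("diploid", "aneuploid")) == 2L) {
      model <- do.call(trainReferenceClassifier,
                       c(list(sce = sce, seed = .subSeed(seed, "classifier"),
                              verbose = verbose), clsArgs))
      jsonlite::write_json(
        list(cv_auc = cvAuc(model), accepted = isAccepted(model),
             gate = model@gateThreshold, folds = model@folds,
             panel_size = length(variableGenes(model))),
        file.path(outdir, "classifier.json"), auto_unbox = TRUE)
      reclassifyUndefined(model, sce, verbose = verbose)
    } else {
      .msg("classify: fewer than two confident ploidy labels; skipped",
           verbose = verbose)
      sce
    }
  })
  clsFile <- file.path(outdir, "classifier.json")
  metaPath <- .writeTsv(as.data.frame(SummarizedExperiment::colData(sce)),
                        file.path(outdir, "metadata.tsv"))
  finishStage("classify", c(if (file.exists(clsFile)) clsFile, metaPath))

  # ---- ssGSEA scoring of malignant cells ----
  res <- stage("score", {
    malig <- SummarizedExperiment::colData(sce)$ploidy == "aneuploid"
    if (sum(malig) < 10L) stop("fewer than 10 malignant cells to score")
    sub <- sce[, malig]
    sp <- do.call(SsgseaParam, as.list(config$ssgsea))
    list(sub = sub, scores = ssgseaScores(sub, bundle$geneSets, sp,
                                          verbose = verbose))
  })
  scoreMat <- SummarizedExperiment::assay(res$scores, "ssgsea")
  scorePath <- .writeTsv(
    data.frame(set = rownames(scoreMat), scoreMat, check.names = FALSE),
    file.path(outdir, "scores.tsv"))
  finishStage("score", scorePath)

  # ---- temporal modeling of pathway scores ----
  temporal <- stage("temporal", {
    meta <- as.data.frame(SummarizedExperiment::colData(res$sub))
    volcanoTable(fitTemporalLinear(res$scores, meta, verbose = verbose))
  })
  tempPath <- .writeTsv(temporal, file.path(outdir, "temporal_pathways.tsv"))
  finishStage("temporal", tempPath)

  # ---- archetype discovery ----
  arch <- stage("archetypes", {
    meta <- as.data.frame(SummarizedExperiment::colData(res$sub))
    emb <- reduceSVD(res$scores)
    if (length(unique(meta$patient)) > 1L) {
      emb <- removeBatchComponent(emb, meta$patient)
    }
    cp <- as.list(config$consensus)
    cp$seed <- .subSeed(seed, "consensus")
    maxK <- min(10L, nrow(embCoords(emb)) %/% 5L)
    if (is.null(cp$kRange)) cp$kRange <- 2:maxK
    cons <- consensusSelectK(emb, do.call(ConsensusParam, cp),
                             verbose = verbose)
    gr <- as.list(config$graph)
    asn <- do.call(clusterToK, c(list(emb = emb, targetK = selectedK(cons),
                                      seed = .subSeed(seed, "louvain"),
                                      verbose = verbose), gr))
    prof <- dpeWilcoxon(res$scores, archetypeLabels(asn))
    props <- archetypeProportions(archetypeLabels(asn), meta)
    list(emb = emb, cons = cons, asn = asn, prof = prof, props = props)
  })
  embPath <- .writeTsv(
    data.frame(cell_id = rownames(embCoords(arch$emb)),
               embCoords(arch$emb), check.names = FALSE),
    file.path(outdir, "embedding.tsv"))
  stabPath <- .writeTsv(
    data.frame(k = as.integer(names(pacValues(arch$cons))),
               pac = unname(pacValues(arch$cons)),
               stability = unname(stabilityValues(arch$cons)),
               selected = as.integer(names(pacValues(arch$cons))) ==
                 selectedK(arch$cons)),
    file.path(outdir, "consensus_stability.tsv"))
  labPath <- .writeTsv(
    data.frame(cell_id = names(archetypeLabels(arch$asn)),
               archetype = as.character(archetypeLabels(arch$asn))),
    file.path(outdir, "archetype_labels.tsv"))
  profPath <- .writeTsv(arch$prof, file.path(outdir, "archetype_profiles.tsv"))
  propPath <- .writeTsv(arch$props,
                        file.path(outdir, "archetype_proportions.tsv"))
  finishStage("archetypes", c(embPath, stabPath, labPath, profPath, propPath))

  manifest$selected_k <- selectedK(arch$cons)
  writeManifest(partial = FALSE)
  .msg(sprintf("runPipeline: complete; %d files in %s",
               length(emitted) + 1L, outdir), verbose = verbose)
  manifest$proportions <- arch$props
  invisible(manifest)
}
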