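# AUC-gated rank-correlation classifier rescuing ambiguous ploidy calls.

# Spearman correlation of each cell (columns of X) with each reference
# profile column.
.profileCorrelation <- function(X, profiles) {
  Xr <- apply(X, 2L, rank)
  Pr <- apply(profiles, 2L, rank)
  stats::cor(Xr, Pr)
}

# Stratified fold ids: cells of each label are shuffled and dealt round-robin.
.stratifiedFolds <- function(labels, nFolds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(.subSeed(seed, "cv_folds"), {
    for (l in unique(labels)) {
      idx <- sample(which(labels == l))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

#' Train the reference-profile malignancy classifier
#'
#' Trains on cells confidently labeled \code{"diploid"} or \code{"aneuploid"}:
#' selects a variable-gene panel by count dispersion (variance / mean over
#' the training cells), builds per-label reference profiles as the mean
#' log-normalized expression over the panel, and scores any cell by Spearman
#' correlation with each profile. Performance is estimated by stratified
#' cross-validation: held-out cells are scored by the correlation margin
#' (a label's correlation minus the best competing label's), the one-vs-rest
#' AUC is computed per label over the pooled held-out cells, and
#' \code{cvAuc} is their unweighted mean. The model is \code{accepted} only
#' when \code{cvAuc} strictly exceeds the gate threshold (default 0.7).
#'
#' @param sce SingleCellExperiment with \code{"counts"} and \code{"lognorm"}
#'   assays and a \code{ploidy} column in its \code{colData}.
#' @param nVariableGenes Panel size (default 2000, capped at the gene count).
#' @param cvFolds Cross-validation folds (default 5); reduced with a warning
#'   when the rarest label has fewer cells.
#' @param gateThreshold Acceptance gate on cvAuc (default 0.7, strict).
#' @param seed Seed for fold assignment.
#' @param verbose Emit progress messages.
#' @return A \linkS4class{ClassifierModel}.
#' @seealso [reclassifyUndefined()]
#' @export
trainReferenceClassifier <- function(sce, nVariableGenes = 2000, cvFolds = 5,
                                     gateThreshold = 0.7, seed = 1L,
                                     verbose = TRUE) {
  cd <- SummarizedExperiment::colData(sce)
  if (!"ploidy" %in% names(cd)) stop("colData must contain 'ploidy'")
  train <- which(cd$ploidy %in% c("diploid", "aneuploid"))
  labels <- as.character(cd$ploidy[train])
  tab <- table(labels)
  if (length(tab) < 2L) {
    stop("need both diploid and aneuploid training cells")
  }
  nFolds <- as.integer(cvFolds)
  if (min(tab) < nFolds) {
    nFolds <- max(2L, as.integer(min(tab)))
    warning("rarest label has ", min(tab), " cells; reducing to ",
            nFolds, " folds")
  }
  counts <- .assayMatrix(sce[, train], "counts")
  ln <- .assayMatrix(sce[, train], "lognorm")
  mu <- rowMeans(counts)
  disp <- ifelse(mu > 0, matrixStats::rowVars(counts) / mu, -Inf)
  nPanel <- min(nVariableGenes, sum(is.finite(disp) & disp > -Inf))
  panel <- rownames(counts)[order(disp, decreasing = TRUE)[seq_len(nPanel)]]

  buildProfiles <- function(mat, lab) {
    vapply(sort(unique(lab)), function(l) {
      rowMeans(mat[, lab == l, drop = FALSE])
    }, numeric(nrow(mat)))
  }
  fold <- .stratifiedFolds(labels, nFolds, seed)
  labelLevels <- sort(unique(labels))
  margin <- matrix(NA_real_, length(train), length(labelLevels),
                   dimnames = list(NULL, labelLevels))
  for (f in seq_len(nFolds)) {
    inTrain <- fold != f
    prof <- buildProfiles(ln[panel, inTrain, drop = FALSE], labels[inTrain])
    cc <- .profileCorrelation(ln[panel, !inTrain, drop = FALSE], prof)
    for (l in labelLevels) {
      other <- apply(cc[, setdiff(labelLevels, l), drop = FALSE], 1L, max)
      margin[!inTrain, l] <- cc[, l] - other
    }
  }
  aucs <- vapply(labelLevels, function(l) {
    .rankAuc(margin[, l], labels == l)
  }, numeric(1))
  cvauc <- mean(aucs)
  prof <- buildProfiles(ln[panel, , drop = FALSE], labels)
  accepted <- cvauc > gateThreshold
  .msg(sprintf("trainReferenceClassifier: cvAuc = %.4f (%s)", cvauc,
               if (accepted) "accepted" else "rejected"), verbose = verbose)
  new("ClassifierModel", profiles = prof, panel = panel, cvAuc = cvauc,
      gateThreshold = gateThreshold, accepted = accepted,
      folds = nFolds, seed = as.integer(seed))
}

#' Reclassify cells with undefined ploidy
#'
#' Applies an accepted \linkS4class{ClassifierModel} to every
#' \code{"not.defined"} cell, assigning the label whose reference profile it
#' correlates with best. Cells already labeled diploid or aneuploid are
#' never altered, and a \code{ploidy_source} column records which cells were
#' rescued. A rejected model (cvAuc at or below the gate) makes this a
#' no-op: the metadata is returned unchanged apart from the provenance
#' column, with an explanatory message.
#'
#' @param model A \linkS4class{ClassifierModel}.
#' @param sce SingleCellExperiment with a \code{"lognorm"} assay and
#'   \code{ploidy} in its \code{colData}.
#' @param verbose Emit messages.
#' @return The SingleCellExperiment with updated \code{ploidy} and an added
#'   \code{ploidy_source} column ("original" or "rescued").
#' @export
reclassifyUndefined <- function(model, sce, verbose = TRUE) {
  stopifnot(is(model, "ClassifierModel"))
  cd <- SummarizedExperiment::colData(sce)
  cd$ploidy_source <- rep("original", ncol(sce))
  if (!isAccepted(model)) {
    .msg(sprintf(
      "classifier rejected (cvAuc = %.3f <= %.2f); no cells reclassified",
      cvAuc(model), model@gateThreshold), verbose = verbose)
    SummarizedExperiment::colData(sce) <- cd
    return(sce)
  }
  nd <- which(cd$ploidy == "not.defined")
  if (length(nd)) {
    ln <- .assayMatrix(sce[, nd], "lognorm")
    cc <- .profileCorrelation(ln[variableGenes(model), , drop = FALSE],
                              referenceProfiles(model))
    pred <- colnames(referenceProfiles(model))[max.col(cc, ties.method = "first")]
    cd$ploidy[nd] <- pred
    cd$ploidy_source[nd] <- "rescued"
  }
  .msg(sprintf("reclassifyUndefined: rescued %d cell(s)", length(nd)),
       verbose = verbose)
  SummarizedExperiment::colData(sce) <- cd
  sce
}
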