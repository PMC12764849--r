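# Temporal linear modeling of pathway scores / gene expression across
# treatment cycles, with Benjamini-Hochberg control.

#' Per-feature linear model of value against treatment cycle
#'
#' Fits, for every feature (pathway score or gene), an ordinary least squares
#' regression of the per-cell value on the numeric treatment cycle, with
#' cells as independent observations. Biopsy sites within a cycle are pooled.
#' The slope, its standard error, the two-sided t-test p-value and the
#' Benjamini-Hochberg FDR (adjusted across features within each patient) are
#' returned per (patient, feature). Fitting is done in one pass per patient
#' with \code{limma::lmFit} (classical, unmoderated t statistics).
#'
#' Degenerate cases: a patient with a single distinct cycle is skipped with a
#' warning; a zero-variance (constant) feature gets estimate 0 with missing
#' p and FDR; a feature fit exactly (zero residual variance, nonzero slope)
#' gets p = 0.
#'
#' @param values A \linkS4class{PathwayScores}, a SingleCellExperiment with a
#'   \code{"lognorm"} assay, or a features x cells numeric matrix.
#' @param meta A data.frame (or DataFrame) with one row per cell of
#'   \code{values}, containing \code{patient} and integer \code{cycle}. When
#'   \code{values} is a SummarizedExperiment its \code{colData} is used if
#'   \code{meta} is NULL.
#' @param groupByPatient Fit each patient separately (default TRUE); with
#'   FALSE all cells are pooled into a single group labeled "all".
#' @param verbose Emit progress messages.
#' @return A data.frame with columns patient, feature, estimate, se, t, p,
#'   fdr, n_cells, one row per (patient, feature).
#' @seealso [bhAdjust()], [volcanoTable()]
#' @export
fitTemporalLinear <- function(values, meta = NULL, groupByPatient = TRUE,
                              verbose = TRUE) {
  if (is(values, "SummarizedExperiment")) {
    if (is.null(meta)) {
      meta <- as.data.frame(SummarizedExperiment::colData(values))
    }
    layer <- if (is(values, "PathwayScores")) "ssgsea" else "lognorm"
    X <- .assayMatrix(values, layer)
  } else {
    X <- as.matrix(values)
  }
  if (is.null(meta) || !all(c("patient", "cycle") %in% names(meta))) {
    stop("meta must provide 'patient' and 'cycle' columns")
  }
  if (nrow(meta) != ncol(X)) stop("meta must have one row per cell")
  groups <- if (groupByPatient) as.character(meta$patient) else
    rep("all", nrow(meta))

  res <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    cyc <- as.numeric(meta$cycle[idx])
    if (length(unique(cyc)) < 2L) {
      warning("patient '", g, "' has a single cycle; skipped")
      return(NULL)
    }
    fit <- limma::lmFit(X[, idx, drop = FALSE],
                        design = cbind(Intercept = 1, cycle = cyc))
    est <- fit$coefficients[, "cycle"]
    se <- fit$stdev.unscaled[, "cycle"] * fit$sigma
    tstat <- est / se
    p <- 2 * stats::pt(abs(tstat), df = fit$df.residual, lower.tail = FALSE)
    constant <- matrixStats::rowVars(X[, idx, drop = FALSE]) == 0
    est[constant] <- 0
    p[constant] <- NA_real_
    se[constant] <- NA_real_
    tstat[constant] <- NA_real_
    # exact (residual-free) non-constant fits: infinitely significant
    exact <- !constant & fit$sigma == 0
    p[exact] <- 0
    tstat[exact] <- sign(est[exact]) * Inf
    data.frame(patient = g, feature = rownames(X), estimate = unname(est),
               se = unname(se), t = unname(tstat), p = unname(p),
               fdr = bhAdjust(unname(p)), n_cells = length(idx),
               row.names = NULL)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no patient had at least two distinct cycles")
  .msg(sprintf("fitTemporalLinear: %d features x %d group(s)",
               nrow(X), length(unique(res$patient))), verbose = verbose)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH FDR with monotonicity enforcement, order-preserving on the
#' input order. Missing values are passed through untouched and excluded
#' from the adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return FDR values in the input order; \code{fdr >= p} elementwise.
#' @examples
#' bhAdjust(c(0.005, 0.04, 0.06))  # 0.015 0.060 0.060
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("validation error: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Annotate temporal fits for a volcano display
#'
#' Adds a signed significance class to a [fitTemporalLinear()] table:
#' \code{"up"} when \code{fdr < fdrCutoff} and
#' \code{estimate > estimateCutoff}, \code{"down"} when \code{fdr < fdrCutoff}
#' and \code{estimate < -estimateCutoff}, otherwise \code{"ns"}. Both cutoffs
#' are strict: a feature at exactly the FDR cutoff is not significant. The
#' table is returned sorted by FDR (NAs last).
#'
#' @param results Output of [fitTemporalLinear()].
#' @param estimateCutoff Minimum absolute slope (default 0).
#' @param fdrCutoff FDR threshold (default 0.05).
#' @return The annotated, FDR-sorted data.frame with a \code{class} column.
#' @export
volcanoTable <- function(results, estimateCutoff = 0, fdrCutoff = 0.05) {
  stopifnot(all(c("estimate", "fdr") %in% names(results)))
  cls <- rep("ns", nrow(results))
  sig <- !is.na(results$fdr) & results$fdr < fdrCutoff
  cls[sig & results$estimate > estimateCutoff] <- "up"
  cls[sig & results$estimate < -estimateCutoff] <- "down"
  results$class <- factor(cls, levels = c("up", "down", "ns"))
  results[order(results$fdr, na.last = TRUE), , drop = FALSE]
}
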