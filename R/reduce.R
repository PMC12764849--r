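# SVD reduction of pathway-score space and batch-component removal.

#' SVD reduction of the pathway-score matrix
#'
#' Column-centers the cells x pathways score matrix (no variance scaling)
#' and decomposes it by SVD, retaining the smallest leading set of components
#' whose cumulative variance reaches \code{target}.
#'
#' @param scores A \linkS4class{PathwayScores} (sets x cells) or a cells x
#'   pathways numeric matrix.
#' @param target Cumulative variance retention target (default 0.90).
#' @return A \linkS4class{ReducedEmbedding} whose coordinates are the cell
#'   projections \eqn{U_r D_r} and whose loadings are the pathway right
#'   singular vectors.
#' @export
reduceSVD <- function(scores, target = 0.90) {
  X <- if (is(scores, "PathwayScores")) {
    t(.assayMatrix(scores, "ssgsea"))
  } else {
    as.matrix(scores)
  }
  if (nrow(X) < 2L || ncol(X) < 2L) {
    stop("need at least 2 cells and 2 pathways")
  }
  if (nrow(unique(X)) < 2L) {
    stop("rank-deficient input: fewer than 2 distinct cells")
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  ve <- sv$d^2 / sum(sv$d^2)
  r <- which(cumsum(ve) >= target)[1]
  if (is.na(r)) r <- length(ve)
  coords <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], nrow = r)
  dimnames(coords) <- list(rownames(X), paste0("SV", seq_len(r)))
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  dimnames(loadings) <- list(colnames(X), paste0("SV", seq_len(r)))
  new("ReducedEmbedding", coords = coords, varExplained = ve[seq_len(r)],
      target = target, centering = ctr, loadings = loadings,
      removedComponent = NA_integer_, removedLoadings = numeric(0))
}

#' Remove the batch-carrying SVD component
#'
#' Scales the retained components to unit variance, computes for each
#' component the distance between batch-group means (for more than two
#' groups, the maximum pairwise absolute mean difference) and removes
#' exactly the component with the largest distance — the direction a global
#' per-batch shift concentrates in. Ties go to the lowest-index component.
#' When the largest distance falls below \code{negligible} a warning is
#' logged; removal still occurs unless \code{removeNegligible = FALSE}.
#' A single batch label makes this a no-op with a warning.
#'
#' @param emb A \linkS4class{ReducedEmbedding}.
#' @param batch Vector of batch (patient) labels, one per cell.
#' @param negligible Distance (in within-component SD units) under which the
#'   separation is considered negligible (default 0.1).
#' @param removeNegligible Remove the component even when the separation is
#'   negligible (default TRUE).
#' @return The embedding without the batch component; its original index and
#'   loadings are recorded in the \code{removedComponent} /
#'   \code{removedLoadings} slots.
#' @export
removeBatchComponent <- function(emb, batch, negligible = 0.1,
                                 removeNegligible = TRUE) {
  stopifnot(is(emb, "ReducedEmbedding"))
  batch <- as.character(batch)
  if (length(batch) != nrow(emb@coords)) {
    stop("one batch label per cell required")
  }
  grp <- unique(batch)
  if (length(grp) < 2L) {
    warning("single batch label; no component removed")
    return(emb)
  }
  Z <- scale(emb@coords)
  means <- vapply(grp, function(g) {
    colMeans(Z[batch == g, , drop = FALSE])
  }, numeric(ncol(Z)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  dists <- apply(means, 1L, function(m) max(stats::dist(m)))
  j <- unname(which.max(dists))  # ties resolve to the lowest index
  if (dists[j] < negligible) {
    warning(sprintf(
      "largest between-batch distance (%.3f SD) is below %.3f%s",
      dists[j], negligible,
      if (removeNegligible) "; removing anyway" else "; not removing"))
    if (!removeNegligible) return(emb)
  }
  if (length(dists) > 1 && dists[j] == max(dists[-j])) {
    warning("tied batch distances; removing the lowest-index component")
  }
  new("ReducedEmbedding",
      coords = emb@coords[, -j, drop = FALSE],
      varExplained = emb@varExplained[-j],
      target = emb@target, centering = emb@centering,
      loadings = emb@loadings[, -j, drop = FALSE],
      removedComponent = as.integer(j),
      removedLoadings = emb@loadings[, j])
}
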