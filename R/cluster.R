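# SNN-Louvain clustering to a target K, archetype characterization and
# per-cycle proportion tracking, and K-means subclone clustering of CNA
# profiles.

#' Cluster cells to a target number of archetypes
#'
#' Builds a k-nearest-neighbor graph (Euclidean, in the reduced embedding,
#' self included), converts it to shared-nearest-neighbor Jaccard weights
#' with pruning, and runs Louvain modularity clustering. The Louvain
#' resolution is found by monotone bisection on \code{resolutionRange} until
#' the cluster count equals \code{targetK} (at most \code{maxSteps} steps);
#' if the target is unreachable the nearest achievable count is returned
#' with a warning, and the realized resolution is recorded either way.
#'
#' @param emb A \linkS4class{ReducedEmbedding} or cells x components matrix.
#' @param targetK Desired number of clusters (normally
#'   \code{selectedK(consensusSelectK(...))}). \code{targetK = 1} returns a
#'   single label without graph construction.
#' @param nNeighbors Neighbors for the kNN graph (default 20).
#' @param pruneJaccard SNN edges with Jaccard weight below this are dropped
#'   (default 1/15).
#' @param resolutionRange Louvain resolution search interval (default
#'   c(0.01, 5)).
#' @param maxSteps Bisection step cap (default 30).
#' @param seed Seed for the Louvain pass.
#' @param verbose Emit progress messages.
#' @return An \linkS4class{ArchetypeAssignment} with labels only (profiles
#'   and proportions are added by [dpeWilcoxon()] /
#'   [archetypeProportions()]).
#' @export
clusterToK <- function(emb, targetK, nNeighbors = 20, pruneJaccard = 1 / 15,
                       resolutionRange = c(0.01, 5), maxSteps = 30,
                       seed = 1L, verbose = TRUE) {
  X <- if (is(emb, "ReducedEmbedding")) embCoords(emb) else as.matrix(emb)
  n <- nrow(X)
  targetK <- as.integer(targetK)
  if (targetK > n) stop("targetK exceeds the number of cells")
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(n))
  if (targetK == 1L) {
    lab <- factor(rep("A1", n))
    names(lab) <- rownames(X)
    return(new("ArchetypeAssignment", labels = lab, resolution = NA_real_,
               targetK = 1L, achievedK = 1L,
               profiles = data.frame(), proportions = data.frame()))
  }
  k <- min(nNeighbors, n - 1L)
  D <- as.matrix(stats::dist(X))
  nnIdx <- t(apply(D, 1L, order))[, seq_len(k), drop = FALSE]  # self first
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nnIdx),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < pruneJaccard] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)

  louvainAt <- function(res) {
    withr::with_seed(.subSeed(seed, "louvain"), {
      igraph::membership(igraph::cluster_louvain(g, resolution = res))
    })
  }
  lo <- resolutionRange[1]
  hi <- resolutionRange[2]
  best <- NULL
  for (step in seq_len(maxSteps)) {
    res <- if (step == 1L) lo else if (step == 2L) hi else (lo + hi) / 2
    memb <- louvainAt(res)
    kAch <- length(unique(memb))
    if (is.null(best) || abs(kAch - targetK) < abs(best$k - targetK)) {
      best <- list(k = kAch, res = res, memb = memb)
    }
    if (kAch == targetK) break
    if (step >= 2L) {
      if (kAch < targetK) lo <- res else hi <- res
    }
  }
  if (best$k != targetK) {
    warning("target of ", targetK, " clusters unreachable; returning ",
            best$k, " clusters at resolution ", signif(best$res, 4))
  }
  .msg(sprintf("clusterToK: %d clusters at resolution %.4g (target %d)",
               best$k, best$res, targetK), verbose = verbose)
  lev <- sort(unique(best$memb))
  lab <- factor(paste0("A", match(best$memb, lev)),
                levels = paste0("A", seq_along(lev)))
  names(lab) <- rownames(X)
  new("ArchetypeAssignment", labels = lab, resolution = best$res,
      targetK = targetK, achievedK = as.integer(best$k),
      profiles = data.frame(), proportions = data.frame())
}

#' Differential pathway enrichment profiles per archetype
#'
#' For each archetype, compares every pathway's scores in the archetype's
#' cells against all other cells with a two-sided Wilcoxon rank-sum test;
#' the effect is the difference of mean scores and p-values are BH-adjusted
#' across pathways within the archetype. The profile keeps the \code{topN}
#' pathways with positive effect (enriched in the archetype), ranked by FDR
#' and then by decreasing absolute effect. Archetypes with fewer than 3
#' cells are excluded with a warning.
#'
#' @param scores A \linkS4class{PathwayScores} or sets x cells matrix.
#' @param labels Factor of archetype labels, named by cell or aligned with
#'   the score columns.
#' @param topN Pathways kept per archetype (default 20); if larger than the
#'   pathway count, all positive-effect pathways are returned.
#' @return data.frame(archetype, pathway, effect, p, fdr, rank).
#' @export
dpeWilcoxon <- function(scores, labels, topN = 20) {
  X <- if (is(scores, "PathwayScores")) .assayMatrix(scores, "ssgsea") else
    as.matrix(scores)
  labels <- as.factor(labels)
  if (!is.null(names(labels)) && !is.null(colnames(X))) {
    labels <- labels[colnames(X)]
  }
  if (length(labels) != ncol(X)) stop("one label per cell required")
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 archetypes")
  small <- names(which(table(labels) < 3L))
  if (length(small)) {
    warning("excluding archetype(s) with < 3 cells: ",
            paste(small, collapse = ", "))
  }
  keepLev <- setdiff(levels(droplevels(labels)), small)
  out <- lapply(keepLev, function(a) {
    inA <- labels == a
    p <- apply(X, 1L, function(v) {
      suppressWarnings(stats::wilcox.test(v[inA], v[!inA])$p.value)
    })
    eff <- rowMeans(X[, inA, drop = FALSE]) -
      rowMeans(X[, !inA, drop = FALSE])
    fdr <- bhAdjust(p)
    d <- data.frame(archetype = a, pathway = rownames(X), effect = eff,
                    p = p, fdr = fdr, row.names = NULL)
    d <- d[d$effect > 0, , drop = FALSE]
    d <- d[order(d$fdr, -abs(d$effect)), , drop = FALSE]
    d <- utils::head(d, topN)
    if (nrow(d)) d$rank <- seq_len(nrow(d))
    d
  })
  do.call(rbind, out)
}

#' Archetype proportions per patient and cycle
#'
#' For every (patient, cycle) with clustered cells, the fraction of cells in
#' each archetype. Fractions sum to 1 per (patient, cycle). A (patient,
#' cycle) present in the metadata but without any clustered cells is omitted
#' with a warning.
#'
#' @param labels Factor of archetype labels, named by cell id.
#' @param meta data.frame (or DataFrame) with cell ids as rownames or a
#'   \code{cell_id} column, plus \code{patient} and \code{cycle}.
#' @return data.frame(patient, cycle, archetype, n, proportion).
#' @export
archetypeProportions <- function(labels, meta) {
  meta <- as.data.frame(meta)
  if (!is.null(meta$cell_id)) rownames(meta) <- meta$cell_id
  if (is.null(names(labels))) stop("labels must be named by cell id")
  missing <- setdiff(names(labels), rownames(meta))
  if (length(missing)) stop("metadata missing for ", length(missing), " cells")
  md <- meta[names(labels), , drop = FALSE]
  allGroups <- unique(meta[, c("patient", "cycle")])
  covered <- unique(md[, c("patient", "cycle")])
  lost <- nrow(allGroups) - nrow(covered)
  if (lost > 0) {
    warning(lost, " (patient, cycle) group(s) have no clustered cells; omitted")
  }
  grp <- interaction(md$patient, md$cycle, drop = TRUE)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    tab <- table(labels[sel])
    data.frame(patient = md$patient[sel][1], cycle = md$cycle[sel][1],
               archetype = names(tab), n = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab), row.names = NULL)
  }))
  out[order(out$patient, out$cycle, out$archetype), , drop = FALSE]
}

#' K-means subclone clustering of CNA profiles
#'
#' Euclidean k-means (10 restarts, seeded) of per-cell copy-number profiles,
#' with an optional per-cluster per-cycle abundance table. Fewer distinct
#' profiles than clusters triggers a warning and a seed-stable arbitrary
#' split.
#'
#' @param profiles Cells x genomic-bins numeric matrix.
#' @param k Number of subclones (default 2).
#' @param meta Optional metadata with \code{patient} and \code{cycle} for the
#'   abundance table (cell ids as rownames or \code{cell_id} column).
#' @param seed Seed for the k-means restarts.
#' @param nstart Random restarts (default 10).
#' @return list(labels = factor named by cell, abundance = data.frame or
#'   NULL).
#' @export
kmeansCnaSubclones <- function(profiles, k = 2, meta = NULL, seed = 1L,
                               nstart = 10) {
  X <- as.matrix(profiles)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(n))
  if (nrow(unique(X)) < k) {
    warning("fewer distinct profiles than clusters; arbitrary seed-stable split")
    cl <- withr::with_seed(.subSeed(seed, "cna_split"),
                           sample(rep_len(seq_len(k), n)))
  } else {
    cl <- withr::with_seed(.subSeed(seed, "cna_kmeans"),
                           stats::kmeans(X, centers = k, nstart = nstart,
                                         iter.max = 50)$cluster)
  }
  lab <- factor(paste0("S", cl), levels = paste0("S", seq_len(k)))
  names(lab) <- rownames(X)
  abundance <- NULL
  if (!is.null(meta)) {
    ab <- archetypeProportions(lab, meta)
    names(ab)[names(ab) == "archetype"] <- "subclone"
    abundance <- ab
  }
  list(labels = lab, abundance = abundance)
}
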