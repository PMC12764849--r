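# Per-cell single-sample gene-set enrichment (ssGSEA).

#' Per-cell ssGSEA scores
#'
#' Computes the single-sample gene-set enrichment statistic for every cell
#' and gene set. Within each cell, genes are ranked by decreasing expression
#' with the rank statistic assigning \eqn{r = N} to the top gene and
#' \eqn{r = 1} to the bottom (ties, including the zero block of sparse data,
#' get the average rank). Walking the ordered gene list, the weighted in-set
#' empirical CDF
#' \deqn{P^G_W(i) = \sum_{j \in S,\; pos(j) \le i} r_j^\alpha \Big/
#'       \sum_{j \in S} r_j^\alpha}
#' is compared to the out-of-set ECDF
#' \eqn{P_{NG}(i) = |\{j \notin S: pos(j) \le i\}| / (N - |S|)}, and the
#' enrichment score is the full running sum
#' \eqn{ES = \sum_{i=1}^N [P^G_W(i) - P_{NG}(i)]} (not the maximum
#' deviation). With \code{normalize = TRUE} every score is divided by the
#' global max minus min of the score matrix, an order-preserving rescale.
#'
#' Gene sets are intersected with the expression rownames; sets that end up
#' empty, equal to all genes (the out-of-set ECDF would be undefined), or
#' outside \code{[minSize, maxSize]} are dropped with a warning. Tied genes
#' are walked in lexicographic gene-name order, so scores are invariant to
#' any permutation of the input rows and to any strictly monotone per-cell
#' transform of expression.
#'
#' @param expr A SingleCellExperiment with a \code{"lognorm"} assay (see
#'   [logNormalize()]), or a genes x cells numeric matrix.
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param param An \linkS4class{SsgseaParam}.
#' @param verbose Emit progress messages.
#' @return A \linkS4class{PathwayScores} (sets x cells) with the parameter
#'   snapshot in \code{metadata(.)$ssgseaParam}.
#' @examples
#' x <- matrix(c(3, 2, 1), ncol = 1, dimnames = list(c("A", "B", "C"), "c1"))
#' gsc <- GeneSetCollection(list(TOP = "A", BOTTOM = "C"))
#' s <- ssgseaScores(x, gsc, SsgseaParam(alpha = 0, normalize = FALSE,
#'                                       minSize = 1))
#' SummarizedExperiment::assay(s)  # TOP = 1.5, BOTTOM = -1.5
#' @export
ssgseaScores <- function(expr, gsc, param = SsgseaParam(), verbose = TRUE) {
  stopifnot(is(gsc, "GeneSetCollection"), is(param, "SsgseaParam"))
  X <- .assayMatrix(expr, "lognorm")
  genes <- rownames(X)
  if (is.null(genes)) stop("expression matrix must have gene rownames")
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 genes to score")

  sets <- lapply(geneSets(gsc), function(g) intersect(g, genes))
  sz <- lengths(sets)
  dropEmpty <- sz == 0L
  dropAll <- sz == N
  dropSize <- !dropEmpty & !dropAll & (sz < param@minSize | sz > param@maxSize)
  if (any(dropEmpty)) {
    warning("dropping ", sum(dropEmpty), " set(s) with no genes in the matrix: ",
            paste(utils::head(names(sets)[dropEmpty], 5), collapse = ", "))
  }
  if (any(dropAll)) {
    warning("dropping ", sum(dropAll),
            " set(s) covering all genes (out-of-set ECDF undefined)")
  }
  if (any(dropSize)) {
    warning("dropping ", sum(dropSize), " set(s) outside size bounds [",
            param@minSize, ", ", param@maxSize, "]")
  }
  keep <- !(dropEmpty | dropAll | dropSize)
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene sets survive filtering")
  S <- length(sets)
  sz <- lengths(sets)

  member <- matrix(FALSE, N, S, dimnames = list(genes, names(sets)))
  for (j in seq_len(S)) member[sets[[j]], j] <- TRUE

  nCells <- ncol(X)
  ES <- matrix(NA_real_, S, nCells, dimnames = list(names(sets), colnames(X)))
  for (c in seq_len(nCells)) {
    v <- X[, c]
    # rank statistic: top gene r = N, bottom r = 1, ties averaged
    r <- rank(v, ties.method = "average")
    ord <- order(-v, genes, method = "radix")
    M <- member[ord, , drop = FALSE]
    w <- r[ord]^param@alpha
    win <- M * w
    pin <- matrixStats::colCumsums(win)
    pin <- sweep(pin, 2L, colSums(win), "/")
    pout <- matrixStats::colCumsums((!M) * 1)
    pout <- sweep(pout, 2L, N - sz, "/")
    ES[, c] <- colSums(pin - pout)
  }
  if (isTRUE(param@normalize)) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  .msg(sprintf("ssgseaScores: scored %d sets x %d cells (alpha = %g)",
               S, nCells, param@alpha), verbose = verbose)
  cd <- if (is(expr, "SummarizedExperiment")) {
    SummarizedExperiment::colData(expr)
  } else {
    S4Vectors::DataFrame(row.names = colnames(X))
  }
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ssgsea = ES), colData = cd)
  S4Vectors::metadata(out)$ssgseaParam <- param
  S4Vectors::metadata(out)$scoredSets <- names(sets)
  methods::as(out, "PathwayScores")
}
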