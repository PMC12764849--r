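# Consensus-clustering K selection with the PAC (proportion of ambiguous
# clustering) statistic.

# k-means that tolerates subsamples with <= k distinct points: such draws are
# clustered by row identity so that repeated points always co-cluster.
.kmeansSafe <- function(X, k, iterMax = 50L) {
  ux <- unique(X)
  if (nrow(ux) <= k) {
    return(match(
      do.call(paste, c(as.data.frame(X), sep = "\r")),
      do.call(paste, c(as.data.frame(ux), sep = "\r"))
    ))
  }
  ctr <- ux[sample(nrow(ux), k), , drop = FALSE]
  km <- tryCatch(
    stats::kmeans(X, centers = ctr, iter.max = iterMax),
    error = function(e) stats::kmeans(X, centers = ctr, iter.max = iterMax,
                                      algorithm = "Lloyd")
  )
  km$cluster
}

#' Select the number of archetypes by consensus-clustering stability
#'
#' For each candidate k, runs \code{nIterations} rounds of k-means (Euclidean,
#' one start per round — the round-to-round stochasticity is what the
#' stability estimate measures) on a fresh random subsample of
#' \code{subsampleFraction} of the cells. The consensus value of a cell pair
#' is its co-clustering count divided by its co-sampling count; pairs never
#' drawn together are excluded. PAC is the fraction of off-diagonal consensus
#' values falling strictly inside the ambiguity band, stability is
#' \eqn{1 - PAC}, and the selected k maximizes stability with ties broken
#' toward the smallest k.
#'
#' The per-iteration random stream derives from \code{param@seed} plus the
#' iteration index, so the same subsamples are drawn for every k.
#'
#' @param emb A \linkS4class{ReducedEmbedding} or a cells x components
#'   numeric matrix.
#' @param param A \linkS4class{ConsensusParam}.
#' @param keepMatrices Keep the per-k consensus matrices (cells x cells, NA
#'   where never co-sampled) in the result.
#' @param verbose Emit progress messages.
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusSelectK <- function(emb, param = ConsensusParam(),
                             keepMatrices = FALSE, verbose = TRUE) {
  stopifnot(is(param, "ConsensusParam"))
  X <- if (is(emb, "ReducedEmbedding")) embCoords(emb) else as.matrix(emb)
  n <- nrow(X)
  if (max(param@kRange) > n - 1L) {
    stop("config error: kRange must lie within [2, n cells - 1]")
  }
  if (n < max(param@kRange) * 5L) {
    stop("need at least 5 cells per candidate cluster (n >= 5 * max k)")
  }
  m <- floor(param@subsampleFraction * n)
  ut <- upper.tri(matrix(0, n, n))

  # the subsample stream depends only on the iteration index, so every k
  # sees the same draws and the co-sampling counts are shared
  subsamples <- lapply(seq_len(param@nIterations), function(it) {
    withr::with_seed(.subSeed(param@seed + it, "consensus_subsample"),
                     sample(n, m))
  })
  cs <- matrix(0, n, n)
  for (idx in subsamples) cs[idx, idx] <- cs[idx, idx] + 1

  pac <- stats::setNames(rep(NA_real_, length(param@kRange)),
                         as.character(param@kRange))
  consensusList <- list()
  for (k in param@kRange) {
    cc <- matrix(0, n, n)
    for (it in seq_len(param@nIterations)) {
      idx <- subsamples[[it]]
      lab <- withr::with_seed(
        .subSeed(param@seed + it, paste0("consensus_kmeans_k", k)),
        .kmeansSafe(X[idx, , drop = FALSE], k))
      Z <- matrix(0, m, k)
      Z[cbind(seq_len(m), lab)] <- 1
      cc[idx, idx] <- cc[idx, idx] + tcrossprod(Z)
    }
    sampled <- ut & cs > 0
    vals <- cc[sampled] / cs[sampled]
    pac[as.character(k)] <-
      mean(vals > param@band[1] & vals < param@band[2])
    if (keepMatrices) {
      cons <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
      cons[cs > 0] <- cc[cs > 0] / cs[cs > 0]
      consensusList[[as.character(k)]] <- cons
    }
    .msg(sprintf("consensusSelectK: k = %d, PAC = %.4f", k,
                 pac[as.character(k)]), verbose = verbose)
  }
  sel <- param@kRange[which.max(1 - pac)]  # first max -> smallest k on ties
  new("ConsensusResult", pac = pac, selectedK = as.integer(sel),
      param = param, consensus = consensusList)
}

#' PAC of a consensus-value vector
#'
#' The proportion of consensus values lying strictly inside the open
#' ambiguity band. Exposed for direct use on consensus summaries.
#'
#' @param consensusValues Numeric vector of consensus values in \[0, 1\].
#' @param band Open interval (low, high), default c(0.1, 0.9).
#' @return The PAC value.
#' @examples
#' pacStatistic(c(0, 0.05, 0.5, 0.95, 1))  # 0.2
#' @export
pacStatistic <- function(consensusValues, band = c(0.1, 0.9)) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  mean(consensusValues > band[1] & consensusValues < band[2])
}
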