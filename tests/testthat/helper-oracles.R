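# Independent oracles used across tests. These deliberately use naive,
# position-by-position formulations rather than the package's vectorized
# paths.

# Direct evaluation of the ssGSEA running sum for one cell and one set:
# walk the decreasing-expression gene order and accumulate the weighted
# in-set ECDF minus the out-of-set ECDF at every position.
ssgseaOracle <- function(v, set, alpha) {
  genes <- names(v)
  N <- length(v)
  r <- rank(v)                       # bottom gene 1 ... top gene N
  ord <- order(-v, genes, method = "radix")
  inSet <- genes %in% set
  den <- sum(r[inSet]^alpha)
  nOut <- N - sum(inSet)
  num <- 0
  out <- 0
  es <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (inSet[g]) num <- num + r[g]^alpha else out <- out + 1
    es <- es + num / den - out / nOut
  }
  es
}

# All scores for a matrix and collection, via the oracle, with the same
# global range normalization.
ssgseaOracleMatrix <- function(X, sets, alpha, normalize = FALSE) {
  ES <- sapply(seq_len(ncol(X)), function(c) {
    v <- X[, c]
    names(v) <- rownames(X)
    vapply(sets, function(s) ssgseaOracle(v, s, alpha), numeric(1))
  })
  if (is.null(dim(ES))) ES <- matrix(ES, nrow = length(sets))
  dimnames(ES) <- list(names(sets), colnames(X))
  if (normalize) ES <- ES / (max(ES) - min(ES))
  ES
}

# Brute-force all-pairs AUC: average over (positive, negative) pairs of
# 1 / 0.5 / 0 for win / tie / loss.
aucOracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p-value by complete enumeration of group
# assignments (small n only).
rankSumExactP <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  wObs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all), n1)
  ws <- apply(combos, 2L, function(i) sum(r[i]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# Small fast simulated cohort shared by several tests.
tinyCohort <- function(seed = 7, cellsPerCycle = 60, nGenes = 400,
                       cycles = c(3, 2), logFC = 1.2) {
  simulateCohort(SimParam(
    cellsPerCycle = cellsPerCycle, nGenes = nGenes,
    cyclesPerPatient = cycles,
    mixingSchedule = list(
      matrix(0.5, cycles[1], 2),
      matrix(0.5, cycles[2], 2)),
    programLogFC = logFC, trendSlopes = c(UP = 0.02), trendSize = 10,
    seed = seed), verbose = FALSE)
}

sceCounts <- function(sce) {
  as.matrix(SummarizedExperiment::assay(sce, "counts"))
}

cdata <- function(sce) as.data.frame(SummarizedExperiment::colData(sce))
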