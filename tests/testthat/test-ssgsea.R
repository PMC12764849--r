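# The ssGSEA running-sum statistic.

mkExpr <- function(values, genes = NULL, cells = NULL) {
  X <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(X)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(X)))
  dimnames(X) <- list(genes, cells)
  X
}

rawParam <- function(alpha = 0.25) {
  SsgseaParam(alpha = alpha, normalize = FALSE, minSize = 1)
}

test_that("three-gene closed forms: top-gene set 1.5, bottom-gene set -1.5", {
  X <- mkExpr(c(3, 2, 1), genes = c("A", "B", "C"))
  gsc <- GeneSetCollection(list(TOP = "A", BOTTOM = "C"))
  es <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, rawParam(alpha = 0), verbose = FALSE))
  expect_equal(unname(es["TOP", 1]), 1.5)
  expect_equal(unname(es["BOTTOM", 1]), -1.5)
})

test_that("alpha=0 singleton top-ranked set equals N/2 for N up to 6", {
  for (N in 2:6) {
    X <- mkExpr(N:1)
    gsc <- GeneSetCollection(list(S = "g1"))
    es <- SummarizedExperiment::assay(
      ssgseaScores(X, gsc, rawParam(alpha = 0), verbose = FALSE))
    expect_equal(unname(es[1, 1]), N / 2)
  }
})

test_that("scores match the independent running-sum oracle to 1e-12", {
  set.seed(42)
  N <- 60
  X <- mkExpr(matrix(rnorm(N * 8), N))
  X[sample(length(X), 150)] <- 0  # sparse-style zero ties
  sets <- lapply(1:6, function(i) rownames(X)[sample(N, sample(3:12, 1))])
  names(sets) <- paste0("S", 1:6)
  gsc <- GeneSetCollection(sets)
  es <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, rawParam(alpha = 0.25), verbose = FALSE))
  ora <- ssgseaOracleMatrix(X, geneSets(gsc), alpha = 0.25)
  expect_lt(max(abs(es - ora)), 1e-12)
})

test_that("ties including all-zero cells are deterministic and order-invariant", {
  set.seed(3)
  X <- mkExpr(cbind(rep(0, 10), c(5, 5, rnorm(8))))
  gsc <- GeneSetCollection(list(S1 = rownames(X)[c(1, 4, 7)],
                                S2 = rownames(X)[c(2, 3)]))
  es <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, rawParam(), verbose = FALSE))
  ora <- ssgseaOracleMatrix(X, geneSets(gsc), alpha = 0.25)
  expect_equal(es, ora, tolerance = 1e-12)

  # permuting the input gene rows leaves scores unchanged
  perm <- sample(nrow(X))
  es2 <- SummarizedExperiment::assay(
    ssgseaScores(X[perm, ], gsc, rawParam(), verbose = FALSE))
  expect_equal(es, es2, tolerance = 1e-12)
})

test_that("scores are invariant under strictly monotone per-cell transforms", {
  set.seed(9)
  X <- mkExpr(matrix(rexp(50 * 4), 50))
  gsc <- GeneSetCollection(list(A = rownames(X)[1:8], B = rownames(X)[20:30]))
  es1 <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, rawParam(), verbose = FALSE))
  es2 <- SummarizedExperiment::assay(
    ssgseaScores(log1p(X), gsc, rawParam(), verbose = FALSE))
  es3 <- SummarizedExperiment::assay(
    ssgseaScores(X^3, gsc, rawParam(), verbose = FALSE))
  expect_equal(es1, es2, tolerance = 1e-12)
  expect_equal(es1, es3, tolerance = 1e-12)
})

test_that("global normalization maps the range to width 1, preserving order", {
  set.seed(5)
  X <- mkExpr(matrix(rnorm(40 * 6), 40))
  gsc <- GeneSetCollection(list(A = rownames(X)[1:5], B = rownames(X)[6:15],
                                C = rownames(X)[16:20]))
  raw <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, rawParam(), verbose = FALSE))
  nrm <- SummarizedExperiment::assay(
    ssgseaScores(X, gsc, SsgseaParam(normalize = TRUE, minSize = 1),
                 verbose = FALSE))
  expect_equal(max(nrm) - min(nrm), 1)
  expect_equal(order(raw), order(nrm))
  expect_equal(nrm, raw / (max(raw) - min(raw)), tolerance = 1e-12)
})

test_that("degenerate sets are dropped with warnings; none left is an error", {
  X <- mkExpr(matrix(rnorm(20), 10, 2))
  gsc <- GeneSetCollection(list(MISSING = c("zz1", "zz2"),
                                ALL = rownames(X),
                                OK = rownames(X)[1:3]))
  expect_warning(expect_warning(
    s <- ssgseaScores(X, gsc, rawParam(), verbose = FALSE),
    "no genes"), "all genes")
  expect_identical(rownames(SummarizedExperiment::assay(s)), "OK")

  gsc2 <- GeneSetCollection(list(MISSING = c("zz1", "zz2")))
  expect_error(suppressWarnings(
    ssgseaScores(X, gsc2, rawParam(), verbose = FALSE)), "no gene sets")

  # size filter
  gsc3 <- GeneSetCollection(list(TINY = rownames(X)[1],
                                 OK = rownames(X)[1:4]))
  expect_warning(
    s3 <- ssgseaScores(X, gsc3, SsgseaParam(minSize = 2, normalize = FALSE),
                       verbose = FALSE), "size bounds")
  expect_identical(rownames(SummarizedExperiment::assay(s3)), "OK")
})
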