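# The AUC-gated rank-correlation ploidy classifier.

markerSce <- function(n = 120, nGenes = 200, sep = 3, seed = 1,
                      maskFrac = 0) {
  withr::with_seed(seed, {
    lab <- rep(c("diploid", "aneuploid"), each = n / 2)
    mu <- matrix(2, nGenes, n)
    mu[1:20, lab == "aneuploid"] <- 2 + sep     # aneuploid marker block
    mu[21:40, lab == "diploid"] <- 2 + sep      # diploid marker block
    counts <- matrix(rpois(length(mu), mu), nGenes, n)
    dimnames(counts) <- list(paste0("g", seq_len(nGenes)),
                             paste0("c", seq_len(n)))
    obs <- lab
    truth <- lab
    if (maskFrac > 0) {
      masked <- sample(n, round(maskFrac * n))
      obs[masked] <- "not.defined"
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(counts, "CsparseMatrix")),
      colData = S4Vectors::DataFrame(ploidy = obs, ploidy_true = truth,
                                     row.names = colnames(counts)))
    logNormalize(sce)
  })
}

test_that("disjoint marker blocks give a perfect, accepted classifier", {
  sce <- markerSce(sep = 6)
  m <- trainReferenceClassifier(sce, nVariableGenes = 100, seed = 2,
                                verbose = FALSE)
  expect_equal(cvAuc(m), 1.0)
  expect_true(isAccepted(m))
})

test_that("permuted labels give a chance-level, rejected classifier", {
  sce <- markerSce(n = 200, sep = 6, seed = 5)
  cd <- SummarizedExperiment::colData(sce)
  cd$ploidy <- withr::with_seed(99, sample(cd$ploidy))
  SummarizedExperiment::colData(sce) <- cd
  m <- trainReferenceClassifier(sce, nVariableGenes = 100, seed = 2,
                                verbose = FALSE)
  expect_lt(abs(cvAuc(m) - 0.5), 0.15)
  expect_false(isAccepted(m))
})

test_that("the rank AUC equals the brute-force pair oracle and pROC", {
  set.seed(31)
  for (rep in 1:5) {
    s <- sample(round(rnorm(40), 1))  # ties present
    pos <- runif(40) < 0.4
    if (!any(pos) || all(pos)) next
    a <- scArchetypes:::.rankAuc(s, pos)
    expect_equal(a, aucOracle(s, pos), tolerance = 1e-12)
    expect_equal(a, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(pos, s, quiet = TRUE, direction = "<",
                          levels = c(FALSE, TRUE))))), tolerance = 1e-12)
  }
})

test_that("rescue assigns masked cells accurately and flags provenance", {
  sce <- markerSce(n = 200, sep = 6, seed = 7, maskFrac = 0.1)
  m <- trainReferenceClassifier(sce, nVariableGenes = 100, seed = 3,
                                verbose = FALSE)
  expect_true(isAccepted(m))
  out <- reclassifyUndefined(m, sce, verbose = FALSE)
  cd <- cdata(out)
  rescued <- cd$ploidy_source == "rescued"
  expect_equal(sum(rescued), sum(cdata(sce)$ploidy == "not.defined"))
  acc <- mean(cd$ploidy[rescued] == cd$ploidy_true[rescued])
  expect_gte(acc, 0.9)
  # confidently labeled cells are never altered
  keep <- !rescued
  expect_identical(cd$ploidy[keep], cdata(sce)$ploidy[keep])
})

test_that("a rejected model leaves the metadata untouched", {
  sce <- markerSce(n = 200, sep = 6, seed = 5, maskFrac = 0.1)
  cd <- SummarizedExperiment::colData(sce)
  conf <- cd$ploidy != "not.defined"
  cd$ploidy[conf] <- withr::with_seed(41, sample(cd$ploidy[conf]))
  SummarizedExperiment::colData(sce) <- cd
  m <- trainReferenceClassifier(sce, nVariableGenes = 100, seed = 2,
                                verbose = FALSE)
  expect_false(isAccepted(m))
  out <- reclassifyUndefined(m, sce, verbose = FALSE)
  expect_identical(cdata(out)$ploidy, cdata(sce)$ploidy)
  expect_true(all(cdata(out)$ploidy_source == "original"))
})

test_that("folds and panel are seed-deterministic; label shortages warn", {
  sce <- markerSce(n = 120, sep = 4, seed = 11)
  m1 <- trainReferenceClassifier(sce, nVariableGenes = 80, seed = 9,
                                 verbose = FALSE)
  m2 <- trainReferenceClassifier(sce, nVariableGenes = 80, seed = 9,
                                 verbose = FALSE)
  expect_identical(cvAuc(m1), cvAuc(m2))
  expect_identical(variableGenes(m1), variableGenes(m2))

  few <- sce[, c(which(cdata(sce)$ploidy == "diploid")[1:3],
                 which(cdata(sce)$ploidy == "aneuploid"))]
  expect_warning(trainReferenceClassifier(few, nVariableGenes = 50,
                                          cvFolds = 5, seed = 1,
                                          verbose = FALSE), "folds")
})

test_that("cvAuc never decreases as class separation grows", {
  seps <- c(0, 1.5, 6)
  aucs <- vapply(seps, function(s) {
    mean(vapply(1:3, function(seed) {
      cvAuc(trainReferenceClassifier(markerSce(n = 80, sep = s, seed = seed),
                                     nVariableGenes = 80, seed = 1,
                                     verbose = FALSE))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.02))
})
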