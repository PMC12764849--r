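# SVD reduction, batch-component removal, consensus K selection,
# SNN-Louvain clustering, DPE profiles, proportions and CNA subclones.

test_that("rank-1 data keeps one component; full retention reconstructs", {
  set.seed(4)
  t_ <- rnorm(30)
  X <- outer(t_, c(1, -2, 0.5)) + 5
  emb <- reduceSVD(X, target = 0.9)
  expect_equal(ncol(embCoords(emb)), 1)

  Y <- matrix(rnorm(40 * 4), 40)
  embAll <- reduceSVD(Y, target = 1)
  rec <- embCoords(embAll) %*% t(componentLoadings(embAll))
  expect_equal(rec, sweep(Y, 2, colMeans(Y)), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(reduceSVD(matrix(1, 5, 3)), "rank-deficient")
})

test_that("isotropic 3-D data needs all components per the eigenvalue oracle", {
  set.seed(10)
  X <- matrix(rnorm(300 * 3), 300)
  emb <- reduceSVD(X, target = 0.9)
  ev <- sort(eigen(cov(X), symmetric = TRUE)$values, decreasing = TRUE)
  oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(ncol(embCoords(emb)), oracle)
  expect_equal(oracle, 3L)
})

mkEmb <- function(coords) {
  colnames(coords) <- paste0("SV", seq_len(ncol(coords)))
  rownames(coords) <- paste0("cell_", seq_len(nrow(coords)))
  methods::new("ReducedEmbedding", coords = coords,
               varExplained = rep(1 / ncol(coords), ncol(coords)),
               target = 0.9, centering = numeric(0),
               loadings = diag(ncol(coords)),
               removedComponent = NA_integer_,
               removedLoadings = numeric(0))
}

test_that("the component separating the batches is the one removed", {
  set.seed(6)
  n <- 60
  batch <- rep(c("A", "B"), each = n / 2)
  coords <- cbind(rnorm(n, sd = 3), rnorm(n) + ifelse(batch == "A", -2, 2),
                  rnorm(n))
  emb <- mkEmb(coords)
  out <- removeBatchComponent(emb, batch)
  expect_equal(removedComponent(out), 2L)
  expect_equal(ncol(embCoords(out)), 2)

  # identical group means on every component: tie -> lowest index, warned
  coordsT <- cbind(rep(c(-1, 1), n / 2), rep(c(-1, 1), n / 2))
  expect_warning(expect_warning(
    outT <- removeBatchComponent(mkEmb(coordsT),
                                 rep(c("A", "B"), each = n / 2)),
    "below"), "tie")
  expect_equal(removedComponent(outT), 1L)

  expect_warning(same <- removeBatchComponent(emb, rep("A", n)), "single")
  expect_identical(embCoords(same), embCoords(emb))
})

test_that("a planted patient shift is removed along its true direction", {
  b <- simulateCohort(SimParam(
    nPatients = 2, cyclesPerPatient = c(2, 2), cellsPerCycle = 100,
    nGenes = 400, batchShift = 0.6, trendSlopes = numeric(0),
    mixingSchedule = list(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
    seed = 19), verbose = FALSE)
  sce <- logNormalize(b$sce)
  sc <- ssgseaScores(sce, b$geneSets, verbose = FALSE)
  emb <- reduceSVD(sc)
  pat <- cdata(sce)$patient
  out <- removeBatchComponent(emb, pat)

  S <- t(SummarizedExperiment::assay(sc))  # cells x sets
  delta <- colMeans(S[pat == "P2", ]) - colMeans(S[pat == "P1", ])
  r <- cor(out@removedLoadings, delta)
  expect_gt(abs(r), 0.9)

  centDist <- function(coords) {
    sqrt(sum((colMeans(coords[pat == "P2", , drop = FALSE]) -
                colMeans(coords[pat == "P1", , drop = FALSE]))^2))
  }
  expect_lt(centDist(embCoords(out)), centDist(embCoords(emb)))
})

test_that("PAC follows its definition and binary consensus is fully stable", {
  expect_equal(pacStatistic(c(0, 0.05, 0.5, 0.95, 1)), 1 / 5)
  expect_equal(pacStatistic(c(0, 1, 1, 0, 0)), 0)
})

test_that("two well-separated point masses give PAC 0 and k = 2", {
  coords <- rbind(matrix(0, 15, 2), matrix(5, 15, 2))
  cons <- consensusSelectK(coords, ConsensusParam(kRange = 2:3,
                                                  nIterations = 30, seed = 2),
                           verbose = FALSE)
  expect_equal(unname(pacValues(cons)["2"]), 0)
  expect_equal(unname(stabilityValues(cons)["2"]), 1)
  expect_equal(selectedK(cons), 2L)
})

test_that("consensus selection recovers three planted Gaussians", {
  set.seed(14)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  coords <- centers[rep(1:3, each = 100), ] + matrix(rnorm(600), 300)
  cons <- consensusSelectK(coords, ConsensusParam(kRange = 2:5,
                                                  nIterations = 50, seed = 5),
                           verbose = FALSE)
  expect_equal(selectedK(cons), 3L)
  expect_true(all(pacValues(cons)["3"] <= pacValues(cons)[c("2", "4", "5")]))
  expect_error(
    consensusSelectK(coords[1:8, ], ConsensusParam(kRange = 2:9), verbose = FALSE),
    "config error|cells")
})

test_that("SNN-Louvain recovers separable clusters at the requested k", {
  set.seed(8)
  coords <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 8), 100))
  truth <- rep(1:2, each = 100)
  asn <- clusterToK(coords, 2, seed = 4, verbose = FALSE)
  expect_equal(asn@achievedK, 2L)
  expect_equal(mclust::adjustedRandIndex(archetypeLabels(asn), truth), 1)

  one <- clusterToK(coords, 1, verbose = FALSE)
  expect_equal(nlevels(archetypeLabels(one)), 1L)
  expect_error(clusterToK(coords, 300, verbose = FALSE), "exceeds")
})

test_that("DPE ranks a planted shift first and drops flat pathways", {
  set.seed(12)
  n <- 10
  lab <- factor(rep(c("A1", "A2"), each = n / 2))
  X <- rbind(shifted = rnorm(n, sd = 0.2) + ifelse(lab == "A1", 1, 0),
             flat = rep(0.3, n),
             noise = rnorm(n, sd = 0.2))
  colnames(X) <- paste0("c", 1:n)
  names(lab) <- colnames(X)
  prof <- dpeWilcoxon(X, lab, topN = 5)
  a1 <- prof[prof$archetype == "A1", ]
  expect_identical(a1$pathway[1], "shifted")
  expect_false("flat" %in% prof$pathway)

  # exact rank-sum oracle at n <= 10
  pOracle <- rankSumExactP(X["shifted", lab == "A1"],
                           X["shifted", lab == "A2"])
  expect_equal(a1$p[a1$pathway == "shifted"], pOracle, tolerance = 1e-12)

  # topN above the pathway count returns all positive-effect pathways
  profAll <- dpeWilcoxon(X, lab, topN = 100)
  expect_true(all(profAll$effect > 0))

  lab3 <- lab
  levels(lab3) <- c("A1", "A2")
  lab3[1:2] <- "A1"
  tiny <- factor(c(rep("A1", 8), rep("A2", 2)))
  names(tiny) <- colnames(X)
  expect_warning(dpeWilcoxon(X, tiny), "< 3 cells")
  expect_error(dpeWilcoxon(X, factor(rep("A1", n))), "2 archetypes")
})

test_that("proportions sum to one per group and track a 30/70 schedule", {
  meta <- data.frame(patient = rep("P1", 500), cycle = 1,
                     row.names = paste0("c", 1:500))
  set.seed(15)
  lab <- factor(ifelse(runif(500) < 0.3, "A1", "A2"))
  names(lab) <- rownames(meta)
  pr <- archetypeProportions(lab, meta)
  expect_equal(sum(pr$proportion), 1)
  sd3 <- 3 * sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(pr$proportion[pr$archetype == "A1"] - 0.3), sd3)

  # degenerate single-archetype labels give 100% everywhere
  lab1 <- factor(rep("A1", 500))
  names(lab1) <- rownames(meta)
  pr1 <- archetypeProportions(lab1, meta)
  expect_equal(pr1$proportion, 1)

  # a (patient, cycle) with no clustered cells is omitted with a warning
  meta2 <- rbind(meta, data.frame(patient = "P1", cycle = 2,
                                  row.names = "extra"))
  expect_warning(pr2 <- archetypeProportions(lab, meta2), "no clustered")
  expect_false(2 %in% pr2$cycle)
})

test_that("k-means subclones separate planted dosage profiles", {
  set.seed(16)
  prof <- rbind(matrix(rnorm(50 * 20, mean = 1.5, sd = 0.1), 50),
                matrix(rnorm(50 * 20, mean = 0.7, sd = 0.1), 50))
  res <- kmeansCnaSubclones(prof, k = 2, seed = 3)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1)

  flat <- matrix(1, 20, 5)
  expect_warning(r1 <- kmeansCnaSubclones(flat, k = 2, seed = 9), "distinct")
  expect_warning(r2 <- kmeansCnaSubclones(flat, k = 2, seed = 9), "distinct")
  expect_identical(r1$labels, r2$labels)
  expect_error(kmeansCnaSubclones(prof[1:2, ], k = 2), "smaller")
})

test_that("the archetype pipeline is deterministic under a fixed seed", {
  b <- tinyCohort(seed = 23, cellsPerCycle = 40, cycles = c(2, 2))
  sce <- logNormalize(b$sce)
  sc <- ssgseaScores(sce, b$geneSets, verbose = FALSE)
  emb <- removeBatchComponent(reduceSVD(sc), cdata(sce)$patient)
  run <- function() {
    cons <- consensusSelectK(emb, ConsensusParam(kRange = 2:3,
                                                 nIterations = 20, seed = 6),
                             verbose = FALSE)
    asn <- clusterToK(emb, selectedK(cons), seed = 6, verbose = FALSE)
    list(k = selectedK(cons), lab = archetypeLabels(asn),
         pr = archetypeProportions(archetypeLabels(asn), cdata(sce)))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
})
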