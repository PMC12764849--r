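# Temporal OLS modeling and BH adjustment.

tmpMeta <- function(cycles, patient = "P1") {
  data.frame(patient = patient, cycle = cycles)
}

test_that("an exact linear response is recovered with zero residual", {
  cyc <- rep(1:3, each = 4)
  X <- rbind(lin = 0.01 * cyc, flat = rep(2, 12))
  res <- fitTemporalLinear(X, tmpMeta(cyc), verbose = FALSE)
  lin <- res[res$feature == "lin", ]
  expect_equal(lin$estimate, 0.01)
  expect_equal(lin$p, 0)
  flat <- res[res$feature == "flat", ]
  expect_equal(flat$estimate, 0)
  expect_true(is.na(flat$p) && is.na(flat$fdr))
})

test_that("slope, SE and p agree with per-feature lm to 1e-10", {
  set.seed(21)
  cyc <- rep(1:4, each = 10)
  X <- matrix(rnorm(5 * 40, sd = 2), 5,
              dimnames = list(paste0("f", 1:5), NULL))
  X <- X + outer(c(0, 0.1, -0.2, 0.05, 0), cyc)
  res <- fitTemporalLinear(X, tmpMeta(cyc), verbose = FALSE)
  for (i in 1:5) {
    co <- summary(lm(X[i, ] ~ cyc))$coefficients["cyc", ]
    row <- res[res$feature == paste0("f", i), ]
    expect_equal(row$estimate, unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(row$se, unname(co["Std. Error"]), tolerance = 1e-10)
    expect_equal(row$p, unname(co["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("slopes shift-invariantly ignore constants and scale linearly", {
  set.seed(2)
  cyc <- rep(1:3, each = 6)
  X <- matrix(rnorm(2 * 18), 2, dimnames = list(c("a", "b"), NULL))
  r1 <- fitTemporalLinear(X, tmpMeta(cyc), verbose = FALSE)
  r2 <- fitTemporalLinear(X + 100, tmpMeta(cyc), verbose = FALSE)
  r3 <- fitTemporalLinear(X * 3, tmpMeta(cyc), verbose = FALSE)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r3$estimate, 3 * r1$estimate, tolerance = 1e-12)
})

test_that("patients are fitted separately; single-cycle groups are skipped", {
  cyc <- c(1, 1, 2, 2, 1, 1)
  meta <- data.frame(patient = c(rep("P1", 4), rep("P2", 2)), cycle = cyc)
  X <- matrix(rnorm(12), 2, dimnames = list(c("a", "b"), NULL))
  expect_warning(res <- fitTemporalLinear(X, meta, verbose = FALSE),
                 "single cycle")
  expect_identical(unique(res$patient), "P1")
  pooled <- fitTemporalLinear(X, meta, groupByPatient = FALSE,
                              verbose = FALSE)
  expect_identical(unique(pooled$patient), "all")
})

test_that("BH matches hand-computed step-up values and passes NAs through", {
  expect_equal(bhAdjust(rep(0.03, 10)), rep(0.03, 10))
  expect_equal(bhAdjust(c(0.005, 0.04, 0.06)), c(0.015, 0.06, 0.06))
  got <- bhAdjust(c(0.01, NA, 0.02))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], p.adjust(c(0.01, 0.02), "BH"))
  expect_error(bhAdjust(c(0.5, 1.2)), "validation")
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("BH is component-wise monotone: lowering a p never raises any fdr", {
  set.seed(33)
  for (rep in 1:20) {
    p <- runif(8)
    i <- sample(8, 1)
    p2 <- p
    p2[i] <- p[i] * runif(1)
    f1 <- bhAdjust(p)
    f2 <- bhAdjust(p2)
    expect_true(all(f2 <= f1 + 1e-12))
  }
})

test_that("volcano classes use strict cutoffs and sort by FDR", {
  res <- data.frame(patient = "P1",
                    feature = c("a", "b", "c", "d"),
                    estimate = c(0.01, -0.02, 0.03, 0.001),
                    fdr = c(0.04, 0.01, 0.05, NA))
  v <- volcanoTable(res, estimateCutoff = 0, fdrCutoff = 0.05)
  expect_identical(as.character(v$class[v$feature == "a"]), "up")
  expect_identical(as.character(v$class[v$feature == "b"]), "down")
  # fdr exactly at the cutoff is not significant
  expect_identical(as.character(v$class[v$feature == "c"]), "ns")
  expect_identical(as.character(v$class[v$feature == "d"]), "ns")
  expect_identical(v$feature, c("b", "a", "c", "d"))
})
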