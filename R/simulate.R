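# Synthetic longitudinal cohort generator: negative-binomial counts with
# planted archetype programs, per-cycle trend drift, patient batch shifts
# and copy-number dosage, plus a full ground-truth record.

.defaultMixing <- function(nPatients, cyclesPerPatient, nArchetypes) {
  if (nPatients == 2L && identical(cyclesPerPatient, c(6L, 2L)) &&
      nArchetypes == 2L) {
    # archetype 2 (metabolism-like): near-even split at baseline, peak at
    # cycle 4, collapse by cycle 6; patient 2 stable with archetype 1
    # (signaling/immune-like) dominant.
    a2p1 <- c(0.50, 0.56, 0.63, 0.695, 0.52, 0.341)
    a1p2 <- c(0.693, 0.643)
    return(list(cbind(1 - a2p1, a2p1), cbind(a1p2, 1 - a1p2)))
  }
  lapply(seq_len(nPatients), function(p) {
    matrix(1 / nArchetypes, cyclesPerPatient[p], nArchetypes)
  })
}

#' @rdname SimParam-class
#' @param nPatients,cyclesPerPatient,cellsPerCycle,nGenes,nArchetypes,programSize,programLogFC,mixingSchedule,trendSlopes,trendSize,batchShift,nbDispersion,libsizeSdlog,meanCountsPerCell,aneuploidFraction,cnaSegments,undefinedFraction,nNullSets,nullSetSize,seed
#'   See the class slots; \code{mixingSchedule = NULL} builds the default
#'   two-patient schedule described above, and \code{cnaSegments = NULL}
#'   places three dosage blocks (1.5x, 0.5x, 1.5x), each covering ~7.5% of
#'   the genes, across the gene-index genome.
#' @return A \linkS4class{SimParam}.
#' @export
SimParam <- function(nPatients = 2, cyclesPerPatient = c(6, 2),
                     cellsPerCycle = 500, nGenes = 2000, nArchetypes = 2,
                     programSize = 60, programLogFC = 1.0,
                     mixingSchedule = NULL,
                     trendSlopes = c(TREND_UP = 0.02, TREND_DOWN = -0.01,
                                     TREND_NULL = 0),
                     trendSize = 20, batchShift = 0.5, nbDispersion = 10,
                     libsizeSdlog = 0.3, meanCountsPerCell = 2500,
                     aneuploidFraction = 0.6, cnaSegments = NULL,
                     undefinedFraction = 0.1, nNullSets = 10,
                     nullSetSize = 30, seed = 1) {
  nPatients <- as.integer(nPatients)
  cyclesPerPatient <- as.integer(cyclesPerPatient)
  nArchetypes <- as.integer(nArchetypes)
  if (is.null(mixingSchedule)) {
    mixingSchedule <- .defaultMixing(nPatients, cyclesPerPatient, nArchetypes)
  }
  if (is.null(cnaSegments)) {
    # three dosage blocks, each ~7.5% of the transcriptome, spread across
    # the gene-index "genome"
    g <- as.integer(nGenes)
    len <- max(1L, as.integer(0.075 * g))
    st <- pmin(as.integer(c(0, 0.25, 0.5) * g) + 1L, g)
    cnaSegments <- data.frame(start = st, end = pmin(st + len - 1L, g),
                              dosage = c(1.5, 0.5, 1.5))
  }
  trendSlopes <- unlist(trendSlopes)  # accept YAML-style named lists
  if (is.null(trendSlopes)) trendSlopes <- numeric(0)
  if (length(trendSlopes) && is.null(names(trendSlopes))) {
    names(trendSlopes) <- paste0("TREND_", seq_along(trendSlopes))
  }
  new("SimParam", nPatients = nPatients,
      cyclesPerPatient = cyclesPerPatient,
      cellsPerCycle = as.integer(cellsPerCycle), nGenes = as.integer(nGenes),
      nArchetypes = nArchetypes, programSize = as.integer(programSize),
      programLogFC = programLogFC, mixingSchedule = mixingSchedule,
      trendSlopes = trendSlopes, trendSize = as.integer(trendSize),
      batchShift = batchShift, nbDispersion = nbDispersion,
      libsizeSdlog = libsizeSdlog, meanCountsPerCell = meanCountsPerCell,
      aneuploidFraction = aneuploidFraction,
      cnaSegments = cnaSegments,
      undefinedFraction = undefinedFraction,
      nNullSets = as.integer(nNullSets),
      nullSetSize = as.integer(nullSetSize), seed = as.integer(seed))
}

setMethod("show", "SimParam", function(object) {
  cat(sprintf(
    "SimParam: %d patient(s), cycles %s, %d cells/cycle, %d genes, %d archetypes\n",
    object@nPatients, paste(object@cyclesPerPatient, collapse = "/"),
    object@cellsPerCycle, object@nGenes, object@nArchetypes))
  cat(sprintf("  program logFC %g on %d genes; batch shift SD %g; NB size %g\n",
              object@programLogFC, object@programSize, object@batchShift,
              object@nbDispersion))
})

#' Simulate a longitudinal single-cell cohort
#'
#' Generates negative-binomial counts whose gene log-means are
#' \code{baseline + archetype program effect + cycle x trend slope (trend
#' genes only) + patient batch offset (+ log dosage on CNA segments for
#' aneuploid cells)}, with lognormal library-size factors. Each cell draws
#' its archetype from the per-(patient, cycle) mixing schedule; true ploidy
#' is aneuploid with probability \code{aneuploidFraction}, and
#' \code{undefinedFraction} of cells have their observed ploidy masked to
#' \code{"not.defined"}. The same seed yields bit-identical output.
#'
#' @param param A \linkS4class{SimParam}.
#' @param verbose Emit a summary message.
#' @return A list with elements \code{sce} (SingleCellExperiment, counts
#'   assay + metadata columns patient, cycle, biopsy_site, cell_type,
#'   ploidy, n_features, pct_mt), \code{geneSets} (a
#'   \linkS4class{GeneSetCollection} holding the archetype program sets,
#'   trend sets, and random null sets), and \code{truth} (per-cell archetype
#'   and true ploidy, realized per-cycle proportions, planted trend slopes,
#'   per-patient batch offset vectors, program gene lists, and the
#'   \linkS4class{SimParam} itself).
#' @examples
#' bundle <- simulateCohort(SimParam(cellsPerCycle = 20, nGenes = 200,
#'                                   cyclesPerPatient = c(2, 2),
#'                                   mixingSchedule = NULL, seed = 7))
#' table(bundle$truth$cells$archetype)
#' @export
simulateCohort <- function(param = SimParam(), verbose = TRUE) {
  stopifnot(is(param, "SimParam"))
  methods::validObject(param)
  G <- param@nGenes
  genes <- sprintf("gene_%05d", seq_len(G))

  withr::with_seed(.subSeed(param@seed, "cohort"), {
    # baseline gene means scaled to the target library size
    mu0 <- exp(stats::rnorm(G, 0, 1))
    mu0 <- mu0 / sum(mu0) * param@meanCountsPerCell
    base <- log(mu0)

    # disjoint archetype-program and trend-program gene panels
    pool <- sample(G)
    need <- param@nArchetypes * param@programSize +
      length(param@trendSlopes) * param@trendSize
    if (need > G) stop("not enough genes for the requested programs")
    programGenes <- list()
    ofs <- 0L
    for (a in seq_len(param@nArchetypes)) {
      programGenes[[paste0("ARCHETYPE", a, "_PROGRAM")]] <-
        sort(pool[ofs + seq_len(param@programSize)])
      ofs <- ofs + param@programSize
    }
    trendGenes <- list()
    for (tname in names(param@trendSlopes)) {
      trendGenes[[tname]] <- sort(pool[ofs + seq_len(param@trendSize)])
      ofs <- ofs + param@trendSize
    }
    nullSets <- lapply(seq_len(param@nNullSets), function(i) {
      sort(sample(G, param@nullSetSize))
    })
    names(nullSets) <- sprintf("NULL_SET_%02d", seq_len(param@nNullSets))

    batchOffsets <- matrix(0, G, param@nPatients,
                           dimnames = list(genes,
                                           paste0("P", seq_len(param@nPatients))))
    if (param@nPatients > 1L && param@batchShift > 0) {
      for (p in 2:param@nPatients) {
        batchOffsets[, p] <- stats::rnorm(G, 0, param@batchShift)
      }
    }

    # per-cell design
    design <- do.call(rbind, lapply(seq_len(param@nPatients), function(p) {
      do.call(rbind, lapply(seq_len(param@cyclesPerPatient[p]), function(cy) {
        data.frame(patient = paste0("P", p), cycle = cy,
                   stringsAsFactors = FALSE)[rep(1, param@cellsPerCycle), ]
      }))
    }))
    n <- nrow(design)
    design$cell_id <- sprintf("cell_%06d", seq_len(n))
    design$archetype <- NA_integer_
    for (p in seq_len(param@nPatients)) {
      for (cy in seq_len(param@cyclesPerPatient[p])) {
        sel <- design$patient == paste0("P", p) & design$cycle == cy
        design$archetype[sel] <- sample.int(
          param@nArchetypes, sum(sel), replace = TRUE,
          prob = param@mixingSchedule[[p]][cy, ])
      }
    }
    design$ploidy_true <- ifelse(
      stats::runif(n) < param@aneuploidFraction, "aneuploid", "diploid")
    design$masked <- stats::runif(n) < param@undefinedFraction
    design$biopsy_site <- sample(c("RU", "RL", "LU", "LL"), n, replace = TRUE)
    design$pct_mt <- stats::rbeta(n, 2, 6) * 4.8
    libFactor <- stats::rlnorm(n, -param@libsizeSdlog^2 / 2,
                               param@libsizeSdlog)

    # CNA dosage on gene log-means for aneuploid cells
    cnaLog <- rep(0, G)
    if (nrow(param@cnaSegments)) {
      for (i in seq_len(nrow(param@cnaSegments))) {
        seg <- param@cnaSegments[i, ]
        cnaLog[seg$start:seg$end] <- cnaLog[seg$start:seg$end] +
          log(seg$dosage)
      }
    }
    trendMat <- matrix(0, G, length(param@trendSlopes))
    for (j in seq_along(param@trendSlopes)) {
      trendMat[trendGenes[[j]], j] <- param@trendSlopes[j]
    }
    trendPerGene <- rowSums(trendMat)

    counts <- matrix(0L, G, n)
    grp <- interaction(design$patient, design$cycle, design$archetype,
                       design$ploidy_true, drop = TRUE)
    for (g in levels(grp)) {
      sel <- which(grp == g)
      d1 <- design[sel[1], ]
      lam <- base +
        batchOffsets[, match(d1$patient, colnames(batchOffsets))] +
        d1$cycle * trendPerGene
      a <- d1$archetype
      lam[programGenes[[a]]] <- lam[programGenes[[a]]] + param@programLogFC
      if (d1$ploidy_true == "aneuploid") lam <- lam + cnaLog
      mu <- exp(lam) %o% libFactor[sel]
      counts[, sel] <- stats::rnbinom(length(mu), mu = mu,
                                      size = param@nbDispersion)
    }
  })

  dimnames(counts) <- list(genes, design$cell_id)
  ploidy <- design$ploidy_true
  ploidy[design$masked] <- "not.defined"
  cd <- S4Vectors::DataFrame(
    cell_id = design$cell_id, patient = design$patient,
    cycle = design$cycle, biopsy_site = design$biopsy_site,
    cell_type = "epithelial", ploidy = ploidy,
    n_features = colSums(counts > 0), pct_mt = design$pct_mt,
    row.names = design$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd)

  sets <- c(lapply(programGenes, function(i) genes[i]),
            lapply(trendGenes, function(i) genes[i]),
            lapply(nullSets, function(i) genes[i]))
  gsc <- GeneSetCollection(sets, source = "synthetic")

  realized <- do.call(rbind, lapply(seq_len(param@nPatients), function(p) {
    do.call(rbind, lapply(seq_len(param@cyclesPerPatient[p]), function(cy) {
      sel <- design$patient == paste0("P", p) & design$cycle == cy
      tab <- tabulate(design$archetype[sel], param@nArchetypes)
      data.frame(patient = paste0("P", p), cycle = cy,
                 archetype = paste0("ARCH", seq_len(param@nArchetypes)),
                 planted = param@mixingSchedule[[p]][cy, ],
                 realized = tab / sum(tab), row.names = NULL)
    }))
  }))
  truth <- list(
    cells = data.frame(cell_id = design$cell_id,
                       archetype = paste0("ARCH", design$archetype),
                       ploidy_true = design$ploidy_true,
                       masked = design$masked, row.names = NULL),
    proportions = realized,
    slopes = data.frame(set = names(param@trendSlopes),
                        slope = unname(param@trendSlopes),
                        genes = vapply(trendGenes, function(i) {
                          paste(genes[i], collapse = ";")
                        }, character(1)), row.names = NULL),
    batchOffsets = batchOffsets,
    programGenes = lapply(programGenes, function(i) genes[i]),
    cnaLogDosage = cnaLog,
    param = param)
  .msg(sprintf("simulateCohort: %d cells x %d genes, %d archetypes, seed %d",
               n, G, param@nArchetypes, param@seed), verbose = verbose)
  list(sce = sce, geneSets = gsc, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard input formats (matrix-market counts, gene and cell
#' annotation TSVs, GMT gene sets) plus ground-truth TSV tables, so a
#' round-trip through [readCounts()] / [readGMT()] reproduces the in-memory
#' bundle.
#'
#' @param bundle Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Named character vector of the emitted paths, invisibly.
#' @export
writeCohort <- function(bundle, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("directory '", dir, "' is not empty; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sce <- bundle$sce
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    cells = file.path(dir, "cells.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    truth_cells = file.path(dir, "truth_cells.tsv"),
    truth_proportions = file.path(dir, "truth_proportions.tsv"),
    truth_slopes = file.path(dir, "truth_slopes.tsv"),
    truth_batch = file.path(dir, "truth_batch.tsv"))
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"),
                  paths[["matrix"]])
  utils::write.table(data.frame(gene = rownames(sce)), paths[["genes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sce)),
                     paths[["cells"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeGMT(bundle$geneSets, paths[["gmt"]])
  utils::write.table(bundle$truth$cells, paths[["truth_cells"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$proportions, paths[["truth_proportions"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$slopes, paths[["truth_slopes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(bundle$truth$batchOffsets),
               bundle$truth$batchOffsets, check.names = FALSE),
    paths[["truth_batch"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
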