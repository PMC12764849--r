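# Reading and writing the on-disk formats: matrix-market counts with
# row-aligned gene/cell annotation tables, and GMT gene-set files.

#' Read a sparse count matrix with annotations
#'
#' Reads a matrix-market (coordinate, 1-based) count file with genes as rows
#' and cells as columns, together with row-aligned annotation tables: a gene
#' table whose first column holds gene symbols, and a cell table with a
#' \code{cell_id} column plus any per-cell metadata (patient, cycle,
#' biopsy_site, cell_type, ploidy, n_features, pct_mt, ...). Duplicate gene
#' symbols are collapsed by summation with a warning.
#'
#' @param matrixPath Path to the \code{.mtx} file.
#' @param genesPath Path to the tab-separated gene table (with header).
#' @param cellsPath Path to the tab-separated cell table (with header,
#'   \code{cell_id} column required).
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   \code{"counts"}, gene symbols as rownames, cell ids as colnames and the
#'   cell table as \code{colData}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(5, 2),
#'                           dims = c(3, 3))
#' Matrix::writeMM(m, file.path(dir, "m.mtx"))
#' write.table(data.frame(gene = c("A", "B", "C")), file.path(dir, "g.tsv"),
#'             sep = "\t", row.names = FALSE, quote = FALSE)
#' write.table(data.frame(cell_id = c("c1", "c2", "c3")),
#'             file.path(dir, "c.tsv"), sep = "\t", row.names = FALSE,
#'             quote = FALSE)
#' sce <- readCounts(file.path(dir, "m.mtx"), file.path(dir, "g.tsv"),
#'                   file.path(dir, "c.tsv"))
#' @export
readCounts <- function(matrixPath, genesPath, cellsPath) {
  for (p in c(matrixPath, genesPath, cellsPath)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(matrixPath), error = function(e) {
    stop("matrix format error in '", matrixPath, "': ", conditionMessage(e))
  })
  genes <- utils::read.delim(genesPath, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cellsPath, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cells)) {
    stop("cell table must contain a 'cell_id' column")
  }
  if (nrow(genes) != nrow(m)) {
    stop("format error: gene table has ", nrow(genes),
         " rows but matrix declares ", nrow(m), " genes")
  }
  if (nrow(cells) != ncol(m)) {
    stop("format error: cell table has ", nrow(cells),
         " rows but matrix declares ", ncol(m), " cells")
  }
  v <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (any(v < 0)) stop("validation error: negative count entries")
  if (any(v != round(v))) stop("validation error: non-integer count entries")
  if (anyDuplicated(cells$cell_id)) stop("cell ids must be unique")

  sym <- as.character(genes[[1]])
  m <- methods::as(m, "CsparseMatrix")
  if (anyDuplicated(sym)) {
    dup <- unique(sym[duplicated(sym)])
    warning("collapsing ", length(dup), " duplicated gene symbol(s) by ",
            "summation: ", paste(utils::head(dup, 5), collapse = ", "))
    grp <- factor(sym, levels = unique(sym))
    agg <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_along(sym),
                                x = 1, dims = c(nlevels(grp), length(sym)))
    m <- agg %*% m
    sym <- levels(grp)
  }
  rownames(m) <- sym
  colnames(m) <- cells$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id)
  )
}

#' Read a GMT gene-set file
#'
#' Tab-separated GMT: set name, description, then genes. The description
#' column is dropped and duplicate genes within a set removed.
#'
#' @param path Path to the GMT file.
#' @param source Source tag stored on the collection (defaults to the file
#'   name without extension).
#' @return A \linkS4class{GeneSetCollection}.
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path, source = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("format error: GMT line ", bad[1], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("format error: duplicated set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  GeneSetCollection(sets, source = source)
}

#' Write a GMT gene-set file
#'
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGMT <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  src <- if (is.na(setSource(gsc))) "na" else setSource(gsc)
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, src, gsc[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter cells on QC thresholds
#'
#' Retains cells with \code{minFeatures < n_features < maxFeatures} and
#' \code{pct_mt < maxPctMt} (all strict inequalities). If the
#' \code{n_features} column is absent it is computed as the number of genes
#' with nonzero counts. A per-criterion removal report is attached to
#' \code{metadata(.)$qcReport} of the returned object.
#'
#' @param sce A [SingleCellExperiment::SingleCellExperiment] with a
#'   \code{"counts"} assay and \code{pct_mt} in its \code{colData}.
#' @param param A \linkS4class{QcParam}.
#' @param verbose Emit a summary message.
#' @return The filtered SingleCellExperiment. An empty result triggers a
#'   warning, not an error.
#' @export
qcFilter <- function(sce, param = QcParam(), verbose = TRUE) {
  stopifnot(is(param, "QcParam"))
  cd <- SummarizedExperiment::colData(sce)
  if (!"n_features" %in% names(cd)) {
    cd$n_features <- Matrix::colSums(
      SummarizedExperiment::assay(sce, "counts") > 0)
  }
  if (!"pct_mt" %in% names(cd)) {
    stop("colData must contain 'pct_mt'")
  }
  if (any(cd$pct_mt < 0 | cd$pct_mt > 100)) {
    stop("validation error: pct_mt outside [0, 100]")
  }
  lowFeat <- cd$n_features <= param@minFeatures
  highFeat <- cd$n_features >= param@maxFeatures
  highMt <- cd$pct_mt >= param@maxPctMt
  keep <- !(lowFeat | highFeat | highMt)
  report <- data.frame(
    criterion = c("n_features_low", "n_features_high", "pct_mt_high",
                  "retained"),
    threshold = c(param@minFeatures, param@maxFeatures, param@maxPctMt, NA),
    n_cells = c(sum(lowFeat), sum(highFeat), sum(highMt), sum(keep))
  )
  out <- sce[, keep]
  S4Vectors::metadata(out)$qcReport <- report
  S4Vectors::metadata(out)$qcParam <- param
  if (sum(keep) == 0L) {
    warning("QC filtering removed every cell; returning an empty object")
  }
  .msg(sprintf("qcFilter: retained %d / %d cells", sum(keep), ncol(sce)),
       verbose = verbose)
  out
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to \code{scaleTotal} and applies
#' \code{log(1 + x)}, storing the result as assay \code{"lognorm"}. This is
#' the pre-scoring transform; because the downstream enrichment statistic
#' depends only on within-cell gene ranks, any per-cell monotone
#' normalization yields identical scores. The choice is recorded in
#' \code{metadata(.)$normalization}.
#'
#' @param sce A SingleCellExperiment with a \code{"counts"} assay.
#' @param scaleTotal Per-cell target total (default 1e4).
#' @return The object with a \code{"lognorm"} assay added.
#' @export
logNormalize <- function(sce, scaleTotal = 1e4) {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(m)[tot == 0], 5), collapse = ", "))
  }
  ln <- log1p(m %*% Matrix::Diagonal(x = scaleTotal / tot))
  dimnames(ln) <- dimnames(m)
  SummarizedExperiment::assay(sce, "lognorm") <- ln
  S4Vectors::metadata(sce)$normalization <-
    list(method = "logCPM", scaleTotal = scaleTotal)
  sce
}
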