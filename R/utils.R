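# Internal helpers shared across stages.

#' @importFrom withr with_seed
NULL

# Derive a reproducible sub-seed for a named stage from one global seed.
# Kept below 2^31 - 1 (R integers are 32-bit).
.subSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + offs) %% 2147483544L) + 1L
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# Extract an assay matrix from an SCE or pass a plain matrix through.
.assayMatrix <- function(x, layer) {
  if (is(x, "SummarizedExperiment")) {
    if (!layer %in% SummarizedExperiment::assayNames(x)) {
      stop("assay '", layer, "' not found; available: ",
           paste(SummarizedExperiment::assayNames(x), collapse = ", "))
    }
    m <- SummarizedExperiment::assay(x, layer)
  } else {
    m <- x
  }
  as.matrix(m)
}

# Rank-based (Mann-Whitney) AUC of scores for a binary label, ties averaged.
.rankAuc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  npos <- sum(positive)
  nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}
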