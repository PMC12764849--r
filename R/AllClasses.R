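#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Gene set collection
#'
#' A named list of gene-symbol vectors with a source tag (e.g. \code{"hallmark"},
#' \code{"C2"}). Set names are unique and every set is non-empty after
#' de-duplication. Gene identity is by symbol, case-sensitive.
#'
#' @slot sets Named list of character vectors of gene symbols.
#' @slot source Single character tag recording where the sets came from.
#'
#' @seealso [readGMT()], [writeGMT()], [ssgseaScores()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", source = "character"),
  prototype(sets = list(), source = NA_character_)
)

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return("collection contains no gene sets")
  nm <- names(s)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) return("all sets must be named")
  if (anyDuplicated(nm)) return("set names must be unique")
  if (!all(vapply(s, is.character, logical(1)))) return("sets must be character vectors")
  if (any(vapply(s, length, integer(1)) == 0L)) return("sets must be non-empty")
  if (any(vapply(s, anyDuplicated, integer(1)) > 0L)) {
    return("sets must not contain duplicated genes")
  }
  TRUE
})

#' Quality-control parameters
#'
#' Cell-level QC thresholds applied with strict inequalities: a cell is kept
#' when \code{minFeatures < nFeatures < maxFeatures} and
#' \code{pctMt < maxPctMt}. The assumed doublet rate is carried as provenance
#' metadata only; no doublet removal is performed here.
#'
#' @slot minFeatures Lower bound (exclusive) on detected genes per cell.
#' @slot maxFeatures Upper bound (exclusive) on detected genes per cell.
#' @slot maxPctMt Upper bound (exclusive) on mitochondrial read percentage.
#' @slot doubletRate Assumed doublet rate, recorded but not acted on.
#'
#' @export
setClass("QcParam",
  representation(minFeatures = "numeric", maxFeatures = "numeric",
                 maxPctMt = "numeric", doubletRate = "numeric")
)

setValidity("QcParam", function(object) {
  if (object@minFeatures >= object@maxFeatures) {
    return("minFeatures must be < maxFeatures")
  }
  if (object@maxPctMt <= 0 || object@maxPctMt > 100) {
    return("maxPctMt must be in (0, 100]")
  }
  if (object@doubletRate < 0 || object@doubletRate > 1) {
    return("doubletRate must be in [0, 1]")
  }
  TRUE
})

#' ssGSEA scoring parameters
#'
#' @slot alpha Rank-weight exponent on the rank statistic (>= 0).
#' @slot normalize Divide all scores by the global max - min after scoring.
#' @slot minSize,maxSize Bounds on the per-set size after intersection with
#'   the expression matrix genes; sets outside the bounds are dropped.
#'
#' @export
setClass("SsgseaParam",
  representation(alpha = "numeric", normalize = "logical",
                 minSize = "numeric", maxSize = "numeric")
)

setValidity("SsgseaParam", function(object) {
  if (object@alpha < 0) return("alpha must be >= 0")
  if (object@minSize > object@maxSize) return("minSize must be <= maxSize")
  if (object@minSize < 1) return("minSize must be >= 1")
  TRUE
})

#' Per-cell pathway score matrix
#'
#' A \linkS4class{SummarizedExperiment} with gene sets as rows and cells as
#' columns, assay \code{"ssgsea"}. The scoring parameters are snapshotted in
#' \code{metadata(x)$ssgseaParam} and the scored set names (post size-filter)
#' in \code{metadata(x)$scoredSets}.
#'
#' @export
setClass("PathwayScores", contains = "SummarizedExperiment")

setValidity("PathwayScores", function(object) {
  if (!"ssgsea" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'ssgsea' is required")
  }
  if (any(!is.finite(SummarizedExperiment::assay(object, "ssgsea")))) {
    return("scores must be finite")
  }
  TRUE
})

#' Reduced pathway-score embedding
#'
#' Cell projections from an SVD of the column-centered pathway-score matrix,
#' keeping the smallest leading set of components whose cumulative variance
#' reaches \code{target}. After [removeBatchComponent()] the removed
#' component's index (in the original component numbering) and its loadings
#' are recorded.
#'
#' @slot coords Numeric matrix, cells x retained components.
#' @slot varExplained Proportion of variance per retained component.
#' @slot target Cumulative-variance retention target (default 0.90).
#' @slot centering Column means subtracted before the SVD.
#' @slot loadings Pathway loadings (right singular vectors) of the retained
#'   components.
#' @slot removedComponent Index of the batch component removed, or NA.
#' @slot removedLoadings Loadings of the removed component (length 0 if none).
#'
#' @export
setClass("ReducedEmbedding",
  representation(coords = "matrix", varExplained = "numeric",
                 target = "numeric", centering = "numeric",
                 loadings = "matrix", removedComponent = "integer",
                 removedLoadings = "numeric")
)

setValidity("ReducedEmbedding", function(object) {
  if (ncol(object@coords) != length(object@varExplained)) {
    return("one variance entry per retained component required")
  }
  if (!is.na(object@removedComponent) &&
      object@removedComponent %in% colnames(object@coords)) {
    return("removed component must be absent from coords")
  }
  TRUE
})

#' Consensus-clustering parameters
#'
#' @slot kRange Candidate cluster numbers (default 2:10).
#' @slot nIterations Subsampled k-means iterations per k (default 100).
#' @slot subsampleFraction Fraction of cells drawn per iteration (default 0.8).
#' @slot band Open ambiguity interval for the PAC statistic (default (0.1, 0.9)).
#' @slot seed Seed for the iteration-level random stream.
#'
#' @export
setClass("ConsensusParam",
  representation(kRange = "integer", nIterations = "integer",
                 subsampleFraction = "numeric", band = "numeric",
                 seed = "integer")
)

setValidity("ConsensusParam", function(object) {
  if (object@subsampleFraction <= 0 || object@subsampleFraction >= 1) {
    return("subsampleFraction must be in (0, 1)")
  }
  b <- object@band
  if (length(b) != 2L || b[1] >= b[2] || b[1] <= 0 || b[2] >= 1) {
    return("band must be (low, high) with 0 < low < high < 1")
  }
  if (any(object@kRange < 2L)) return("kRange must be >= 2")
  TRUE
})

#' Consensus-clustering K selection result
#'
#' Per-k proportion of ambiguous clustering (PAC) and stability = 1 - PAC;
#' \code{selectedK} maximizes stability with ties broken toward the smallest k.
#'
#' @slot pac Named numeric, PAC per candidate k.
#' @slot selectedK The selected number of clusters.
#' @slot param The \linkS4class{ConsensusParam} used.
#' @slot consensus Optional list of per-k consensus matrices (kept when
#'   \code{keepMatrices = TRUE}).
#'
#' @export
setClass("ConsensusResult",
  representation(pac = "numeric", selectedK = "integer",
                 param = "ConsensusParam", consensus = "list")
)

setValidity("ConsensusResult", function(object) {
  if (any(object@pac < 0 | object@pac > 1, na.rm = TRUE)) {
    return("PAC values must be in [0, 1]")
  }
  if (!object@selectedK %in% object@param@kRange) {
    return("selectedK must lie in the evaluated k range")
  }
  TRUE
})

#' Archetype assignment
#'
#' Cell-to-archetype labels from SNN-Louvain clustering of the reduced
#' embedding, optionally annotated with per-archetype top-pathway profiles
#' ([dpeWilcoxon()]) and per-(patient, cycle) proportions
#' ([archetypeProportions()]).
#'
#' @slot labels Factor of archetype labels, named by cell id.
#' @slot resolution Louvain resolution that realized the partition.
#' @slot targetK Requested number of archetypes.
#' @slot achievedK Number of archetypes actually obtained.
#' @slot profiles data.frame of per-archetype enriched pathways (may be empty).
#' @slot proportions data.frame of per-(patient, cycle) archetype fractions
#'   (may be empty).
#'
#' @export
setClass("ArchetypeAssignment",
  representation(labels = "factor", resolution = "numeric",
                 targetK = "integer", achievedK = "integer",
                 profiles = "data.frame", proportions = "data.frame")
)

setValidity("ArchetypeAssignment", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by cell id")
  if (anyNA(object@labels)) return("labels must cover all clustered cells")
  TRUE
})

#' AUC-gated malignancy classifier
#'
#' Rank-correlation classifier trained on cells confidently labeled diploid or
#' aneuploid: each label gets a mean log-normalized reference profile over a
#' variable-gene panel, cells are scored by Spearman correlation to each
#' profile, and cross-validated one-vs-rest AUC (averaged over labels) gates
#' acceptance: predictions are applied only when \code{cvAuc > gateThreshold}.
#'
#' @slot profiles Numeric matrix, panel genes x labels, of mean log-normalized
#'   expression.
#' @slot panel Character vector of variable genes used for correlation.
#' @slot cvAuc Cross-validated multiclass (mean one-vs-rest) AUC.
#' @slot gateThreshold Acceptance threshold (default 0.7, strict inequality).
#' @slot accepted \code{cvAuc > gateThreshold}.
#' @slot folds Number of cross-validation folds actually used.
#' @slot seed Seed used for fold assignment.
#'
#' @export
setClass("ClassifierModel",
  representation(profiles = "matrix", panel = "character", cvAuc = "numeric",
                 gateThreshold = "numeric", accepted = "logical",
                 folds = "integer", seed = "integer")
)

setValidity("ClassifierModel", function(object) {
  if (!is.na(object@cvAuc) && (object@cvAuc < 0 || object@cvAuc > 1)) {
    return("cvAuc must be in [0, 1]")
  }
  if (!identical(object@accepted, object@cvAuc > object@gateThreshold)) {
    return("accepted must equal cvAuc > gateThreshold")
  }
  if (nrow(object@profiles) != length(object@panel)) {
    return("profiles rows must match the variable-gene panel")
  }
  TRUE
})

#' Synthetic cohort parameters
#'
#' Defines the statistical structure of a simulated longitudinal cohort:
#' negative-binomial counts whose gene log-means combine a baseline, an
#' archetype program effect, per-cycle trend drift on trend-program genes, a
#' per-patient global batch offset and multiplicative copy-number dosage on
#' contiguous gene blocks for aneuploid cells. Defaults emulate a two-patient
#' serial-biopsy study: one patient sampled over six treatment cycles with a
#' metabolism-like archetype rising to ~70% of cells at cycle 4 before
#' collapsing to ~34% at cycle 6, and one sampled over two cycles with a
#' stable ~69/31 split.
#'
#' @slot nPatients Number of patients.
#' @slot cyclesPerPatient Integer vector, cycles sampled per patient.
#' @slot cellsPerCycle Cells simulated per (patient, cycle).
#' @slot nGenes Number of genes.
#' @slot nArchetypes Number of latent archetypes (2-3).
#' @slot programSize Genes per archetype program.
#' @slot programLogFC Log-fold effect of a program on its genes.
#' @slot mixingSchedule List (one matrix per patient, cycles x archetypes) of
#'   archetype mixing proportions; rows sum to 1.
#' @slot trendSlopes Named numeric, per-cycle drift of each trend program on
#'   the gene log-mean scale.
#' @slot trendSize Genes per trend program.
#' @slot batchShift SD of the per-gene log-mean offset applied to patients
#'   after the first.
#' @slot nbDispersion Negative-binomial size parameter.
#' @slot libsizeSdlog SD (log scale) of the lognormal library-size factor.
#' @slot meanCountsPerCell Target mean library size.
#' @slot aneuploidFraction Fraction of cells that are truly aneuploid.
#' @slot cnaSegments data.frame(start, end, dosage): gene-index blocks with
#'   multiplicative dosage applied to aneuploid cells.
#' @slot undefinedFraction Fraction of cells whose ploidy label is masked to
#'   \code{"not.defined"}.
#' @slot nNullSets,nullSetSize Additional random gene sets with no planted
#'   structure, included in the emitted collection.
#' @slot seed Simulation seed.
#'
#' @export
setClass("SimParam",
  representation(nPatients = "integer", cyclesPerPatient = "integer",
                 cellsPerCycle = "integer", nGenes = "integer",
                 nArchetypes = "integer", programSize = "integer",
                 programLogFC = "numeric", mixingSchedule = "list",
                 trendSlopes = "numeric", trendSize = "integer",
                 batchShift = "numeric", nbDispersion = "numeric",
                 libsizeSdlog = "numeric", meanCountsPerCell = "numeric",
                 aneuploidFraction = "numeric", cnaSegments = "data.frame",
                 undefinedFraction = "numeric", nNullSets = "integer",
                 nullSetSize = "integer", seed = "integer")
)

setValidity("SimParam", function(object) {
  if (length(object@cyclesPerPatient) != object@nPatients) {
    return("cyclesPerPatient must have one entry per patient")
  }
  if (length(object@mixingSchedule) != object@nPatients) {
    return("mixingSchedule must have one matrix per patient")
  }
  for (p in seq_len(object@nPatients)) {
    m <- object@mixingSchedule[[p]]
    if (!is.matrix(m) || nrow(m) != object@cyclesPerPatient[p] ||
        ncol(m) != object@nArchetypes) {
      return("each mixingSchedule matrix must be cycles x archetypes")
    }
    if (any(abs(rowSums(m) - 1) > 1e-8)) {
      return("each mixingSchedule row must sum to 1 (within 1e-8)")
    }
    if (any(m < 0)) return("mixing proportions must be non-negative")
  }
  if (!all(is.finite(object@programLogFC)) ||
      !all(is.finite(object@trendSlopes))) {
    return("effect sizes must be finite")
  }
  fr <- c(object@aneuploidFraction, object@undefinedFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must be in [0, 1]")
  if (nrow(object@cnaSegments) > 0) {
    cs <- object@cnaSegments
    if (!all(c("start", "end", "dosage") %in% names(cs))) {
      return("cnaSegments needs columns start, end, dosage")
    }
    if (any(cs$start < 1 | cs$end > object@nGenes | cs$start > cs$end)) {
      return("cnaSegments out of gene range")
    }
    if (any(cs$dosage <= 0)) return("dosage must be positive")
  }
  TRUE
})
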