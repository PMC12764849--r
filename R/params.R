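# Constructors and methods for parameter and container classes.

#' @rdname GeneSetCollection-class
#' @param sets Named list of character vectors of gene symbols. Duplicate
#'   genes within a set are removed.
#' @param source Optional tag recording the collection's origin.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")), "toy")
#' lengths(geneSets(gsc))
#' @export
GeneSetCollection <- function(sets, source = NA_character_) {
  sets <- lapply(sets, unique)
  new("GeneSetCollection", sets = sets, source = as.character(source))
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("setSource", "GeneSetCollection", function(x) x@source)

#' @describeIn GeneSetCollection-class Number of sets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class Set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class Extract one set's genes by name or index.
#' @param i Set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection with", length(object@sets), "sets",
      sprintf("(source: %s)\n", object@source))
  cat("  set sizes:", min(sz), "-", max(sz),
      sprintf("(median %g)\n", stats::median(sz)))
})

#' @rdname QcParam-class
#' @param minFeatures,maxFeatures,maxPctMt,doubletRate See the class slots.
#' @return A \linkS4class{QcParam}.
#' @export
QcParam <- function(minFeatures = 300, maxFeatures = 8000, maxPctMt = 5,
                    doubletRate = 0.04) {
  new("QcParam", minFeatures = minFeatures, maxFeatures = maxFeatures,
      maxPctMt = maxPctMt, doubletRate = doubletRate)
}

setMethod("show", "QcParam", function(object) {
  cat(sprintf(
    "QcParam: keep cells with %g < nFeatures < %g and pctMt < %g%%\n",
    object@minFeatures, object@maxFeatures, object@maxPctMt))
  cat(sprintf("  assumed doublet rate (metadata only): %g\n",
              object@doubletRate))
})

#' @rdname SsgseaParam-class
#' @param alpha,normalize,minSize,maxSize See the class slots.
#' @return An \linkS4class{SsgseaParam}.
#' @export
SsgseaParam <- function(alpha = 0.25, normalize = TRUE, minSize = 2,
                        maxSize = 1000) {
  new("SsgseaParam", alpha = alpha, normalize = normalize,
      minSize = minSize, maxSize = maxSize)
}

setMethod("show", "SsgseaParam", function(object) {
  cat(sprintf(
    "SsgseaParam: alpha = %g, normalize = %s, set size in [%g, %g]\n",
    object@alpha, object@normalize, object@minSize, object@maxSize))
})

#' @rdname ConsensusParam-class
#' @param kRange,nIterations,subsampleFraction,band,seed See the class slots.
#' @return A \linkS4class{ConsensusParam}.
#' @export
ConsensusParam <- function(kRange = 2:10, nIterations = 100,
                           subsampleFraction = 0.8, band = c(0.1, 0.9),
                           seed = 1L) {
  new("ConsensusParam", kRange = as.integer(kRange),
      nIterations = as.integer(nIterations),
      subsampleFraction = subsampleFraction, band = as.numeric(band),
      seed = as.integer(seed))
}

setMethod("show", "ConsensusParam", function(object) {
  cat(sprintf(
    "ConsensusParam: k in [%d, %d], %d iterations x %g%% subsampling, PAC band (%g, %g)\n",
    min(object@kRange), max(object@kRange), object@nIterations,
    100 * object@subsampleFraction, object@band[1], object@band[2]))
})

# ---- result-class accessors & show ----

#' @rdname accessors
#' @export
setMethod("embCoords", "ReducedEmbedding", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "ReducedEmbedding", function(x) x@varExplained)

#' @rdname accessors
#' @export
setMethod("componentLoadings", "ReducedEmbedding", function(x) x@loadings)

#' @rdname accessors
#' @export
setMethod("removedComponent", "ReducedEmbedding", function(x) x@removedComponent)

setMethod("show", "ReducedEmbedding", function(object) {
  cat(sprintf(
    "ReducedEmbedding: %d cells x %d components (%.1f%% variance, target %.0f%%)\n",
    nrow(object@coords), ncol(object@coords),
    100 * sum(object@varExplained), 100 * object@target))
  if (!is.na(object@removedComponent)) {
    cat(sprintf("  batch component removed: SVD component %d\n",
                object@removedComponent))
  }
})

#' @rdname accessors
#' @export
setMethod("pacValues", "ConsensusResult", function(x) x@pac)

#' @rdname accessors
#' @export
setMethod("stabilityValues", "ConsensusResult", function(x) 1 - x@pac)

#' @rdname accessors
#' @export
setMethod("selectedK", "ConsensusResult", function(x) x@selectedK)

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =",
      paste(range(object@param@kRange), collapse = ".."), "\n")
  cat("  selected k:", object@selectedK,
      sprintf("(stability %.3f)\n", 1 - object@pac[as.character(object@selectedK)]))
  print(round(object@pac, 4))
})

#' @rdname accessors
#' @export
setMethod("archetypeLabels", "ArchetypeAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("archetypeProfiles", "ArchetypeAssignment", function(x) x@profiles)

#' @rdname accessors
#' @export
setMethod("proportionTable", "ArchetypeAssignment", function(x) x@proportions)

#' @rdname accessors
#' @export
setMethod("clusterResolution", "ArchetypeAssignment", function(x) x@resolution)

setMethod("show", "ArchetypeAssignment", function(object) {
  cat(sprintf("ArchetypeAssignment: %d cells in %d archetypes (target %d)\n",
              length(object@labels), object@achievedK, object@targetK))
  print(table(object@labels))
  if (nrow(object@profiles)) {
    cat("  profiles:", nrow(object@profiles), "pathway rows\n")
  }
})

#' @rdname accessors
#' @export
setMethod("referenceProfiles", "ClassifierModel", function(x) x@profiles)

#' @rdname accessors
#' @export
setMethod("variableGenes", "ClassifierModel", function(x) x@panel)

#' @rdname accessors
#' @export
setMethod("cvAuc", "ClassifierModel", function(x) x@cvAuc)

#' @rdname accessors
#' @export
setMethod("isAccepted", "ClassifierModel", function(x) x@accepted)

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: %d-gene panel, labels: %s\n",
    length(object@panel), paste(colnames(object@profiles), collapse = ", ")))
  cat(sprintf("  cross-validated AUC = %.4f (%d folds); gate > %g: %s\n",
              object@cvAuc, object@folds, object@gateThreshold,
              if (object@accepted) "ACCEPTED" else "rejected"))
})
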