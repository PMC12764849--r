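#' @name accessors
#' @title Accessors for scArchetypes classes
#'
#' @description Slot accessors for the S4 result classes. Use these rather
#' than reaching into slots directly.
#'
#' @param x An object of the documented class.
#' @return The accessed component; see the individual class pages.
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setSource", function(x) standardGeneric("setSource"))

#' @rdname accessors
#' @export
setGeneric("embCoords", function(x) standardGeneric("embCoords"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("componentLoadings", function(x) standardGeneric("componentLoadings"))

#' @rdname accessors
#' @export
setGeneric("removedComponent", function(x) standardGeneric("removedComponent"))

#' @rdname accessors
#' @export
setGeneric("pacValues", function(x) standardGeneric("pacValues"))

#' @rdname accessors
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname accessors
#' @export
setGeneric("archetypeLabels", function(x) standardGeneric("archetypeLabels"))

#' @rdname accessors
#' @export
setGeneric("archetypeProfiles", function(x) standardGeneric("archetypeProfiles"))

#' @rdname accessors
#' @export
setGeneric("proportionTable", function(x) standardGeneric("proportionTable"))

#' @rdname accessors
#' @export
setGeneric("clusterResolution", function(x) standardGeneric("clusterResolution"))

#' @rdname accessors
#' @export
setGeneric("referenceProfiles", function(x) standardGeneric("referenceProfiles"))

#' @rdname accessors
#' @export
setGeneric("variableGenes", function(x) standardGeneric("variableGenes"))

#' @rdname accessors
#' @export
setGeneric("cvAuc", function(x) standardGeneric("cvAuc"))

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
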