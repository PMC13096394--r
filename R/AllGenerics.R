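#' @include AllClasses.R
NULL

#' Accessors for ascvs classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an ascvs object.
#' @return \code{objectIds}: character vector of object identifiers.
#' @name accessors
#' @aliases objectIds
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname accessors
#' @return \code{classLevels}: class gradation labels in
#'   classification-scale order.
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))

#' @rdname accessors
#' @return \code{gradationInfo}: data.frame describing the descriptive
#'   gradations (scale, kind, index, label, id).
#' @export
setGeneric("gradationInfo", function(x) standardGeneric("gradationInfo"))

#' @rdname accessors
#' @return \code{scaleCounts}: named vector with \code{nText},
#'   \code{nNumeric} and \code{nGradations}.
#' @export
setGeneric("scaleCounts", function(x) standardGeneric("scaleCounts"))

#' @rdname accessors
#' @return \code{incidence}: sparse binary objects-by-gradations matrix.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname accessors
#' @return \code{classOf}: factor of true class gradations.
#' @export
setGeneric("classOf", function(x) standardGeneric("classOf"))

#' @rdname accessors
#' @return \code{scaleSet}: the associated [ScaleSet-class].
#' @export
setGeneric("scaleSet", function(x) standardGeneric("scaleSet"))

#' @rdname accessors
#' @return \code{freqCounts}: the absolute frequency matrix \eqn{N_{ij}}.
#' @export
setGeneric("freqCounts", function(x) standardGeneric("freqCounts"))

#' @rdname accessors
#' @return \code{modelValues}: the knowledge matrix \eqn{I_{ij}}.
#' @export
setGeneric("modelValues", function(x) standardGeneric("modelValues"))

#' @rdname accessors
#' @return \code{similarityMatrix}: objects-by-classes percent similarities.
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @return \code{predictedClass}: factor of predicted classes.
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))

#' @rdname accessors
#' @return \code{reliabilityTable}: one evaluation row per model.
#' @export
setGeneric("reliabilityTable", function(x) standardGeneric("reliabilityTable"))

#' @rdname accessors
#' @return \code{bestModel}: criterion id of the L1-selected model.
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

setMethod("objectIds", "DescriptorTable", function(x) x@objectIds)
setMethod("objectIds", "CodedSample", function(x) rownames(x@incidence))
setMethod("objectIds", "RecognitionResult", function(x) rownames(x@similarity))

setMethod("classLevels", "ScaleSet", function(x) x@classScale$levels)
setMethod("classLevels", "CodedSample", function(x) levels(x@classOf))
setMethod("classLevels", "FrequencyMatrix", function(x) colnames(x@counts))
setMethod("classLevels", "KnowledgeModel", function(x) colnames(x@values))

setMethod("gradationInfo", "ScaleSet", function(x) x@gradations)
setMethod("gradationInfo", "KnowledgeModel", function(x) x@scaleSet@gradations)

setMethod("scaleCounts", "ScaleSet", function(x) {
  kinds <- vapply(x@scales, `[[`, character(1), "kind")
  c(nText = sum(kinds == "text"), nNumeric = sum(kinds == "numeric"),
    nGradations = nrow(x@gradations))
})

setMethod("incidence", "CodedSample", function(x) x@incidence)
setMethod("classOf", "CodedSample", function(x) x@classOf)
setMethod("scaleSet", "CodedSample", function(x) x@scaleSet)
setMethod("scaleSet", "FrequencyMatrix", function(x) x@scaleSet)
setMethod("scaleSet", "KnowledgeModel", function(x) x@scaleSet)

setMethod("freqCounts", "FrequencyMatrix", function(x) x@counts)
setMethod("modelValues", "KnowledgeModel", function(x) x@values)

setMethod("similarityMatrix", "RecognitionResult", function(x) x@similarity)
setMethod("predictedClass", "RecognitionResult", function(x) x@predicted)
setMethod("classOf", "RecognitionResult", function(x) x@trueClass)

setMethod("reliabilityTable", "ReliabilityReport", function(x) x@table)
setMethod("bestModel", "ReliabilityReport", function(x) x@best)

#' Margins and probability views of a frequency matrix
#'
#' @param x a [FrequencyMatrix-class].
#' @return \code{gradTotals}: \eqn{N_i}; \code{classTotals}: \eqn{N_j};
#'   \code{grandTotal}: \eqn{N}; \code{objectTotals}: per-class object
#'   counts \eqn{N^{obj}_j} plus total.
#' @name freq-margins
#' @aliases gradTotals
#' @export
setGeneric("gradTotals", function(x) standardGeneric("gradTotals"))
#' @rdname freq-margins
#' @export
setGeneric("classTotals", function(x) standardGeneric("classTotals"))
#' @rdname freq-margins
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))
#' @rdname freq-margins
#' @export
setGeneric("objectTotals", function(x) standardGeneric("objectTotals"))

setMethod("gradTotals", "FrequencyMatrix", function(x) rowSums(x@counts))
setMethod("classTotals", "FrequencyMatrix", function(x) colSums(x@counts))
setMethod("grandTotal", "FrequencyMatrix", function(x) sum(x@counts))
setMethod("objectTotals", "FrequencyMatrix", function(x)
  c(x@nObjPerClass, total = x@nObj))
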