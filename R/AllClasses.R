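#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Raw descriptor table
#'
#' An untyped objects-by-columns descriptor table as read from disk: one row
#' per screened object, one designated classification column (e.g.
#' \code{Outcome} with gradations \code{Active}/\code{Inactive}) and an
#' arbitrary mix of text and numeric descriptor columns, all stored as
#' character until scales are built.
#'
#' @slot objectIds unique, non-empty object identifiers.
#' @slot classLabels class label per object; never missing.
#' @slot className name of the classification column.
#' @slot idName name of the identifier column in the source file, or
#'   \code{""} when identifiers were generated sequentially.
#' @slot data descriptor columns in file order, character storage, \code{NA}
#'   for missing cells.
#' @slot columnOrder the full header in file order, used to reproduce the
#'   layout on write.
#'
#' @seealso [readDescriptorTable()], [buildScales()]
#' @export
setClass("DescriptorTable", representation(
  objectIds   = "character",
  classLabels = "character",
  className   = "character",
  idName      = "character",
  data        = "data.frame",
  columnOrder = "character"
))

setValidity("DescriptorTable", function(object) {
  n <- length(object@objectIds)
  msg <- character()
  if (anyDuplicated(object@objectIds))
    msg <- c(msg, "object identifiers must be unique")
  if (any(!nzchar(object@objectIds)) || anyNA(object@objectIds))
    msg <- c(msg, "object identifiers must be non-empty")
  if (length(object@classLabels) != n)
    msg <- c(msg, "one class label per object required")
  if (anyNA(object@classLabels) || any(!nzchar(object@classLabels)))
    msg <- c(msg, sprintf("class column '%s' contains missing values",
                          object@className))
  if (nrow(object@data) != n)
    msg <- c(msg, "descriptor columns must have one value slot per object")
  if (length(msg)) msg else TRUE
})

#' Scale set
#'
#' The formalized view of a descriptor table: the classification scale plus
#' one descriptive scale per retained column, each partitioned into discrete
#' gradations (text categories, point values, or half-open numeric
#' intervals).  Gradations are the unit rows of every downstream matrix and
#' carry globally unique identifiers \code{"scale::label"}.
#'
#' @slot classScale list with \code{name} and \code{levels} (class gradation
#'   labels in classification-scale order, used for tie-breaking).
#' @slot scales named list of descriptive scales; each a list with
#'   \code{name}, \code{kind} (\code{"text"} or \code{"numeric"}), and either
#'   \code{levels} (text), \code{points} (numeric with few distinct values)
#'   or \code{breaks} (interval bin edges, half-open \code{[lo, hi)} with the
#'   last interval closed).
#' @slot gradations data.frame with one row per descriptive gradation:
#'   \code{scale}, \code{kind}, \code{index} (1-based within scale),
#'   \code{label}, \code{id}.
#'
#' @seealso [buildScales()], [codeObjects()]
#' @export
setClass("ScaleSet", representation(
  classScale = "list",
  scales     = "list",
  gradations = "data.frame"
))

setValidity("ScaleSet", function(object) {
  msg <- character()
  if (length(object@classScale$levels) < 1L)
    msg <- c(msg, "classification scale needs at least one gradation")
  if (length(object@scales) &&
      any(vapply(object@scales, function(s) .nGradations(s) < 1L, logical(1))))
    msg <- c(msg, "every scale needs at least one gradation")
  if (anyDuplicated(object@gradations$id))
    msg <- c(msg, "gradation identifiers must be globally unique")
  if (nrow(object@gradations) !=
      sum(vapply(object@scales, .nGradations, integer(1))))
    msg <- c(msg, "gradation table inconsistent with scale list")
  if (length(msg)) msg else TRUE
})

.nGradations <- function(s) {
  if (s$kind == "text") return(length(s$levels))
  if (!is.null(s$points)) return(length(s$points))
  length(s$breaks) - 1L
}

#' Coded training sample
#'
#' The binary object-by-gradation incidence structure produced by coding a
#' [DescriptorTable-class] against a [ScaleSet-class]: for each object and
#' each descriptive scale with a non-missing value exactly one gradation bit
#' is set; missing values set none.
#'
#' @slot incidence sparse binary matrix, objects (rows, named by object id)
#'   by descriptive gradations (columns, named by gradation id).
#' @slot classOf factor of true class gradations, levels in
#'   classification-scale order.
#' @slot scaleSet the [ScaleSet-class] the sample was coded with.
#'
#' @seealso [codeObjects()], [frequencyMatrix()]
#' @export
setClass("CodedSample", representation(
  incidence = "dgCMatrix",
  classOf   = "factor",
  scaleSet  = "ScaleSet"
))

setValidity("CodedSample", function(object) {
  msg <- character()
  if (nrow(object@incidence) != length(object@classOf))
    msg <- c(msg, "one class label per coded object required")
  if (!identical(levels(object@classOf), object@scaleSet@classScale$levels))
    msg <- c(msg, "class factor levels must match the classification scale")
  if (ncol(object@incidence) != nrow(object@scaleSet@gradations))
    msg <- c(msg, "incidence columns must match the descriptive gradations")
  x <- object@incidence@x
  if (length(x) && any(x != 1))
    msg <- c(msg, "incidence must be binary")
  if (length(msg)) msg else TRUE
})

#' Gradation-by-class frequency matrix
#'
#' Absolute co-occurrence counts \eqn{N_{ij}}: the number of training objects
#' of class \eqn{j} whose incidence bit for descriptive gradation \eqn{i} is
#' set, together with the per-class object counts.  All nine knowledge models
#' are functions of this object alone.  Margins \eqn{N_i = \sum_j N_{ij}},
#' \eqn{N_j = \sum_i N_{ij}} and the grand total \eqn{N} are available via
#' accessors, as are the conditional/unconditional probability views
#' \eqn{P1_{ij} = N_{ij}/N_j}, \eqn{P2_{ij} = N_{ij}/N^{obj}_j},
#' \eqn{P1_i = N_i/N}, \eqn{P2_i = N_i/N^{obj}} (0/0 read as 0).
#'
#' @slot counts integer-valued matrix, gradations x classes.
#' @slot nObjPerClass objects per class gradation.
#' @slot nObj total number of training objects.
#' @slot scaleSet the originating [ScaleSet-class].
#'
#' @seealso [frequencyMatrix()], [buildModel()]
#' @export
setClass("FrequencyMatrix", representation(
  counts       = "matrix",
  nObjPerClass = "numeric",
  nObj         = "numeric",
  scaleSet     = "ScaleSet"
))

setValidity("FrequencyMatrix", function(object) {
  msg <- character()
  ct <- object@counts
  if (any(ct < 0) || any(ct != round(ct)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@nObjPerClass) != ncol(ct))
    msg <- c(msg, "one object count per class required")
  if (abs(sum(object@nObjPerClass) - object@nObj) > 1e-9)
    msg <- c(msg, "per-class object counts must sum to the total")
  if (any(sweep(ct, 2, object@nObjPerClass) > 0))
    msg <- c(msg, "a gradation cannot co-occur with a class more often than the class has objects")
  if (length(msg)) msg else TRUE
})

#' Knowledge model
#'
#' One criterion's real-valued knowledge matrix \eqn{I_{ij}} over descriptive
#' gradations (rows) and class gradations (columns), quantifying how much
#' each feature value promotes (\eqn{I_{ij} > 0}) or hinders
#' (\eqn{I_{ij} < 0}) membership in each class.  See [buildModel()] for the
#' nine criteria.
#'
#' @slot criterion one of \code{"PRC1"}, \code{"PRC2"}, \code{"INF1"} ...
#'   \code{"INF7"}.
#' @slot values the matrix \eqn{I_{ij}}, finite everywhere.
#' @slot psi the Kharkevich emergence normalization
#'   \eqn{\Psi = 1/\log_2 N^{obj}} (used by INF1/INF2; carried for all).
#' @slot scaleSet the originating [ScaleSet-class].
#' @slot fingerprint hash of the source [FrequencyMatrix-class] counts.
#'
#' @seealso [buildModel()], [similarityScores()], [informationPortrait()]
#' @export
setClass("KnowledgeModel", representation(
  criterion   = "character",
  values      = "matrix",
  psi         = "numeric",
  scaleSet    = "ScaleSet",
  fingerprint = "character"
))

setValidity("KnowledgeModel", function(object) {
  msg <- character()
  if (!object@criterion %in% modelCriteria())
    msg <- c(msg, "unknown criterion id")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "knowledge matrix must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Recognition result
#'
#' Per-object signed percent similarities \eqn{S(o, j) \in [-100, 100]} to
#' every class gradation, the implied descending class ranking, and the
#' predicted class (top of the ranking, ties broken by
#' classification-scale order).
#'
#' @slot similarity numeric matrix, objects x classes, in percent.
#' @slot predicted factor of predicted classes.
#' @slot trueClass factor of true classes (length 0 when unknown).
#' @slot criterion the integral criterion used (\code{"correlation"} or
#'   \code{"info_sum"}).
#' @slot modelCriterion criterion id of the knowledge model scored against.
#'
#' @seealso [classifySample()], [identificationAccuracy()],
#'   [confusionCounts()]
#' @export
setClass("RecognitionResult", representation(
  similarity     = "matrix",
  predicted      = "factor",
  trueClass      = "factor",
  criterion      = "character",
  modelCriterion = "character"
))

setValidity("RecognitionResult", function(object) {
  msg <- character()
  if (any(abs(object@similarity) > 100 + 1e-9))
    msg <- c(msg, "similarities must lie in [-100, 100]")
  if (length(object@predicted) != nrow(object@similarity))
    msg <- c(msg, "one prediction per object required")
  if (length(object@trueClass) &&
      length(object@trueClass) != nrow(object@similarity))
    msg <- c(msg, "true classes, when present, must cover every object")
  if (length(msg)) msg else TRUE
})

#' Reliability report
#'
#' Crisp and fuzzy evaluation of one or more knowledge models on a coded
#' sample: micro-averaged confusion counts over object-by-class positive
#' decisions (\eqn{S > 0}), the Van Rijsbergen F-measure, the
#' similarity-weighted fuzzy L1 analogue, and identification accuracy; plus
#' the L1-selected best model.
#'
#' @slot table data.frame, one row per model: \code{criterion}, \code{TP},
#'   \code{FP}, \code{FN}, \code{TN}, \code{TPf}, \code{FPf}, \code{FNf},
#'   \code{precision}, \code{recall}, \code{F1}, \code{L1},
#'   \code{accuracy}.
#' @slot best criterion id of the winning model (highest L1; ties by F1,
#'   then criterion id).
#'
#' @seealso [selectBestModel()], [l1Measure()]
#' @export
setClass("ReliabilityReport", representation(
  table = "data.frame",
  best  = "character"
))

#' Significance table
#'
#' Per-gradation significance \eqn{\sigma_i} (population standard deviation
#' of \eqn{I_{ij}} across classes), per-scale significance (mean over the
#' scale's gradations), and the cumulative normalized Pareto curves, both
#' sorted descending.
#'
#' @slot gradations data.frame: \code{id}, \code{scale}, \code{index},
#'   \code{label}, \code{sigma}, \code{cumPercent}.
#' @slot scales data.frame: \code{scale}, \code{sigma}, \code{cumPercent}.
#' @slot criterion criterion id of the model the table was computed from.
#'
#' @seealso [significanceTable()], [paretoCoverage()]
#' @export
setClass("SignificanceTable", representation(
  gradations = "data.frame",
  scales     = "data.frame",
  criterion  = "character"
))

setValidity("SignificanceTable", function(object) {
  msg <- character()
  for (nm in c("gradations", "scales")) {
    df <- slot(object, nm)
    if (any(df$sigma < 0)) msg <- c(msg, "significances must be non-negative")
    if (is.unsorted(rev(df$sigma))) msg <- c(msg, "rows must be sorted descending")
    if (nrow(df) && abs(df$cumPercent[nrow(df)] - 100) > 1e-6)
      msg <- c(msg, "cumulative curve must end at 100%")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic ground truth
#'
#' The generation record accompanying a synthetic bioassay table: which
#' gradations carry planted class association (and in which direction),
#' which objects had their class labels flipped, and the generator
#' parameters, so that parameter-recovery metrics can be computed in the
#' same coordinates the models score.
#'
#' @slot seed integer seed the table was generated from.
#' @slot informative data.frame: \code{scale}, \code{kind},
#'   \code{gradation} (text label, or bin index as character for numeric
#'   scales), \code{direction} (+1 toward the active class).
#' @slot activeRate nominal active-class prevalence in (0, 1).
#' @slot artifactIds object ids whose labels were flipped (planted
#'   artifacts).
#' @slot params full generator parameter list.
#'
#' @seealso [generateBioassay()], [truthRecoveryReport()]
#' @export
setClass("SyntheticTruth", representation(
  seed        = "integer",
  informative = "data.frame",
  activeRate  = "numeric",
  artifactIds = "character",
  params      = "list"
))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (object@activeRate <= 0 || object@activeRate >= 1)
    msg <- c(msg, "activeRate must lie in (0, 1)")
  if (!is.null(object@params$effectSize) && object@params$effectSize < 0)
    msg <- c(msg, "effect size must be non-negative")
  if (length(msg)) msg else TRUE
})
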