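#' @include AllClasses.R AllGenerics.R
NULL

#' Crisp and fuzzy confusion components
#'
#' Counts positive decisions over all (object, class) pairs: a pair with
#' similarity \eqn{S > 0} is a true positive when the class is the object's
#' true class and a false positive otherwise; pairs with \eqn{S \le 0} are
#' false negatives when true and true negatives otherwise.  The fuzzy
#' components accumulate \eqn{|S|/100} instead of 1 for TP, FP and FN, so a
#' barely-positive correct decision earns little credit and a confident
#' wrong one costs much.
#'
#' @param result a [RecognitionResult-class] with known true classes.
#' @return named list: \code{TP}, \code{FP}, \code{FN}, \code{TN},
#'   \code{TPf}, \code{FPf}, \code{FNf}, \code{nPairs}.
#' @export
confusionCounts <- function(result) {
  stopifnot(is(result, "RecognitionResult"))
  if (!length(result@trueClass)) .stopf("true classes required")
  S <- result@similarity
  truth <- outer(as.character(result@trueClass), colnames(S), "==")
  pos <- S > 0
  A <- abs(S) / 100
  list(TP = sum(pos & truth), FP = sum(pos & !truth),
       FN = sum(!pos & truth), TN = sum(!pos & !truth),
       TPf = sum(A[pos & truth]), FPf = sum(A[pos & !truth]),
       FNf = sum(A[!pos & truth]), nPairs = length(S))
}

#' Van Rijsbergen F-measure
#'
#' \eqn{F_1 = 2TP / (2TP + FP + FN)} over the crisp confusion components.
#' When no pair is positive and no pair is actually a member
#' (\eqn{TP + FP + FN = 0}) the measure is undefined and reported as 0 with
#' an \code{"undefined"} attribute.
#'
#' @param components output of [confusionCounts()].
#' @return F-measure in \eqn{[0, 1]}.
#' @export
fMeasure <- function(components) {
  d <- 2 * components$TP + components$FP + components$FN
  if (d == 0) return(structure(0, undefined = TRUE))
  2 * components$TP / d
}

#' Fuzzy L1 reliability measure
#'
#' A similarity-weighted analogue of the F-measure:
#' \eqn{L_1 = 2\,TP_f / (2\,TP_f + FP_f + FN_f)} where the fuzzy components
#' weight every decision by its similarity magnitude \eqn{|S|/100}.  Equal
#' to the crisp \eqn{F_1} whenever all decisions are made at
#' \eqn{|S| \in \{0, 100\}}.
#'
#' @param components output of [confusionCounts()].
#' @return L1 measure in \eqn{[0, 1]}.
#' @export
l1Measure <- function(components) {
  d <- 2 * components$TPf + components$FPf + components$FNf
  if (d == 0) return(structure(0, undefined = TRUE))
  2 * components$TPf / d
}

# one evaluation row for a model already classified
.reliabilityRow <- function(criterion, result) {
  cc <- confusionCounts(result)
  prec <- if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)
  rec <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
  data.frame(criterion = criterion, TP = cc$TP, FP = cc$FP, FN = cc$FN,
             TN = cc$TN, TPf = cc$TPf, FPf = cc$FPf, FNf = cc$FNf,
             precision = prec, recall = rec,
             F1 = as.numeric(fMeasure(cc)), L1 = as.numeric(l1Measure(cc)),
             accuracy = identificationAccuracy(result),
             stringsAsFactors = FALSE)
}

#' Evaluate all models and select the most reliable
#'
#' Classifies the training sample under every supplied knowledge model,
#' computes the crisp F-measure, the fuzzy L1 measure and identification
#' accuracy for each, and selects the model with the highest L1 (ties broken
#' by F1, then by criterion id) as the current model for downstream work.
#' The evaluation is retrospective on the training sample, mirroring the
#' standard ASC protocol; see the package vignette for the optimism this
#' implies.
#'
#' @param sample a [CodedSample-class].
#' @param models named list of [KnowledgeModel-class] objects (e.g. from
#'   [buildAllModels()]).
#' @param criterion integral criterion passed to [classifySample()].
#' @return a [ReliabilityReport-class].
#' @export
selectBestModel <- function(sample, models,
                            criterion = c("correlation", "info_sum")) {
  stopifnot(is(sample, "CodedSample"), length(models) >= 1L)
  criterion <- match.arg(criterion)
  rows <- lapply(models, function(m)
    .reliabilityRow(m@criterion, classifySample(sample, m, criterion)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(-tab$L1, -tab$F1, tab$criterion)
  new("ReliabilityReport", table = tab[ord, ], best = tab$criterion[ord[1L]])
}

#' Export a reliability table
#'
#' @param report a [ReliabilityReport-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReliabilityTable <- function(report, path) {
  stopifnot(is(report, "ReliabilityReport"))
  utils::write.table(report@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
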