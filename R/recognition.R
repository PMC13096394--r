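#' @include AllClasses.R AllGenerics.R
NULL

# core similarity engine over a (possibly sparse) objects x gradations
# matrix; returns objects x classes percent similarities
.similarityCore <- function(X, I, criterion) {
  if (ncol(X) != nrow(I))
    .stopf("incidence has %d gradations but the model has %d",
           ncol(X), nrow(I))
  if (any(!is.finite(I))) .stopf("model contains non-finite cells")
  XI <- as.matrix(X %*% I)                      # sum_i I_ij L_i
  if (criterion == "info_sum") {
    denom <- colSums(abs(I))
    S <- sweep(XI, 2, ifelse(denom == 0, Inf, denom), "/")
  } else {
    G <- nrow(I)
    s <- Matrix::rowSums(X)                     # set bits per object
    num <- XI - outer(s / G, colSums(I))        # sum (L - Lbar)(I - Ibar)
    ssL <- s - s^2 / G                          # sum (L - Lbar)^2
    ssI <- colSums(I^2) - colSums(I)^2 / G
    den <- outer(sqrt(pmax(ssL, 0)), sqrt(pmax(ssI, 0)))
    S <- ifelse(den == 0, 0, num / den)
  }
  S <- pmin(pmax(S * 100, -100), 100)
  dimnames(S) <- list(rownames(X), colnames(I))
  S
}

#' Similarity of an object to every class
#'
#' The integral criterion: a signed percent scalar comparing an object's
#' binary feature-indicator vector \eqn{L} with each class column of the
#' knowledge matrix.  Two reconstructions are provided:
#' \describe{
#'   \item{correlation (default)}{\eqn{S(o,j) = 100\,\mathrm{cor}((I_{ij})_i,
#'     (L_i)_i)}, the resonance-style bounded criterion; 0 when either
#'     vector has zero variance.}
#'   \item{info_sum}{\eqn{S(o,j) = 100 \sum_i I_{ij} L_i / \sum_i
#'     |I_{ij}|}, the additive sum-of-knowledge reading; 0 when the
#'     denominator is 0.}
#' }
#'
#' @param L binary incidence vector (one slot per descriptive gradation), or
#'   a matrix of such rows.
#' @param model a [KnowledgeModel-class].
#' @param criterion \code{"correlation"} or \code{"info_sum"}.
#' @return named numeric vector of percent similarities (or a matrix when
#'   \code{L} is a matrix).
#' @export
similarityScores <- function(L, model,
                             criterion = c("correlation", "info_sum")) {
  stopifnot(is(model, "KnowledgeModel"))
  criterion <- match.arg(criterion)
  vec <- is.null(dim(L))
  X <- if (vec) matrix(as.numeric(L), nrow = 1L) else as.matrix(L)
  S <- .similarityCore(X, model@values, criterion)
  if (vec) S[1L, ] else S
}

#' Classify every object of a coded sample
#'
#' Scores each object's similarity to every class under the chosen model and
#' integral criterion, ranks the classes in descending similarity, and
#' predicts the top class.  Ties are broken by classification-scale order
#' and reported via a message when they fire.
#'
#' @param sample a [CodedSample-class] coded with the model's scale set.
#' @param model a [KnowledgeModel-class].
#' @param criterion integral criterion, as in [similarityScores()].
#' @return a [RecognitionResult-class].
#' @export
classifySample <- function(sample, model,
                           criterion = c("correlation", "info_sum")) {
  stopifnot(is(sample, "CodedSample"), is(model, "KnowledgeModel"))
  criterion <- match.arg(criterion)
  if (!identical(colnames(sample@incidence), rownames(model@values)))
    .stopf("sample and model use different descriptive gradations")
  S <- .similarityCore(sample@incidence, model@values, criterion)
  top <- max.col(S, ties.method = "first")
  nTies <- sum(apply(S, 1L, function(r) sum(r == max(r)) > 1L))
  if (nTies > 0L)
    message(sprintf("similarity ties for %d object(s); broken by class order",
                    nTies))
  lev <- colnames(S)
  new("RecognitionResult", similarity = S,
      predicted = factor(lev[top], levels = lev),
      trueClass = sample@classOf, criterion = criterion,
      modelCriterion = model@criterion)
}

#' Identification accuracy
#'
#' @param result a [RecognitionResult-class] with known true classes.
#' @return percent of objects whose predicted class equals their true class.
#' @export
identificationAccuracy <- function(result) {
  stopifnot(is(result, "RecognitionResult"))
  if (nrow(result@similarity) == 0L) .stopf("empty recognition result")
  if (!length(result@trueClass))
    .stopf("true classes unknown; accuracy undefined")
  100 * mean(as.character(result@predicted) ==
               as.character(result@trueClass))
}

#' Export a recognition report
#'
#' One row per (object, class) pair with the percent similarity, the class
#' rank for that object, and the predicted flag, sorted within object by
#' descending similarity.
#'
#' @param result a [RecognitionResult-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecognitionReport <- function(result, path) {
  stopifnot(is(result, "RecognitionResult"))
  S <- result@similarity
  n <- nrow(S); K <- ncol(S)
  rows <- lapply(seq_len(n), function(o) {
    ord <- order(-S[o, ], seq_len(K))
    data.frame(object_id = rownames(S)[o], class = colnames(S)[ord],
               similarity_percent = S[o, ord], rank = seq_len(K),
               predicted = colnames(S)[ord] ==
                 as.character(result@predicted[o]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
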