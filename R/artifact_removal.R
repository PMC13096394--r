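#' @include AllClasses.R AllGenerics.R
NULL

#' Flag training artifacts
#'
#' An artifact is a training object whose similarity to its own class falls
#' below the threshold: its features, its class, or their relationship is
#' effectively random, and keeping it degrades model reliability.  The
#' comparison is strict (\code{<}) on the signed percent scale.
#'
#' By default the own-class similarity is computed leave-one-out: the
#' object's own contribution to the frequency counts is subtracted before
#' its class column is formed.  A training object always pulls its class
#' profile toward itself, and with few objects in a class this
#' self-similarity inflates the score of exactly the label-noise objects the
#' mechanism exists to catch; leave-one-out scoring removes that bias.
#' \code{leaveOneOut = FALSE} scores against the model as trained.
#'
#' @param sample a [CodedSample-class].
#' @param model a [KnowledgeModel-class] trained on the sample (or, with
#'   \code{leaveOneOut = FALSE}, on a superset).
#' @param threshold percent similarity threshold in \eqn{[-100, 100]}
#'   (default 12).
#' @param criterion integral criterion, as in [similarityScores()].
#' @param leaveOneOut subtract each object's own count contribution before
#'   scoring it (default TRUE); requires the model to have been trained on
#'   exactly \code{sample}.
#' @return data.frame of flagged objects: \code{object_id},
#'   \code{own_class_similarity}.
#' @export
flagArtifacts <- function(sample, model, threshold = 12,
                          criterion = c("correlation", "info_sum"),
                          leaveOneOut = TRUE) {
  stopifnot(is(sample, "CodedSample"), is(model, "KnowledgeModel"))
  if (threshold < -100 || threshold > 100)
    .stopf("threshold must lie in [-100, 100]")
  criterion <- match.arg(criterion)
  own <- if (leaveOneOut)
    .looOwnSimilarity(sample, model@criterion, criterion)
  else {
    S <- .similarityCore(sample@incidence, model@values, criterion)
    S[cbind(seq_len(nrow(S)), as.integer(sample@classOf))]
  }
  flag <- own < threshold
  data.frame(object_id = objectIds(sample)[flag],
             own_class_similarity = own[flag],
             stringsAsFactors = FALSE)
}

# own-class similarity with the object's own contribution removed from the
# counts; falls back to the full-sample column when a class has one object
.looOwnSimilarity <- function(sample, modelCriterion, integral) {
  freq <- frequencyMatrix(sample)
  X <- sample@incidence
  cls <- as.integer(sample@classOf)
  Nij <- freq@counts
  Ni <- rowSums(Nij); Nj <- colSums(Nij); N <- sum(Nij)
  nObj <- freq@nObj; nObjJ <- freq@nObjPerClass
  G <- nrow(Nij)
  full <- buildModel(freq, modelCriterion)@values
  out <- numeric(nrow(X))
  Xt <- Matrix::t(X)   # column access per object
  for (o in seq_len(nrow(X))) {
    L <- Xt[, o]
    s <- sum(L)
    j <- cls[o]
    if (nObjJ[j] <= 1) {            # LOO would empty the class
      Icol <- full[, j]
    } else {
      nij <- Nij[, j] - L
      ni <- Ni - L
      nj <- Nj[j] - s
      n2 <- N - s
      nobj <- nObj - 1
      nobjj <- nObjJ[j] - 1
      Icol <- .modelColumn(modelCriterion, nij, ni, nj, n2, nobj, nobjj)
    }
    out[o] <- .integralScalar(Icol, L, s, G, integral)
  }
  out
}

# one class column of a knowledge model from marginal pieces
.modelColumn <- function(criterion, nij, ni, nj, N, nObj, nObjJ) {
  zs <- function(v) { v[nij == 0] <- 0; v }
  safeDiv <- function(a, b) {
    if (length(b) == 1L) {
      if (b == 0) rep(0, length(a)) else a / b
    } else ifelse(b == 0, 0, a / b)
  }
  switch(criterion,
    PRC1 = safeDiv(nij, nj),
    PRC2 = nij / nObjJ,
    INF1 = zs(1 / log2(nObj) *
                log2(safeDiv(nij / nObjJ, ifelse(ni == 0, Inf, ni / nObj)))),
    INF2 = zs(1 / log2(nObj) *
                log2(safeDiv(safeDiv(nij, nj),
                             ifelse(ni == 0, Inf, ni / N)))),
    INF3 = nij - ni * nj / N,
    INF4 = zs(safeDiv(nij / nObjJ, ifelse(ni == 0, Inf, ni / nObj)) - 1),
    INF5 = zs(safeDiv(safeDiv(nij, nj), ifelse(ni == 0, Inf, ni / N)) - 1),
    INF6 = nij / nObjJ - ni / nObj,
    INF7 = safeDiv(nij, nj) - ni / N)
}

# scalar integral criterion between one model column and one binary profile
.integralScalar <- function(Icol, L, s, G, integral) {
  if (integral == "info_sum") {
    d <- sum(abs(Icol))
    return(if (d == 0) 0 else 100 * sum(Icol[L > 0]) / d)
  }
  num <- sum(Icol[L > 0]) - s * mean(Icol)
  den <- sqrt(max(s - s^2 / G, 0) * max(sum(Icol^2) - sum(Icol)^2 / G, 0))
  if (den == 0) 0 else max(min(100 * num / den, 100), -100)
}

# subset a coded sample by object index, keeping class levels
.subsetSample <- function(sample, keep) {
  new("CodedSample", incidence = sample@incidence[keep, , drop = FALSE],
      classOf = sample@classOf[keep], scaleSet = sample@scaleSet)
}

#' Remove artifacts and retrain
#'
#' One or more passes of: train all nine models, pick the scoring model,
#' flag objects whose own-class similarity is below the threshold, remove
#' them, and rebuild the frequency matrix and all models from the survivors.
#' Stops when a pass flags nothing or \code{maxPasses} is reached.  If a
#' pass would empty a class gradation entirely, the pass is aborted with a
#' diagnostic and the state before that pass is returned.
#'
#' @param sample a [CodedSample-class].
#' @param threshold percent similarity threshold (default 12).
#' @param maxPasses maximum number of removal passes (default 1; the
#'   removal event is usually a single sweep).
#' @param modelCriterion criterion id used for scoring (default
#'   \code{"INF3"}, the chi-square model conventionally used as the current
#'   model for all heavy recognition work), or \code{"best"} to re-select
#'   the L1-best model each pass.  Under heavy class imbalance L1-selection
#'   on the uncleaned sample can prefer a raw-probability model whose
#'   columns correlate positively with every object and flag nothing, so
#'   the fixed chi-square scorer is the safer default for cleaning.
#' @param criterion integral criterion, as in [similarityScores()].
#' @param leaveOneOut leave-one-out scoring for flagging, as in
#'   [flagArtifacts()] (default TRUE).
#' @return list with \code{sample} (cleaned [CodedSample-class]),
#'   \code{log} (data.frame: \code{pass}, \code{object_id},
#'   \code{own_class_similarity}), \code{models} (all nine retrained on the
#'   cleaned sample), \code{best} (criterion id of the final L1-best
#'   model), and \code{aborted} (TRUE when a pass was aborted to avoid
#'   emptying a class).
#' @export
cleanAndRetrain <- function(sample, threshold = 12, maxPasses = 1L,
                            modelCriterion = "INF3",
                            criterion = c("correlation", "info_sum"),
                            leaveOneOut = TRUE) {
  stopifnot(is(sample, "CodedSample"))
  if (maxPasses < 1L) .stopf("maxPasses must be >= 1")
  criterion <- match.arg(criterion)
  if (!identical(modelCriterion, "best") &&
      !modelCriterion %in% modelCriteria())
    .stopf("modelCriterion must be 'best' or one of the nine criterion ids")
  cur <- sample
  log <- data.frame(pass = integer(), object_id = character(),
                    own_class_similarity = numeric(),
                    stringsAsFactors = FALSE)
  aborted <- FALSE
  pass <- 0L
  repeat {
    pass <- pass + 1L
    models <- buildAllModels(frequencyMatrix(cur))
    scorerId <- if (identical(modelCriterion, "best"))
      bestModel(selectBestModel(cur, models, criterion)) else modelCriterion
    flagged <- flagArtifacts(cur, models[[scorerId]], threshold, criterion,
                             leaveOneOut = leaveOneOut)
    if (nrow(flagged) == 0L) break
    keep <- !(objectIds(cur) %in% flagged$object_id)
    remaining <- table(cur@classOf[keep])
    if (any(remaining == 0L)) {
      .warnf("pass %d would empty class gradation(s) %s; pass aborted, returning the pre-removal state",
             pass,
             paste(names(remaining)[remaining == 0L], collapse = ", "))
      aborted <- TRUE
      break
    }
    log <- rbind(log, data.frame(pass = pass,
                                 object_id = flagged$object_id,
                                 own_class_similarity =
                                   flagged$own_class_similarity,
                                 stringsAsFactors = FALSE))
    cur <- .subsetSample(cur, keep)
    if (pass >= maxPasses) break
  }
  finalModels <- buildAllModels(frequencyMatrix(cur))
  finalBest <- bestModel(selectBestModel(cur, finalModels, criterion))
  list(sample = cur, log = log, models = finalModels, best = finalBest,
       aborted = aborted)
}

#' Export a removal log
#'
#' @param log the \code{log} component of [cleanAndRetrain()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRemovalLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
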