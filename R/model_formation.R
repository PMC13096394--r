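#' @include AllClasses.R AllGenerics.R
NULL

#' Criterion identifiers of the nine knowledge models
#'
#' Two raw-probability models (\code{PRC1}, \code{PRC2}) and seven
#' information-theoretic models (\code{INF1} ... \code{INF7}).  Identifiers
#' are explicit strings, never positional.
#'
#' @return character vector of the nine criterion ids.
#' @export
modelCriteria <- function() {
  c("PRC1", "PRC2", "INF1", "INF2", "INF3", "INF4", "INF5", "INF6", "INF7")
}

#' Compute the absolute frequency matrix
#'
#' Counts \eqn{N_{ij}}: the number of training objects of class \eqn{j}
#' whose incidence bit for descriptive gradation \eqn{i} is set.  This
#' matrix, with its margins and the per-class object counts, is the sole
#' substrate of all nine knowledge models.
#'
#' @param sample a [CodedSample-class] with at least two class gradations,
#'   each with at least one object.
#' @return a [FrequencyMatrix-class].
#' @examples
#' gen <- generateBioassay(nObjects = 60, nNumericScales = 2,
#'                         nTextScales = 3, activeRate = 0.2,
#'                         nInformative = 2, effectSize = 2, seed = 1)
#' sam <- codeObjects(gen$table, buildScales(gen$table))
#' frequencyMatrix(sam)
#' @export
frequencyMatrix <- function(sample) {
  stopifnot(is(sample, "CodedSample"))
  if (nrow(sample@incidence) == 0L) .stopf("sample is empty")
  cls <- sample@classOf
  if (nlevels(cls) < 2L) .stopf("at least two class gradations required")
  perClass <- table(cls)
  if (any(perClass == 0L))
    .stopf("class gradation(s) with zero objects: %s",
           paste(names(perClass)[perClass == 0L], collapse = ", "))
  # class indicator (objects x classes); crossprod gives gradations x classes
  ind <- Matrix::sparseMatrix(i = seq_along(cls), j = as.integer(cls), x = 1,
                              dims = c(length(cls), nlevels(cls)),
                              dimnames = list(NULL, levels(cls)))
  counts <- as.matrix(Matrix::crossprod(sample@incidence, ind))
  new("FrequencyMatrix", counts = counts,
      nObjPerClass = stats::setNames(as.numeric(perClass), levels(cls)),
      nObj = length(cls), scaleSet = sample@scaleSet)
}

# probability views, with the 0/0 -> 0 convention
.probViews <- function(freq) {
  Nij <- freq@counts
  Ni <- rowSums(Nij); Nj <- colSums(Nij); N <- sum(Nij)
  list(Nij = Nij, Ni = Ni, Nj = Nj, N = N,
       P1ij = sweep(Nij, 2, ifelse(Nj == 0, Inf, Nj), "/"),
       P2ij = sweep(Nij, 2, freq@nObjPerClass, "/"),
       P1i = if (N == 0) Ni * 0 else Ni / N,
       P2i = Ni / freq@nObj)
}

#' Build one knowledge model
#'
#' Computes the knowledge matrix \eqn{I_{ij}} for one criterion from a
#' [FrequencyMatrix-class].  With \eqn{P1_{ij} = N_{ij}/N_j},
#' \eqn{P2_{ij} = N_{ij}/N^{obj}_j}, \eqn{P1_i = N_i/N},
#' \eqn{P2_i = N_i/N^{obj}} and \eqn{\Psi = 1/\log_2 N^{obj}}:
#' \describe{
#'   \item{PRC1}{\eqn{I = P1_{ij}} (conditional percentage distribution).}
#'   \item{PRC2}{\eqn{I = P2_{ij}} (object-conditional distribution).}
#'   \item{INF1}{Kharkevich measure on the object base:
#'     \eqn{\Psi \log_2(P2_{ij}/P2_i)}.}
#'   \item{INF2}{Kharkevich measure on the frequency base:
#'     \eqn{\Psi \log_2(P1_{ij}/P1_i)}.}
#'   \item{INF3}{chi-square deviation, observed minus expected under
#'     feature-class independence: \eqn{N_{ij} - N_i N_j / N}.}
#'   \item{INF4}{ROI criterion, object base: \eqn{P2_{ij}/P2_i - 1}.}
#'   \item{INF5}{ROI criterion, frequency base: \eqn{P1_{ij}/P1_i - 1}.}
#'   \item{INF6}{probability difference, object base:
#'     \eqn{P2_{ij} - P2_i}.}
#'   \item{INF7}{probability difference, frequency base:
#'     \eqn{P1_{ij} - P1_i}.}
#' }
#' For the log- and ratio-based criteria (INF1, INF2, INF4, INF5) cells with
#' \eqn{N_{ij} = 0} are set to 0: absence of co-occurrence is read as no
#' knowledge, not as infinitely negative knowledge, keeping additive
#' recognition sums finite.
#'
#' @param freq a [FrequencyMatrix-class] with a positive grand total.
#' @param criterion one of [modelCriteria()].
#' @return a [KnowledgeModel-class].
#' @export
buildModel <- function(freq, criterion) {
  stopifnot(is(freq, "FrequencyMatrix"))
  if (!is.character(criterion) || length(criterion) != 1L ||
      !criterion %in% modelCriteria())
    .stopf("unknown criterion id: %s",
           paste(as.character(criterion), collapse = ","))
  if (sum(freq@counts) <= 0) .stopf("frequency matrix has zero grand total")
  if (freq@nObj < 2L)
    .stopf("at least two training objects required (Psi undefined)")
  v <- .probViews(freq)
  psi <- 1 / log2(freq@nObj)
  zeroSafe <- function(m) { m[v$Nij == 0] <- 0; m }
  ratio2 <- sweep(v$P2ij, 1, ifelse(v$P2i == 0, Inf, v$P2i), "/")
  ratio1 <- sweep(v$P1ij, 1, ifelse(v$P1i == 0, Inf, v$P1i), "/")
  I <- switch(criterion,
    PRC1 = v$P1ij,
    PRC2 = v$P2ij,
    INF1 = zeroSafe(psi * log2(ratio2)),
    INF2 = zeroSafe(psi * log2(ratio1)),
    INF3 = v$Nij - outer(v$Ni, v$Nj) / v$N,
    INF4 = zeroSafe(ratio2 - 1),
    INF5 = zeroSafe(ratio1 - 1),
    INF6 = v$P2ij - v$P2i,
    INF7 = v$P1ij - v$P1i)
  dimnames(I) <- dimnames(freq@counts)
  new("KnowledgeModel", criterion = criterion, values = I, psi = psi,
      scaleSet = freq@scaleSet,
      fingerprint = .fnv1a(c(dim(freq@counts), as.vector(freq@counts))))
}

#' Build all nine knowledge models
#'
#' @param freq a [FrequencyMatrix-class].
#' @return named list of nine [KnowledgeModel-class] objects, one per
#'   criterion in [modelCriteria()].
#' @export
buildAllModels <- function(freq) {
  ids <- modelCriteria()
  stats::setNames(lapply(ids, function(cr) buildModel(freq, cr)), ids)
}

#' Export a knowledge model as TSV plus JSON sidecar
#'
#' The matrix is written as a TSV with gradation rows labeled
#' \code{"scale::gradation"} and class columns labeled by class gradation;
#' the sidecar records the criterion, \eqn{\Psi} and the source fingerprint.
#'
#' @param model a [KnowledgeModel-class].
#' @param path TSV path; the sidecar is written at \code{paste0(path,
#'   ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "KnowledgeModel"))
  df <- data.frame(gradation = rownames(model@values),
                   model@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(criterion = model@criterion, psi = model@psi,
                            fingerprint = model@fingerprint),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a knowledge model written by [writeModel()]
#'
#' @param path TSV path (with its \code{.json} sidecar alongside).
#' @param scales the [ScaleSet-class] the model was trained on.
#' @return a [KnowledgeModel-class].
#' @export
readModel <- function(path, scales) {
  stopifnot(is(scales, "ScaleSet"))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gradation
  new("KnowledgeModel", criterion = meta$criterion, values = m,
      psi = meta$psi, scaleSet = scales,
      fingerprint = meta$fingerprint)
}
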