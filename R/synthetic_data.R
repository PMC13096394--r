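#' @include AllClasses.R AllGenerics.R
NULL

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.motifs <- c("NEG", "POS", "HBD", "HBA", "HYP", "ARO", "LIP")

#' Generate a synthetic bioassay descriptor table
#'
#' Emulates the statistical shape of a highly imbalanced screening set: a
#' few thousand objects, an active class around 1.4 percent, a couple of
#' hundred text (pharmacophore-code-like) descriptors and ~90 numeric
#' descriptors with heavy-tailed MW/PSA-like distributions, including one
#' binary blood-brain-barrier-style column.  Class association is planted
#' at the gradation level in spread units: an informative numeric
#' descriptor is location-shifted in actives by \code{effectSize} standard
#' deviations (realized as the exact discretized bin-mass shift, with the
#' top quantile bin designated; values are then drawn within bins, so the
#' pooled distribution stays log-normal and default equal-frequency coding
#' recovers the planted bins); an informative text descriptor moves
#' \code{effectSize} Bernoulli spreads of probability mass onto one
#' designated category in actives (capped at 0.97 so gradation
#' probabilities stay proper).  \code{labelNoiseCount} objects get flipped
#' class labels and are recorded as planted artifacts.
#'
#' The generated table stores every value pre-formatted as text in the same
#' dialect [readDescriptorTable()] parses, so in-memory use and a CSV
#' round trip code identically and identical seeds give byte-identical
#' tables.
#'
#' @param nObjects number of objects (default 3523).
#' @param nNumericScales numeric descriptor columns, including the binary
#'   BBB-style column (default 93).
#' @param nTextScales text descriptor columns (default 214).
#' @param activeRate active-class prevalence in (0, 1) (default 0.014;
#'   objects are drawn independently, so the realized active count is
#'   binomial around \code{nObjects * activeRate}).
#' @param nInformative number of descriptors carrying planted class
#'   association (default 10).
#' @param effectSize shift of the informative descriptors in actives, in
#'   units of spread (default 2; 0 means no planted structure).
#' @param labelNoiseCount number of objects whose class label is flipped
#'   after feature generation (default 0).
#' @param numericBins quantile bins the numeric effects are planted in
#'   (default 3, matching the [buildScales()] default).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return list with \code{table} (a [DescriptorTable-class]) and
#'   \code{truth} (a [SyntheticTruth-class]).
#' @examples
#' gen <- generateBioassay(nObjects = 200, nNumericScales = 5,
#'                         nTextScales = 10, activeRate = 0.1,
#'                         nInformative = 3, effectSize = 2, seed = 1)
#' table(gen$table@classLabels)
#' @export
generateBioassay <- function(nObjects = 3523L, nNumericScales = 93L,
                             nTextScales = 214L, activeRate = 0.014,
                             nInformative = 10L, effectSize = 2,
                             labelNoiseCount = 0L, numericBins = 3L,
                             seed = 42L) {
  if (nObjects < 2L) .stopf("nObjects must be >= 2")
  if (activeRate <= 0 || activeRate >= 1) .stopf("activeRate must lie in (0, 1)")
  if (effectSize < 0) .stopf("effectSize must be >= 0")
  if (nNumericScales < 1L) .stopf("need at least the binary BBB-style column")
  if (nInformative > nNumericScales - 1L + nTextScales)
    .stopf("nInformative exceeds the number of plantable descriptors")
  if (labelNoiseCount < 0L || labelNoiseCount > nObjects / 2)
    .stopf("labelNoiseCount must lie in [0, nObjects/2]")
  if (numericBins < 2L) .stopf("numericBins must be >= 2")
  .withSeed(seed, {
    active <- stats::runif(nObjects) < activeRate
    trueClass <- ifelse(active, "Active", "Inactive")

    numNames <- c("XlogP", "PSA", "NumRot", "NumHBD", "MW", "BadGroup",
                  if (nNumericScales > 7L)
                    paste0("NumD", seq_len(nNumericScales - 7L)))
    numNames <- c(utils::head(numNames, nNumericScales - 1L), "BBB")
    txtNames <- if (nTextScales > 0L) sprintf(
      "%s_no%d_%s", sample(.motifs, nTextScales, replace = TRUE),
      seq_len(nTextScales), sample(.motifs, nTextScales, replace = TRUE))
      else character()

    # plantable descriptors: everything except the binary BBB column
    candidates <- c(setdiff(numNames, "BBB"), txtNames)
    informative <- sample(candidates, nInformative)

    cols <- vector("list", nNumericScales + nTextScales)
    names(cols) <- c(numNames, txtNames)
    truthRows <- list()

    textProbs <- function(k) {
      # move effectSize Bernoulli spreads of mass onto the designated
      # category, capped so the distribution stays proper
      pA <- min(1 / k + effectSize * sqrt((1 / k) * (1 - 1 / k)), 0.97)
      c(pA, rep((1 - pA) / (k - 1), k - 1L))
    }

    for (nm in numNames) {
      if (nm == "BBB") {
        cols[[nm]] <- as.character(stats::rbinom(nObjects, 1L, 0.4))
        next
      }
      mu <- stats::runif(1, 2, 6); sg <- stats::runif(1, 0.3, 0.8)
      u <- stats::runif(nObjects)
      if (nm %in% informative) {
        B <- numericBins
        # discretized location shift by effectSize spreads: bin mass under
        # a +effectSize shift of the latent standard normal
        pr <- diff(stats::pnorm(stats::qnorm(seq(0, 1, length.out = B + 1L))
                                - effectSize))
        bin <- sample.int(B, sum(active), replace = TRUE, prob = pr)
        u[active] <- (bin - 1 + u[active]) / B
        truthRows[[length(truthRows) + 1L]] <-
          data.frame(scale = nm, kind = "numeric",
                     gradation = as.character(B), direction = 1,
                     stringsAsFactors = FALSE)
      }
      cols[[nm]] <- sprintf("%.6g", stats::qlnorm(u, mu, sg))
    }

    for (nm in txtNames) {
      k <- sample(3:6, 1L)
      lv <- paste0("g", seq_len(k))
      val <- lv[sample.int(k, nObjects, replace = TRUE)]
      if (nm %in% informative) {
        des <- sample.int(k, 1L)
        pr <- textProbs(k)
        probs <- rep(0, k); probs[des] <- pr[1L]
        probs[-des] <- pr[-1L]
        val[active] <- lv[sample.int(k, sum(active), replace = TRUE,
                                     prob = probs)]
        truthRows[[length(truthRows) + 1L]] <-
          data.frame(scale = nm, kind = "text", gradation = lv[des],
                     direction = 1, stringsAsFactors = FALSE)
      }
      cols[[nm]] <- val
    }

    observed <- trueClass
    artifactIds <- character()
    if (labelNoiseCount > 0L) {
      flip <- sample.int(nObjects, labelNoiseCount)
      observed[flip] <- ifelse(observed[flip] == "Active",
                               "Inactive", "Active")
      artifactIds <- paste0("S", flip)
    }

    ids <- paste0("S", seq_len(nObjects))
    data <- as.data.frame(cols, check.names = FALSE,
                          stringsAsFactors = FALSE)
    table <- new("DescriptorTable", objectIds = ids,
                 classLabels = observed, className = "Outcome",
                 idName = "id", data = data,
                 columnOrder = c("id", "Outcome", names(cols)))
    truthDf <- if (length(truthRows)) do.call(rbind, truthRows)
      else data.frame(scale = character(), kind = character(),
                      gradation = character(), direction = numeric(),
                      stringsAsFactors = FALSE)
    truth <- new("SyntheticTruth", seed = as.integer(seed),
                 informative = truthDf, activeRate = activeRate,
                 artifactIds = artifactIds,
                 params = list(nObjects = nObjects,
                               nNumericScales = nNumericScales,
                               nTextScales = nTextScales,
                               nInformative = nInformative,
                               effectSize = effectSize,
                               labelNoiseCount = labelNoiseCount,
                               numericBins = numericBins,
                               activeLabel = "Active"))
    list(table = table, truth = truth)
  })
}

#' Parameter-recovery report against planted ground truth
#'
#' Measures how well the fitted model recovers the generator's planted
#' structure: (a) the rank of each planted informative gradation in the
#' significance table, (b) the sign agreement between the planted effect
#' direction and the model's knowledge value for the active class, and (c)
#' the fraction of planted label-noise artifacts among the flagged ids, when
#' a flagged set is supplied.
#'
#' @param truth a [SyntheticTruth-class].
#' @param model a [KnowledgeModel-class] trained on the generated table.
#' @param significance the [SignificanceTable-class] of \code{model}.
#' @param flaggedIds object ids flagged by [flagArtifacts()] (optional).
#' @return list: \code{gradationRanks} (data.frame with \code{rank} and
#'   \code{topFraction} per planted gradation), \code{signAgreement},
#'   \code{artifactRecall} (NA when \code{flaggedIds} is missing),
#'   \code{nGradations}.
#' @export
truthRecoveryReport <- function(truth, model, significance,
                                flaggedIds = NULL) {
  stopifnot(is(truth, "SyntheticTruth"), is(model, "KnowledgeModel"),
            is(significance, "SignificanceTable"))
  grad <- gradationInfo(model)
  inf <- truth@informative
  ids <- character(nrow(inf))
  for (r in seq_len(nrow(inf))) {
    hit <- if (inf$kind[r] == "text")
      which(grad$scale == inf$scale[r] & grad$label == inf$gradation[r])
    else
      which(grad$scale == inf$scale[r] &
              grad$index == as.integer(inf$gradation[r]))
    if (length(hit) != 1L)
      .stopf("planted gradation %s of scale %s not found in the model; truth/model mismatch",
             inf$gradation[r], inf$scale[r])
    ids[r] <- grad$id[hit]
  }
  gdf <- significance@gradations
  rank <- match(ids, gdf$id)
  activeLabel <- truth@params$activeLabel
  if (!activeLabel %in% colnames(model@values))
    .stopf("active class '%s' not in the model", activeLabel)
  agree <- model@values[ids, activeLabel] * inf$direction > 0
  out <- data.frame(scale = inf$scale, gradation = inf$gradation,
                    id = ids, rank = rank,
                    topFraction = rank / nrow(gdf),
                    value = unname(model@values[ids, activeLabel]),
                    signAgree = unname(agree), stringsAsFactors = FALSE)
  recall <- if (is.null(flaggedIds)) NA_real_
    else if (length(truth@artifactIds) == 0L) NA_real_
    else mean(truth@artifactIds %in% flaggedIds)
  list(gradationRanks = out,
       signAgreement = if (nrow(out)) mean(out$signAgree) else NA_real_,
       artifactRecall = recall, nGradations = nrow(gdf))
}
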