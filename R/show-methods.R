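#' @include AllClasses.R AllGenerics.R
NULL

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d objects, %d descriptor columns\n",
              length(object@objectIds), ncol(object@data)))
  cat(sprintf("  class column '%s': %s\n", object@className,
              paste(sprintf("%s (%d)", names(table(object@classLabels)),
                            table(object@classLabels)), collapse = ", ")))
})

setMethod("show", "ScaleSet", function(object) {
  sc <- scaleCounts(object)
  cat(sprintf("ScaleSet: %d descriptive scales (%d text, %d numeric), %d gradations\n",
              length(object@scales), sc[["nText"]], sc[["nNumeric"]],
              sc[["nGradations"]]))
  cat(sprintf("  classification scale '%s': %s\n", object@classScale$name,
              paste(object@classScale$levels, collapse = ", ")))
})

setMethod("show", "CodedSample", function(object) {
  cat(sprintf("CodedSample: %d objects x %d gradations (%d bits set)\n",
              nrow(object@incidence), ncol(object@incidence),
              length(object@incidence@x)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s (%d)", levels(object@classOf),
                            table(object@classOf)), collapse = ", ")))
})

setMethod("show", "FrequencyMatrix", function(object) {
  cat(sprintf("FrequencyMatrix: %d gradations x %d classes, N = %d, %d objects\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              as.integer(object@nObj)))
})

setMethod("show", "KnowledgeModel", function(object) {
  v <- object@values
  cat(sprintf("KnowledgeModel %s: %d gradations x %d classes (Psi = %.4f)\n",
              object@criterion, nrow(v), ncol(v), object@psi))
  cat(sprintf("  I range [%.4g, %.4g], fingerprint %s\n",
              min(v), max(v), object@fingerprint))
})

setMethod("show", "RecognitionResult", function(object) {
  cat(sprintf("RecognitionResult (%s on %s): %d objects x %d classes\n",
              object@criterion, object@modelCriterion,
              nrow(object@similarity), ncol(object@similarity)))
  if (length(object@trueClass))
    cat(sprintf("  identification accuracy: %.3f%%\n",
                identificationAccuracy(object)))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("ReliabilityReport over %d model(s); best by L1: %s\n",
              nrow(object@table), object@best))
  print(object@table[, c("criterion", "F1", "L1", "accuracy")],
        row.names = FALSE, digits = 4)
})

setMethod("show", "SignificanceTable", function(object) {
  cat(sprintf("SignificanceTable (%s): %d gradations over %d scales\n",
              object@criterion, nrow(object@gradations),
              nrow(object@scales)))
})

setMethod("show", "SyntheticTruth", function(object) {
  p <- object@params
  cat(sprintf("SyntheticTruth (seed %d): %d objects, %d+%d scales, active rate %.4f\n",
              object@seed, p$nObjects, p$nTextScales, p$nNumericScales,
              object@activeRate))
  cat(sprintf("  %d informative gradations, %d planted artifacts, effect size %.2f\n",
              nrow(object@informative), length(object@artifactIds),
              p$effectSize))
})
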