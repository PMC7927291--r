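#' @rdname MultimodalDataset-class
#' @param x a \linkS4class{MultimodalDataset}
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname MultimodalDataset-class
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))
#' @rdname MultimodalDataset-class
#' @param modality modality tag; if missing, the full named list
#' @export
setGeneric("featureMatrix",
  function(x, modality) standardGeneric("featureMatrix"))
#' @rdname MultimodalDataset-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname MultimodalDataset-class
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname MultimodalDataset-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

setMethod("subjectIds", "MultimodalDataset", function(x) x@subjectIds)
setMethod("modalities", "MultimodalDataset", function(x) names(x@features))
setMethod("featureMatrix", "MultimodalDataset", function(x, modality) {
  if (missing(modality)) return(x@features)
  if (!modality %in% names(x@features))
    stop("unknown modality: ", modality)
  x@features[[modality]]
})
setMethod("scores", "MultimodalDataset",
  function(x) setNames(x@scores, x@subjectIds))
setMethod("plantedTruth", "MultimodalDataset", function(x) x@truth)
setMethod("nSubjects", "MultimodalDataset", function(x) length(x@subjectIds))

#' @rdname WeightMap-class
#' @param x a \linkS4class{WeightMap}
#' @export
setGeneric("voxelWeights", function(x) standardGeneric("voxelWeights"))
setMethod("voxelWeights", "WeightMap", function(x) x@voxelWeights)

#' @rdname RVRModel-class
#' @param object,x an \linkS4class{RVRModel}
#' @export
setGeneric("relevanceVectors", function(x) standardGeneric("relevanceVectors"))
setMethod("relevanceVectors", "RVRModel",
  function(x) x@activeSet[x@activeSet > 0L])

setMethod("show", "MultimodalDataset", function(object) {
  cat("MultimodalDataset:", length(object@subjectIds), "subjects\n")
  for (m in names(object@features))
    cat(sprintf("  %-6s %d voxels\n", m, ncol(object@features[[m]])))
  cat("  scores: [", sprintf("%.3g", min(object@scores)), ",",
      sprintf("%.3g", max(object@scores)), "]",
      if (!is.null(object@truth)) " (planted truth attached)", "\n", sep = "")
})

setMethod("show", "RVRModel", function(object) {
  cat(sprintf(
    "RVRModel (%s basis): %d active of %d basis functions, sigma^2 = %.4g\n",
    object@basis, length(object@activeSet),
    length(object@activeSet) + length(object@prunedAlpha), object@noiseVar))
  cat(sprintf("  converged: %s after %d iterations\n",
    object@converged, object@iterations))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: r = %.3f, MAE = %.3f (%s, %d subjects)\n",
    object@modelId, object@r, object@mae,
    object@scheme$kind, length(object@observed)))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "Steiger T2 = %.3f, df = %d, one-sided p (upper) = %.3g, P(T>|T2|) = %.3g\n",
    object@t2, as.integer(object@df), object@pUpper, object@pAbsUpper))
})

setMethod("show", "ExclusionReport", function(object) {
  cat(sprintf("ExclusionReport: %d in, %d excluded (%d overlap), %d included\n",
    object@nInput, length(object@excludedIds), object@nOverlap,
    object@nIncluded))
  for (r in names(object@countsPerReason))
    cat(sprintf("  %-22s %d\n", r, object@countsPerReason[[r]]))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed r = %.3f, p = %.4g (smoothed %.4g), %d perms\n",
    object@observedR, object@pValue, object@pSmoothed, length(object@nullR)))
})

setMethod("show", "WeightMap", function(object) {
  cat(sprintf("WeightMap [%s]: %d voxels, %d nonzero, averaged over %d folds\n",
    object@modalityTag, length(object@voxelWeights),
    sum(object@voxelWeights != 0), object@nFolds))
})
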