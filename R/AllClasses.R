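#' @import methods
#' @importFrom stats cor pt sd rnorm runif var quantile setNames
#' @importFrom utils head read.delim write.table packageVersion
#' @useDynLib rvrfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Atlas labels: voxel -> node -> network
#'
#' A two-level parcellation of a 1-D voxel space: every voxel belongs to
#' exactly one node, every node to exactly one network. Stands in for
#' region/network atlases (e.g. a 268-node functional parcellation grouped
#' into large-scale networks, or a white-matter tract atlas) when aggregating
#' voxel-wise discriminative weights.
#'
#' @slot voxelNode integer vector, one node id (1-based) per voxel.
#' @slot nodeNetwork integer vector, one network id per node.
#' @slot nodeNames,networkNames character labels.
#' @export
setClass("AtlasLabels",
  representation(
    voxelNode = "integer",
    nodeNetwork = "integer",
    nodeNames = "character",
    networkNames = "character"
  )
)

setValidity("AtlasLabels", function(object) {
  nNodes <- length(object@nodeNetwork)
  if (length(object@voxelNode) == 0L) return("atlas covers no voxels")
  if (any(is.na(object@voxelNode))) return("voxelNode contains NA")
  if (min(object@voxelNode) < 1L || max(object@voxelNode) > nNodes)
    return("voxelNode ids outside 1..nNodes")
  if (!all(seq_len(nNodes) %in% object@voxelNode))
    return("empty node: every node must own at least one voxel")
  if (any(object@nodeNetwork < 1L))
    return("nodeNetwork ids must be >= 1")
  if (length(object@nodeNames) != nNodes)
    return("nodeNames length must equal number of nodes")
  TRUE
})

#' Planted ground truth of a synthetic dataset
#'
#' Records everything needed to recompute the noise-free generative score
#' from the feature matrices: per-modality voxel weight maps (zero outside
#' the planted clusters), the per-subject latent draws, the generative
#' intercept, and the affine map that rescales the raw linear predictor into
#' the behavioural score range.
#'
#' @slot weightMaps named list of numeric vectors, one per modality.
#' @slot latentScore numeric, the raw (pre-rescaling) linear predictor plus
#'   score noise, one value per subject.
#' @slot intercept numeric(1), generative intercept on the raw scale.
#' @slot affine numeric(2) \code{c(a, b)}: observed score = a * raw + b.
#' @slot scoreNoise numeric, the per-subject score residual actually drawn.
#' @export
setClass("PlantedTruth",
  representation(
    weightMaps = "list",
    latentScore = "numeric",
    intercept = "numeric",
    affine = "numeric",
    scoreNoise = "numeric"
  )
)

setValidity("PlantedTruth", function(object) {
  if (length(object@affine) != 2L) return("affine must be c(a, b)")
  if (!all(vapply(object@weightMaps, is.numeric, logical(1))))
    return("weightMaps must be numeric vectors")
  TRUE
})

setClassUnion("PlantedTruthOrNULL", c("PlantedTruth", "NULL"))
setClassUnion("AtlasOrNULL", c("AtlasLabels", "NULL"))

#' Multimodal voxel-wise feature container
#'
#' Holds subjects-by-voxels feature matrices for one or more imaging
#' modalities together with the behavioural score of each subject. All
#' modalities share an identical subject order; alignment is by subject id,
#' never by position alone. Optionally carries the planted ground truth
#' (synthetic data) and a toy atlas.
#'
#' @slot subjectIds character vector of unique subject identifiers.
#' @slot features named list of numeric matrices (subjects x voxels).
#' @slot scores numeric vector, one behavioural score per subject.
#' @slot truth \linkS4class{PlantedTruth} or NULL.
#' @slot atlas named list of \linkS4class{AtlasLabels} (per modality), or NULL.
#' @export
setClass("MultimodalDataset",
  representation(
    subjectIds = "character",
    features = "list",
    scores = "numeric",
    truth = "PlantedTruthOrNULL",
    atlas = "listOrNULL"
  )
)

setValidity("MultimodalDataset", function(object) {
  n <- length(object@subjectIds)
  if (anyDuplicated(object@subjectIds)) return("duplicate subject ids")
  if (length(object@scores) != n) return("scores length != number of subjects")
  if (anyNA(object@scores)) return("scores contain missing values")
  if (length(object@features) == 0L) return("at least one modality required")
  if (is.null(names(object@features)) || any(names(object@features) == ""))
    return("features list must be named by modality tag")
  for (m in names(object@features)) {
    X <- object@features[[m]]
    if (!is.matrix(X) || !is.numeric(X))
      return(sprintf("features[[%s]] must be a numeric matrix", m))
    if (nrow(X) != n)
      return(sprintf("features[[%s]] has %d rows, expected %d", m, nrow(X), n))
    if (anyNA(X)) return(sprintf("features[[%s]] contains missing values", m))
  }
  TRUE
})

#' Synthetic resting-state time series with motion traces
#'
#' @slot series list of (timepoints x voxels) matrices, one per subject.
#' @slot trSeconds numeric(1), sampling interval (TR) in seconds.
#' @slot motion list of (timepoints x 6) matrices (3 translations mm,
#'   3 rotations rad), one per subject.
#' @export
setClass("TimeSeriesSet",
  representation(
    series = "list",
    trSeconds = "numeric",
    motion = "list"
  )
)

setValidity("TimeSeriesSet", function(object) {
  if (object@trSeconds <= 0) return("trSeconds must be > 0")
  if (length(object@series) != length(object@motion))
    return("series and motion must have one entry per subject")
  for (i in seq_along(object@series)) {
    if (nrow(object@series[[i]]) < 8L) return("need >= 8 timepoints")
    if (!identical(nrow(object@series[[i]]), nrow(object@motion[[i]])))
      return("motion rows must match series timepoints")
    if (ncol(object@motion[[i]]) != 6L) return("motion must have 6 columns")
  }
  TRUE
})

#' Exclusion bookkeeping report
#'
#' Summarises which subjects survive quality-control exclusion: per-reason
#' counts, the size of the overlap between reasons, and the included roster.
#' A subject is excluded iff it carries at least one flag; the union is
#' counted once.
#'
#' @slot nInput integer(1) subjects entering QC.
#' @slot countsPerReason named integer vector of per-flag counts.
#' @slot nOverlap integer(1), (sum of counts) minus (distinct flagged).
#' @slot includedIds,excludedIds character vectors.
#' @slot nIncluded integer(1).
#' @export
setClass("ExclusionReport",
  representation(
    nInput = "integer",
    countsPerReason = "integer",
    nOverlap = "integer",
    includedIds = "character",
    excludedIds = "character",
    nIncluded = "integer"
  )
)

setValidity("ExclusionReport", function(object) {
  if (object@nIncluded != object@nInput - length(object@excludedIds))
    return("nIncluded must equal nInput minus distinct excluded subjects")
  if (object@nIncluded != length(object@includedIds))
    return("nIncluded must equal length(includedIds)")
  TRUE
})

#' Fitted relevance vector regression model
#'
#' Sparse Bayesian linear regression in either a linear-kernel-on-samples
#' basis (design K = X X' plus a bias column) or a primal-features basis.
#' Per-basis precisions alpha are optimised by evidence maximisation;
#' diverging precisions prune their basis functions, leaving the relevance
#' vectors in \code{activeSet}.
#'
#' @slot basis "kernel", "primal" or "intercept" (degenerate response).
#' @slot alpha numeric, precisions of the active basis functions (bias first
#'   when present).
#' @slot mu numeric, posterior mean weights over active basis functions.
#' @slot sigmaPosterior matrix, posterior covariance over active weights.
#' @slot noiseVar numeric(1), noise variance sigma^2.
#' @slot activeSet integer, retained basis indices (0 marks the bias; for
#'   the kernel basis positive entries index training samples, for the primal
#'   basis they index features).
#' @slot trainReference matrix, the training rows needed for kernel
#'   prediction (rows = active samples), or a 0-row matrix in primal mode.
#' @slot nFeatures integer(1), expected column count of prediction inputs.
#' @slot converged logical(1); @slot iterations integer(1).
#' @slot prunedAlpha numeric, named log10 precision at which each pruned
#'   basis left the model (bookkeeping only).
#' @export
setClass("RVRModel",
  representation(
    basis = "character",
    alpha = "numeric",
    mu = "numeric",
    sigmaPosterior = "matrix",
    noiseVar = "numeric",
    activeSet = "integer",
    trainReference = "matrix",
    nFeatures = "integer",
    converged = "logical",
    iterations = "integer",
    prunedAlpha = "numeric"
  )
)

setValidity("RVRModel", function(object) {
  if (!object@basis %in% c("kernel", "primal", "intercept"))
    return("basis must be 'kernel', 'primal' or 'intercept'")
  if (object@noiseVar <= 0) return("noiseVar must be > 0")
  if (any(object@alpha <= 0)) return("alpha must be positive on the active set")
  if (length(object@mu) != length(object@activeSet))
    return("mu and activeSet lengths differ")
  d <- dim(object@sigmaPosterior)
  if (d[1] != d[2] || d[1] != length(object@mu))
    return("sigmaPosterior must be square, matching length(mu)")
  TRUE
})

#' Cross-validated prediction result for one model combination
#'
#' Out-of-fold predictions for a mono- or multi-modality model, with the
#' Pearson correlation and mean absolute error between observed and
#' predicted scores. For repeated k-fold schemes, \code{predicted} holds one
#' column per repeat and \code{perRepeat} the per-repeat r and MAE; \code{r}
#' and \code{mae} are then means across repeats.
#'
#' @slot modelId character(1), e.g. "alff+gmv+fa".
#' @slot predicted matrix (subjects x repeats) of out-of-fold predictions.
#' @slot observed numeric, observed scores in subject order.
#' @slot r,mae numeric(1).
#' @slot nSelectedMean named numeric, per-modality mean selected-feature
#'   count across folds (and repeats).
#' @slot perRepeat data.frame with columns repeat_id, r, mae.
#' @slot scheme list describing the cross-validation scheme.
#' @export
setClass("CVResult",
  representation(
    modelId = "character",
    predicted = "matrix",
    observed = "numeric",
    r = "numeric",
    mae = "numeric",
    nSelectedMean = "numeric",
    perRepeat = "data.frame",
    scheme = "list"
  )
)

setValidity("CVResult", function(object) {
  if (nrow(object@predicted) != length(object@observed))
    return("predicted rows must match observed length")
  if (!is.na(object@mae) && object@mae < 0) return("mae must be >= 0")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12) return("r outside [-1, 1]")
  TRUE
})

#' Permutation-test result for prediction accuracy
#'
#' @slot observedR numeric(1), out-of-fold r of the unpermuted pipeline.
#' @slot nullR numeric(nPerm), r from full pipeline re-runs on shuffled
#'   scores (selection re-done inside every fold).
#' @slot pValue numeric(1), #\{null > observed\}/nPerm (strict inequality).
#' @slot pSmoothed numeric(1), (#\{null >= observed\} + 1)/(nPerm + 1).
#' @slot seed integer(1).
#' @export
setClass("PermutationResult",
  representation(
    observedR = "numeric",
    nullR = "numeric",
    pValue = "numeric",
    pSmoothed = "numeric",
    seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0, 1]")
  TRUE
})

#' Steiger dependent-correlation test result
#'
#' T2 statistic for the difference between two correlations r12 = cor(y, a)
#' and r13 = cor(y, b) that share the variable y, accounting for
#' r23 = cor(a, b), with df = n - 3.
#'
#' @slot t2 numeric(1) test statistic.
#' @slot df numeric(1) degrees of freedom, n - 3.
#' @slot pUpper numeric(1) P(T > t2); @slot pLower numeric(1) P(T < t2).
#' @slot pAbsUpper numeric(1) P(T > |t2|), the tail used when reporting a
#'   one-sided p against the better-fitting model irrespective of direction.
#' @slot r12,r13,r23 numeric(1) input correlations; @slot n numeric(1).
#' @export
setClass("SteigerResult",
  representation(
    t2 = "numeric", df = "numeric",
    pUpper = "numeric", pLower = "numeric", pAbsUpper = "numeric",
    r12 = "numeric", r13 = "numeric", r23 = "numeric", n = "numeric"
  )
)

setValidity("SteigerResult", function(object) {
  if (object@df < 1) return("df must be >= 1")
  if (object@pUpper < 0 || object@pUpper > 1) return("pUpper outside [0, 1]")
  TRUE
})

#' Fold-averaged voxel-space discriminative weight map
#'
#' @slot voxelWeights numeric over the full modality voxel space (zeros at
#'   voxels never selected).
#' @slot modalityTag character(1).
#' @slot nFolds integer(1) folds averaged.
#' @export
setClass("WeightMap",
  representation(
    voxelWeights = "numeric",
    modalityTag = "character",
    nFolds = "integer"
  )
)

setValidity("WeightMap", function(object) {
  if (any(!is.finite(object@voxelWeights))) return("weights must be finite")
  if (object@nFolds < 1L) return("nFolds must be >= 1")
  TRUE
})
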