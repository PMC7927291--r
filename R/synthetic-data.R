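#' Configuration for the synthetic multimodal generator
#'
#' Describes a synthetic cohort: per-modality voxel counts, how many voxels
#' carry true signal and how wide their contiguous clusters are, how much of
#' the latent signal is shared across modalities (collinearity between
#' modalities), feature- and score-level noise, and the behavioural score
#' range. The generator plants a forward linear model: features are drawn
#' first, scores are computed from the features, so mass-univariate selection
#' and regression have an exact ground truth.
#'
#' @param nSubjects number of subjects.
#' @param voxelsPerModality named integer vector, voxels per modality tag.
#' @param nTrueVoxels scalar or named vector, signal-carrying voxels per
#'   modality.
#' @param sharedSignalFraction fraction in \[0, 1\] of each modality's latent
#'   signal variance that is common across modalities.
#' @param noiseSd scalar or named per-modality SD of the independent feature
#'   noise added on top of the latent component.
#' @param scoreNoiseSd SD of the residual added to the raw score, or NULL to
#'   set it equal to the SD of the linear predictor (planted R^2 = 0.5).
#' @param scoreRange length-2 numeric, the affine target range of the
#'   observed behavioural score (default 0–4, a working-memory capacity
#'   scale).
#' @param clusterWidth voxels per contiguous true-weight cluster (1-D
#'   adjacency). Each cluster carries a single weight sign; signs alternate
#'   across clusters.
#' @param seed integer RNG seed.
#' @return a list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nSubjects = 200L,
                            voxelsPerModality = c(alff = 500L, gmv = 500L,
                                                  fa = 500L),
                            nTrueVoxels = 10L,
                            sharedSignalFraction = 0.5,
                            noiseSd = 1,
                            scoreNoiseSd = NULL,
                            scoreRange = c(0, 4),
                            clusterWidth = 5L,
                            seed = 1L) {
  tags <- names(voxelsPerModality)
  if (is.null(tags) || any(tags == ""))
    stop("voxelsPerModality must be named by modality tag")
  nTrueVoxels <- perModality(nTrueVoxels, tags, "nTrueVoxels")
  noiseSd <- perModality(noiseSd, tags, "noiseSd")
  if (any(nTrueVoxels > voxelsPerModality))
    stop("nTrueVoxels exceeds voxelsPerModality for: ",
         paste(tags[nTrueVoxels > voxelsPerModality], collapse = ", "))
  if (sharedSignalFraction < 0 || sharedSignalFraction > 1)
    stop("sharedSignalFraction must lie in [0, 1]")
  if (any(noiseSd < 0)) stop("noiseSd must be >= 0")
  if (clusterWidth < 1L) stop("clusterWidth must be >= 1")
  if (any(clusterWidth > voxelsPerModality))
    stop("clusterWidth exceeds voxel count for: ",
         paste(tags[clusterWidth > voxelsPerModality], collapse = ", "))
  if (length(scoreRange) != 2L || scoreRange[2] <= scoreRange[1])
    stop("scoreRange must be c(min, max) with min < max")
  structure(list(
    nSubjects = as.integer(nSubjects),
    voxelsPerModality = voxelsPerModality,
    nTrueVoxels = setNames(as.integer(nTrueVoxels), tags),
    sharedSignalFraction = sharedSignalFraction,
    noiseSd = noiseSd,
    scoreNoiseSd = scoreNoiseSd,
    scoreRange = as.numeric(scoreRange),
    clusterWidth = as.integer(clusterWidth),
    seed = as.integer(seed)
  ), class = "SyntheticConfig")
}

# Contiguous cluster layout for one modality: voxel indices and per-voxel
# sign, clusters evenly spread over the voxel axis, signs alternating.
clusterLayout <- function(nVoxels, nTrue, clusterWidth) {
  if (nTrue == 0L)
    return(list(idx = integer(0), sign = numeric(0)))
  nClusters <- ceiling(nTrue / clusterWidth)
  starts <- floor((seq_len(nClusters) - 1L) * nVoxels / nClusters) + 1L
  idx <- integer(0); sgn <- numeric(0)
  left <- nTrue
  for (j in seq_len(nClusters)) {
    w <- min(clusterWidth, left)
    idx <- c(idx, starts[j]:(starts[j] + w - 1L))
    sgn <- c(sgn, rep(if (j %% 2L == 1L) 1 else -1, w))
    left <- left - w
  }
  if (max(idx) > nVoxels || anyDuplicated(idx))
    stop("cluster layout infeasible: clusters overlap or exceed voxel count")
  list(idx = idx, sign = sgn)
}

#' Generate a synthetic multimodal dataset with planted ground truth
#'
#' Draws a common latent g and per-modality latents h_m (all standard
#' normal), forms each modality's signal driver
#' L_m = sqrt(f) g + sqrt(1-f) h_m with f = sharedSignalFraction, and sets
#' each true voxel to (cluster sign) * L_m plus independent N(0, noiseSd^2)
#' noise. Null voxels are pure noise with matched marginal variance. The raw
#' score is the forward linear model sum_m X_m w_m + intercept + eps with
#' planted weights w_v = sign_v / nTrueVoxels\[m\]; observed scores are an
#' affine rescaling of the raw score into \code{scoreRange}, with the affine
#' coefficients recorded in the returned truth so linear-model recovery
#' stays exact.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{MultimodalDataset} with \code{truth} populated.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, {
    n <- config$nSubjects
    tags <- names(config$voxelsPerModality)
    f <- config$sharedSignalFraction
    g <- rnorm(n)
    features <- list()
    weightMaps <- list()
    lin <- numeric(n)
    for (m in tags) {
      p <- config$voxelsPerModality[[m]]
      h <- rnorm(n)
      L <- sqrt(f) * g + sqrt(1 - f) * h
      lay <- clusterLayout(p, config$nTrueVoxels[[m]], config$clusterWidth)
      sdNoise <- config$noiseSd[[m]]
      # null voxels get sd matching the structured columns' marginal SD
      X <- matrix(rnorm(n * p, sd = sqrt(1 + sdNoise^2)), n, p)
      if (length(lay$idx))
        X[, lay$idx] <- outer(L, lay$sign) +
          matrix(rnorm(n * length(lay$idx), sd = sdNoise),
                 n, length(lay$idx))
      w <- numeric(p)
      if (length(lay$idx)) w[lay$idx] <- lay$sign / config$nTrueVoxels[[m]]
      features[[m]] <- X
      weightMaps[[m]] <- w
      lin <- lin + as.numeric(X %*% w)
    }
    intercept <- 0
    sNoise <- config$scoreNoiseSd
    if (is.null(sNoise)) sNoise <- stats::sd(lin)
    eps <- if (sNoise > 0) rnorm(n, sd = sNoise) else numeric(n)
    raw <- lin + intercept + eps
    rng <- range(raw)
    if (diff(rng) > 0) {
      a <- diff(config$scoreRange) / diff(rng)
      b <- config$scoreRange[1] - a * rng[1]
    } else {
      a <- 1; b <- mean(config$scoreRange) - rng[1]
    }
    ids <- sprintf("sub-%04d", seq_len(n))
    rownames(features[[1]]) <- NULL
    truth <- new("PlantedTruth", weightMaps = weightMaps, latentScore = raw,
                 intercept = intercept, affine = c(a, b), scoreNoise = eps)
    new("MultimodalDataset", subjectIds = ids, features = features,
        scores = a * raw + b, truth = truth, atlas = NULL)
  })
}

#' Generate band-limited synthetic resting-state time series
#'
#' Each voxel's series is the sum of the requested sinusoids plus white
#' noise; motion traces are Gaussian random walks in the six rigid-body
#' parameters (translations in mm, rotations in radians).
#'
#' @param nSubjects,timepoints,voxels dimensions; timepoints >= 8.
#' @param trSeconds sampling interval in seconds.
#' @param bandComponents data.frame with columns \code{freq} (Hz) and
#'   \code{amplitude}, or NULL for pure noise. Frequencies must lie below
#'   Nyquist, 1/(2 TR).
#' @param noiseSd white-noise SD added to every voxel series.
#' @param motionStepSd length-2 numeric: random-walk step SD for
#'   translations (mm) and rotations (rad).
#' @param seed integer RNG seed.
#' @return a \linkS4class{TimeSeriesSet}.
#' @export
generateTimeSeries <- function(nSubjects = 1L, timepoints = 200L,
                               voxels = 10L, trSeconds = 2,
                               bandComponents = NULL, noiseSd = 0,
                               motionStepSd = c(0.02, 2e-4), seed = 1L) {
  if (timepoints < 8L) stop("timepoints must be >= 8")
  assertScalarNumber(trSeconds, "trSeconds", positive = TRUE)
  nyquist <- 1 / (2 * trSeconds)
  if (!is.null(bandComponents)) {
    bandComponents <- as.data.frame(bandComponents)
    if (!all(c("freq", "amplitude") %in% names(bandComponents)))
      stop("bandComponents needs columns 'freq' and 'amplitude'")
    if (any(bandComponents$freq >= nyquist))
      stop(sprintf("component frequency >= Nyquist (%.4g Hz)", nyquist))
  }
  withSeed(seed, {
    tGrid <- (seq_len(timepoints) - 1L) * trSeconds
    base <- numeric(timepoints)
    if (!is.null(bandComponents) && nrow(bandComponents) > 0)
      for (k in seq_len(nrow(bandComponents)))
        base <- base + bandComponents$amplitude[k] *
          sin(2 * pi * bandComponents$freq[k] * tGrid)
    series <- vector("list", nSubjects)
    motion <- vector("list", nSubjects)
    for (s in seq_len(nSubjects)) {
      noise <- if (noiseSd > 0)
        matrix(rnorm(timepoints * voxels, sd = noiseSd), timepoints, voxels)
      else matrix(0, timepoints, voxels)
      series[[s]] <- matrix(base, timepoints, voxels) + noise
      stepSd <- rep(motionStepSd, each = 3L)
      motion[[s]] <- vapply(stepSd, function(sdj)
        cumsum(rnorm(timepoints, sd = sdj)), numeric(timepoints))
    }
    new("TimeSeriesSet", series = series, trSeconds = trSeconds,
        motion = motion)
  })
}

#' Generate a quality-control exclusion roster
#'
#' Produces a wide roster: one row per subject, one logical column per
#' exclusion flag, with exactly the requested number of subjects carrying
#' each flag and the requested pairwise overlaps between flags (unspecified
#' pairs are disjoint).
#'
#' @param nTotal total subjects.
#' @param countsPerFlag named integer vector, subjects carrying each flag.
#' @param overlapSpec NULL, or a data.frame with columns \code{flag1},
#'   \code{flag2}, \code{n} giving required pairwise overlap counts.
#' @param seed integer RNG seed (controls which subjects are flagged).
#' @return data.frame with \code{subject_id} plus one logical column per
#'   flag.
#' @export
generateRoster <- function(nTotal, countsPerFlag, overlapSpec = NULL,
                           seed = 1L) {
  flags <- names(countsPerFlag)
  if (is.null(flags) || any(flags == ""))
    stop("countsPerFlag must be named")
  counts <- as.integer(countsPerFlag)
  names(counts) <- flags
  overlapWith <- setNames(integer(length(flags)), flags)
  pairs <- list()
  if (!is.null(overlapSpec) && nrow(overlapSpec) > 0) {
    for (k in seq_len(nrow(overlapSpec))) {
      f1 <- as.character(overlapSpec$flag1[k])
      f2 <- as.character(overlapSpec$flag2[k])
      nk <- as.integer(overlapSpec$n[k])
      if (!f1 %in% flags || !f2 %in% flags)
        stop("overlapSpec names a flag absent from countsPerFlag")
      overlapWith[f1] <- overlapWith[f1] + nk
      overlapWith[f2] <- overlapWith[f2] + nk
      pairs[[k]] <- list(f1 = f1, f2 = f2, n = nk)
    }
  }
  singles <- counts - overlapWith
  if (any(singles < 0))
    stop("infeasible overlap: requested overlaps exceed flag count for ",
         paste(flags[singles < 0], collapse = ", "))
  nFlagged <- sum(singles) + sum(vapply(pairs, `[[`, integer(1), "n"))
  if (nFlagged > nTotal)
    stop("infeasible roster: ", nFlagged, " flagged subjects > nTotal")
  withSeed(seed, {
    ids <- sprintf("sub-%04d", seq_len(nTotal))
    roster <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    for (f in flags) roster[[f]] <- FALSE
    pool <- sample.int(nTotal, nFlagged)
    cursor <- 0L
    take <- function(k) {
      out <- pool[cursor + seq_len(k)]
      cursor <<- cursor + k
      out
    }
    for (pr in pairs) {
      i <- take(pr$n)
      roster[[pr$f1]][i] <- TRUE
      roster[[pr$f2]][i] <- TRUE
    }
    for (f in flags) if (singles[[f]] > 0)
      roster[[f]][take(singles[[f]])] <- TRUE
    roster
  })
}

#' Generate a toy two-level atlas over a 1-D voxel space
#'
#' Partitions the voxel axis into contiguous nodes (random sizes, every node
#' non-empty) and assigns every node to a network, each network guaranteed
#' at least one node.
#'
#' @param nVoxels,nNodes,nNetworks partition sizes;
#'   nNetworks <= nNodes <= nVoxels.
#' @param seed integer RNG seed.
#' @return an \linkS4class{AtlasLabels}.
#' @export
generateAtlas <- function(nVoxels, nNodes, nNetworks = 1L, seed = 1L) {
  if (nNodes > nVoxels) stop("impossible partition: nNodes > nVoxels")
  if (nNetworks > nNodes) stop("impossible partition: nNetworks > nNodes")
  withSeed(seed, {
    extra <- nVoxels - nNodes
    sizes <- rep(1L, nNodes)
    if (extra > 0) {
      add <- tabulate(sample.int(nNodes, extra, replace = TRUE), nNodes)
      sizes <- sizes + add
    }
    voxelNode <- rep(seq_len(nNodes), times = sizes)
    nodeNetwork <- c(seq_len(nNetworks),
                     if (nNodes > nNetworks)
                       sample.int(nNetworks, nNodes - nNetworks,
                                  replace = TRUE))
    # permuting preserves the multiset, so every network keeps >= 1 node
    nodeNetwork <- nodeNetwork[sample.int(nNodes)]
    new("AtlasLabels",
        voxelNode = as.integer(voxelNode),
        nodeNetwork = as.integer(nodeNetwork),
        nodeNames = sprintf("node%03d", seq_len(nNodes)),
        networkNames = sprintf("network%d", seq_len(nNetworks)))
  })
}
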