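# Small dataset builders shared across test files.

tinyDataset <- function(n = 60L, voxels = c(a = 100L, b = 100L),
                        nTrue = 6L, noiseSd = 0.5, scoreNoiseSd = NULL,
                        seed = 1L, ...) {
  generateDataset(syntheticConfig(
    nSubjects = n, voxelsPerModality = voxels, nTrueVoxels = nTrue,
    noiseSd = noiseSd, scoreNoiseSd = scoreNoiseSd, seed = seed, ...))
}

# Null cohort: no planted signal anywhere, scores are pure noise.
nullDataset <- function(n = 60L, voxels = c(x = 200L), seed = 1L) {
  generateDataset(syntheticConfig(
    nSubjects = n, voxelsPerModality = voxels, nTrueVoxels = 0L,
    scoreNoiseSd = 1, seed = seed))
}

# Reconstruct observed scores from the planted truth (independent oracle
# for the generative identity).
truthScores <- function(dataset) {
  tr <- plantedTruth(dataset)
  lin <- Reduce(`+`, lapply(modalities(dataset), function(m)
    as.numeric(featureMatrix(dataset, m) %*% tr@weightMaps[[m]])))
  tr@affine[1] * (lin + tr@intercept + tr@scoreNoise) + tr@affine[2]
}
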