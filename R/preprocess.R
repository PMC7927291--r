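#' Apply exclusion flags to a quality-control roster
#'
#' A subject is excluded iff it carries at least one flag; subjects carrying
#' several flags are counted once in the exclusion union but appear in every
#' per-reason count, mirroring the usual QC bookkeeping of large imaging
#' cohorts.
#'
#' @param roster data.frame with a \code{subject_id} column and one logical
#'   column per exclusion flag (as from \code{\link{generateRoster}}).
#' @return an \linkS4class{ExclusionReport}.
#' @export
applyExclusions <- function(roster) {
  if (!is.data.frame(roster) || nrow(roster) == 0L)
    stop("roster must be a non-empty data.frame")
  if (!"subject_id" %in% names(roster))
    stop("roster needs a subject_id column")
  if (anyDuplicated(roster$subject_id))
    stop("duplicate subject_id in roster: ",
         paste(unique(roster$subject_id[duplicated(roster$subject_id)]),
               collapse = ", "))
  flagCols <- setdiff(names(roster), "subject_id")
  flagCols <- flagCols[vapply(roster[flagCols], is.logical, logical(1))]
  counts <- vapply(roster[flagCols], sum, integer(1))
  excluded <- if (length(flagCols))
    Reduce(`|`, roster[flagCols]) else rep(FALSE, nrow(roster))
  nOverlap <- as.integer(sum(counts) - sum(excluded))
  new("ExclusionReport",
      nInput = nrow(roster),
      countsPerReason = counts,
      nOverlap = nOverlap,
      includedIds = roster$subject_id[!excluded],
      excludedIds = roster$subject_id[excluded],
      nIncluded = as.integer(sum(!excluded)))
}

#' Expand six rigid-body motion parameters to the Friston 24 set
#'
#' Columns are ordered \[R, R^2, R_\{t-1\}, R_\{t-1\}^2\]: the six parameters,
#' their squares, the one-volume-lagged parameters, and the squared lags.
#' The first row of the lagged blocks is zero-padded.
#'
#' @param motion numeric matrix, timepoints x 6.
#' @return numeric matrix, timepoints x 24.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have exactly 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 timepoints")
  lag <- rbind(matrix(0, 1L, 6L), motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag, lag^2)
  colnames(out) <- c(paste0("R", 1:6), paste0("R", 1:6, "_sq"),
                     paste0("R", 1:6, "_lag"), paste0("R", 1:6, "_lagsq"))
  out
}

#' Framewise displacement (Power-style sum of absolute differences)
#'
#' FD at frame t is the sum of absolute frame-to-frame differences of the
#' three translations (mm) plus \code{headRadiusMm} times the sum of
#' absolute rotation differences (radians, converted to arc length on a
#' sphere of the given radius). The first frame has FD = 0. This is the
#' sum-of-absolute-differences form rather than Jenkinson's RMS form: it is
#' fully specified by the motion trace alone and preserves the usual
#' spike-threshold semantics (e.g. 0.5 mm).
#'
#' @param motion timepoints x 6 matrix; rotations in radians.
#' @param headRadiusMm sphere radius used to convert rotations, default 50.
#' @return numeric vector of length timepoints.
#' @export
framewiseDisplacement <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have exactly 6 columns")
  if (any(!is.finite(motion))) stop("motion contains non-finite values")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Assemble a nuisance regression design
#'
#' Builds the confound design used before ALFF computation: intercept,
#' linear trend, Friston-24 motion expansion, cerebrospinal-fluid and
#' white-matter mean signals, optionally the global signal, and one
#' indicator (spike) column per frame whose framewise displacement exceeds
#' \code{fdThreshold} — scrubbing as spike regression, not frame deletion.
#'
#' @param motion timepoints x 6 motion parameters.
#' @param tissueSignals named list or data.frame with numeric elements
#'   \code{csf}, \code{wm} and (if \code{includeGsr}) \code{global}, each of
#'   length timepoints.
#' @param includeGsr include the global signal column (global signal
#'   regression on/off).
#' @param fd framewise displacement vector, or NULL to skip spike columns.
#' @param fdThreshold spike threshold in mm, default 0.5.
#' @return numeric matrix with named columns; full column rank guaranteed.
#' @export
buildNuisanceDesign <- function(motion, tissueSignals, includeGsr = TRUE,
                                fd = NULL, fdThreshold = 0.5) {
  fr24 <- friston24(motion)
  nT <- nrow(fr24)
  need <- c("csf", "wm", if (includeGsr) "global")
  miss <- setdiff(need, names(tissueSignals))
  if (length(miss)) stop("tissueSignals missing: ", paste(miss, collapse = ", "))
  tis <- vapply(need, function(k) {
    v <- as.numeric(tissueSignals[[k]])
    if (length(v) != nT) stop("tissue signal '", k, "' has wrong length")
    v
  }, numeric(nT))
  design <- cbind(intercept = rep(1, nT),
                  trend = seq_len(nT) - (nT + 1) / 2,
                  fr24, tis)
  if (!is.null(fd)) {
    if (length(fd) != nT) stop("fd length must match timepoints")
    spikes <- which(fd > fdThreshold)
    if (length(spikes)) {
      S <- matrix(0, nT, length(spikes))
      S[cbind(spikes, seq_along(spikes))] <- 1
      colnames(S) <- sprintf("spike_t%03d", spikes)
      design <- cbind(design, S)
    }
  }
  # drop exactly duplicated and all-zero columns (e.g. zero motion blocks)
  dup <- duplicated(t(design)) | colSums(design != 0) == 0L
  design <- design[, !dup, drop = FALSE]
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("nuisance design rank-deficient: rank ", qrd$rank, " of ",
         ncol(design), " columns (offending: ",
         paste(dropped, collapse = ", "), ")")
  }
  design
}

#' Regress a nuisance design out of voxel time series
#'
#' Returns the least-squares residuals of every voxel series on the design
#' (covariate regression and, through the trend column, linear detrending in
#' one step). Residuals are orthogonal to every design column.
#'
#' @param series timepoints x voxels matrix.
#' @param design timepoints x regressors matrix.
#' @return residual matrix, same shape as \code{series}.
#' @export
regressNuisance <- function(series, design) {
  series <- as.matrix(series); design <- as.matrix(design)
  if (nrow(series) != nrow(design))
    stop("design rows (", nrow(design), ") != series timepoints (",
         nrow(series), ")")
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("singular nuisance design: rank ", qrd$rank, " < ",
         ncol(design), " columns")
  series - design %*% qr.coef(qrd, series)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Converts each voxel's series to the frequency domain with an FFT, takes
#' the square root of the power spectrum — equivalently the one-sided
#' amplitude spectrum, defined here as 2|DFT|/T for non-DC bins — and
#' averages it across the frequency bins inside \code{band}. A constant
#' series therefore has ALFF 0, and ALFF is homogeneous of degree one in the
#' signal amplitude.
#'
#' @param series timepoints x voxels matrix (a vector is treated as one
#'   voxel).
#' @param trSeconds sampling interval in seconds.
#' @param band length-2 numeric (f_low, f_high) in Hz, default
#'   \code{c(0.01, 0.1)}; bins with f_low <= f <= f_high are averaged.
#' @return list with \code{values} (non-negative, one per voxel),
#'   \code{band}, \code{trSeconds}, \code{nBins} (in-band bin count).
#' @export
computeALFF <- function(series, trSeconds, band = c(0.01, 0.1)) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  series <- as.matrix(series)
  nT <- nrow(series)
  assertScalarNumber(trSeconds, "trSeconds", positive = TRUE)
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be c(f_low, f_high) with f_low < f_high")
  nyquist <- 1 / (2 * trSeconds)
  if (band[2] >= nyquist)
    stop(sprintf("f_high (%.4g) must be below Nyquist (%.4g Hz)",
                 band[2], nyquist))
  freqs <- (seq_len(nT) - 1L) / (nT * trSeconds)
  inBand <- which(freqs >= band[1] & freqs <= band[2] & freqs <= nyquist &
                    seq_len(nT) > 1L)
  if (length(inBand) < 2L) {
    minT <- ceiling(2 / (band[2] - band[1]) / trSeconds)
    stop("fewer than 2 frequency bins in band; need at least ~", minT,
         " timepoints at TR = ", trSeconds, " s")
  }
  amp <- 2 * Mod(stats::mvfft(series)) / nT
  values <- colMeans(amp[inBand, , drop = FALSE])
  list(values = values, band = band, trSeconds = trSeconds,
       nBins = length(inBand))
}

#' Threshold a probability map into a binary mask
#'
#' A voxel enters the mask iff its probability strictly exceeds
#' \code{threshold} (default 0.2, the usual gray-matter probability cut).
#' The strictness of the comparison is a documented convention and can be
#' flipped.
#'
#' @param probabilityMap numeric vector/array with values in \[0, 1\].
#' @param threshold scalar in \[0, 1), default 0.2.
#' @param strict if TRUE (default) use \code{>}, else \code{>=}.
#' @return logical vector/array of the same shape.
#' @export
makeMask <- function(probabilityMap, threshold = 0.2, strict = TRUE) {
  if (any(!is.finite(probabilityMap)) ||
      any(probabilityMap < 0 | probabilityMap > 1))
    stop("probability map values must lie in [0, 1]")
  if (strict) probabilityMap > threshold else probabilityMap >= threshold
}
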