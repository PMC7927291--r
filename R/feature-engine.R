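#' Fit z-normalisation statistics on training rows
#'
#' Per-column mean and sample standard deviation (n-1 denominator), computed
#' from training rows only — test rows must never contribute, so statistics
#' fitted here are applied unchanged to held-out data via
#' \code{\link{zscoreApply}}.
#'
#' @param trainMatrix numeric matrix, training subjects x voxels.
#' @return list with \code{means}, \code{sds} and \code{constant} (logical,
#'   flags zero-variance columns).
#' @export
zscoreFit <- function(trainMatrix) {
  trainMatrix <- as.matrix(trainMatrix)
  if (nrow(trainMatrix) < 2L)
    stop("need at least 2 training rows to estimate an SD")
  means <- colMeans(trainMatrix)
  sds <- sqrt(colSums(sweep(trainMatrix, 2L, means)^2) /
                (nrow(trainMatrix) - 1L))
  list(means = means, sds = sds, constant = sds == 0)
}

#' Apply fitted z-normalisation statistics
#'
#' \code{(x - mean) / sd} per column, using statistics from
#' \code{\link{zscoreFit}}; zero-variance columns map to 0.
#'
#' @param matrix numeric matrix with the same column count as the fit.
#' @param stats a \code{\link{zscoreFit}} result.
#' @return normalised matrix.
#' @export
zscoreApply <- function(matrix, stats) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(stats$means))
    stop("column count (", ncol(matrix), ") does not match fitted stats (",
         length(stats$means), ")")
  sds <- ifelse(stats$constant, 1, stats$sds)
  out <- sweep(sweep(matrix, 2L, stats$means), 2L, sds, "/")
  if (any(stats$constant)) out[, stats$constant] <- 0
  out
}

#' Mass-univariate correlation screening
#'
#' Pearson correlation of every feature column with the behavioural score,
#' with a two-sided p-value from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of
#' freedom. Zero-variance columns get r = 0, p = 1 so they can never be
#' selected.
#'
#' @param matrixZ subjects x voxels matrix (normalised or raw; r is
#'   scale-free).
#' @param y numeric score vector.
#' @return list with \code{r} and \code{p}, one entry per column.
#' @export
correlationScreen <- function(matrixZ, y) {
  matrixZ <- as.matrix(matrixZ)
  n <- nrow(matrixZ)
  if (n < 4L) stop("need n >= 4 for correlation screening")
  if (length(y) != n) stop("y length must match rows")
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  xc <- sweep(matrixZ, 2L, colMeans(matrixZ))
  sx <- sqrt(colSums(xc^2))
  num <- as.numeric(crossprod(xc, yc))
  denom <- sx * sy
  r <- ifelse(denom > 0, num / denom, 0)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[denom == 0] <- 1
  p[abs(r) == 1] <- 0
  list(r = r, p = p)
}

#' Select features by Bonferroni-corrected or relaxed correlation threshold
#'
#' In \code{"bonferroni"} mode a feature is kept iff its screening p-value
#' is below \code{alpha / nFeatures}. In \code{"relaxed"} mode the threshold
#' is \code{relaxedP}, and when fewer than \code{minFeatures} pass, the
#' \code{minFeatures} smallest-p features are taken instead (ties broken by
#' ascending voxel index) so a model can always be trained.
#'
#' @param r,p screening vectors from \code{\link{correlationScreen}}.
#' @param nFeatures the modality's feature count used in the Bonferroni
#'   denominator; defaults to \code{length(p)}.
#' @param mode "bonferroni" or "relaxed".
#' @param alpha family-wise level for Bonferroni mode, default 0.05.
#' @param relaxedP relaxed threshold, default 0.001.
#' @param minFeatures guaranteed selection size in relaxed mode, default 10.
#' @return list with \code{selected} (integer indices, ascending),
#'   \code{r}, \code{p}, \code{thresholdUsed}, \code{mode}.
#' @export
selectFeatures <- function(r, p, nFeatures = length(p),
                           mode = c("bonferroni", "relaxed"),
                           alpha = 0.05, relaxedP = 0.001,
                           minFeatures = 10L) {
  mode <- match.arg(mode)
  if (length(r) != length(p)) stop("r and p must have the same length")
  if (mode == "bonferroni") {
    thr <- alpha / nFeatures
    sel <- which(p < thr)
  } else {
    thr <- relaxedP
    sel <- which(p < thr)
    if (length(sel) < minFeatures) {
      k <- min(minFeatures, length(p))
      sel <- order(p, seq_along(p))[seq_len(k)]
      sel <- sort(sel)
    }
  }
  list(selected = sel, r = r, p = p, thresholdUsed = thr, mode = mode)
}
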