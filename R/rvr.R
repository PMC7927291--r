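#' Fit a relevance vector regression model
#'
#' Sparse Bayesian linear regression. With a Gaussian likelihood
#' y ~ N(Phi w, sigma^2 I) and independent zero-mean Gaussian priors
#' w_i ~ N(0, 1/alpha_i), the per-basis precisions alpha and the noise
#' variance sigma^2 are optimised by evidence maximisation using the
#' classic re-estimation updates: with posterior covariance
#' Sigma = (sigma^-2 Phi'Phi + A)^-1 and mean mu = sigma^-2 Sigma Phi'y,
#'
#'   gamma_i = 1 - alpha_i Sigma_ii,  alpha_i <- gamma_i / mu_i^2,
#'   sigma^2 <- ||y - Phi mu||^2 / (n - sum gamma).
#'
#' Basis functions whose precision exceeds \code{pruneThreshold} are pruned
#' (their posterior collapses on zero); iteration stops when the largest
#' absolute change in log alpha falls below \code{tol} or at
#' \code{maxIter}. The default basis is a linear kernel on samples,
#' Phi = \[1, X X'\], with an effectively unpenalised bias (its precision is
#' fixed near zero and never updated or pruned); the kernel is not centred
#' — z-scored inputs make centring nearly moot. A primal basis
#' Phi = \[1, X\] is available for small feature counts.
#'
#' @param X numeric matrix, subjects x features (no missing values).
#' @param y numeric response vector.
#' @param basis "kernel" (linear kernel on samples, the default) or
#'   "primal".
#' @param bias include an unpenalised bias basis function (default TRUE).
#' @param alphaInit scalar or per-basis initial precision (default 1e-3).
#' @param noiseVarInit initial sigma^2; default (0.1 sd(y))^2, the usual
#'   sparse-Bayesian starting point.
#' @param updateAlpha,updateNoise freeze the corresponding hyperparameter
#'   update when FALSE (with both FALSE the fit is a single posterior solve
#'   at the supplied hyperparameters — the ridge closed form).
#' @param pruneThreshold precision above which a basis is pruned (1e9).
#' @param noiseVarFloor lower bound kept on sigma^2 during re-estimation,
#'   as a fraction of var(y) (default 1e-6). Prevents the noise estimate
#'   from collapsing to zero on interpolating bases (more basis functions
#'   than samples), which would freeze the pruning.
#' @param noiseUpdateStart iterations for which sigma^2 is held at its
#'   initial value before its update is switched on (default 20). With a
#'   broad initial prior the very first posterior interpolates the data
#'   whenever the basis can, and an immediate noise update would collapse
#'   sigma^2 to zero before any basis has been pruned; a short burn-in lets
#'   the precisions differentiate first.
#' @param tol convergence tolerance on max |delta log alpha| (1e-6).
#' @param maxIter iteration cap (1000); non-convergence returns the model
#'   with \code{converged = FALSE} and a warning.
#' @return an \linkS4class{RVRModel}.
#' @export
rvrFit <- function(X, y, basis = c("kernel", "primal"), bias = TRUE,
                   alphaInit = 1e-3, noiseVarInit = NULL,
                   updateAlpha = TRUE, updateNoise = TRUE,
                   pruneThreshold = 1e9, noiseVarFloor = 1e-6,
                   noiseUpdateStart = 20L, tol = 1e-6, maxIter = 1000L) {
  basis <- match.arg(basis)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  if (length(y) != n) stop("y length must match rows of X")
  if (anyNA(X) || anyNA(y)) stop("X and y must not contain missing values")

  if (stats::var(y) == 0) {
    # degenerate response: intercept-only model
    return(new("RVRModel", basis = "intercept", alpha = 1e-9,
               mu = mean(y), sigmaPosterior = matrix(1e-9, 1, 1),
               noiseVar = 1e-12, activeSet = 0L,
               trainReference = matrix(0, 0, ncol(X)),
               nFeatures = ncol(X), converged = TRUE, iterations = 0L,
               prunedAlpha = numeric(0)))
  }

  Phi <- if (basis == "kernel") tcrossprod(X) else X
  if (bias) Phi <- cbind(1, Phi)
  M <- ncol(Phi)
  alpha <- if (length(alphaInit) == 1L) rep(alphaInit, M) else {
    if (length(alphaInit) != M - bias && length(alphaInit) != M)
      stop("alphaInit must be scalar or one value per basis function")
    if (length(alphaInit) == M) alphaInit else c(alphaInit[1], alphaInit)
  }
  biasIndex <- if (bias) 0L else -1L
  if (bias) alpha[1] <- 1e-9
  if (is.null(noiseVarInit)) noiseVarInit <- 0.01 * stats::var(y)

  fit <- .rvrCore(Phi, as.numeric(y), as.numeric(alpha), biasIndex,
                  noiseVarInit, updateAlpha, updateNoise,
                  pruneThreshold, tol, as.integer(maxIter),
                  noiseVarFloor * stats::var(y),
                  if (updateNoise) as.integer(noiseUpdateStart) else 0L)
  if (!fit$converged)
    warning("RVR did not converge within ", maxIter, " iterations")
  active <- as.integer(fit$active)         # 1-based columns of Phi
  # recode: 0 marks the bias; positive entries index samples/features
  codes <- if (bias) active - 1L else active
  sampleIdx <- codes[codes > 0L]
  trainRef <- if (basis == "kernel")
    X[sampleIdx, , drop = FALSE] else matrix(0, 0, ncol(X))
  prunedIdx <- setdiff(seq_len(M), active)
  new("RVRModel", basis = basis, alpha = as.numeric(fit$alpha),
      mu = as.numeric(fit$mu),
      sigmaPosterior = if (length(fit$mu))
        as.matrix(fit$sigma) else matrix(0, 0, 0),
      noiseVar = fit$noiseVar, activeSet = codes,
      trainReference = trainRef, nFeatures = ncol(X),
      converged = fit$converged, iterations = as.integer(fit$iterations),
      prunedAlpha = setNames(rep(log10(pruneThreshold), length(prunedIdx)),
                             as.character(prunedIdx)))
}

#' Predict from a fitted RVR model
#'
#' Point predictions Phi(X_test) mu (plus the bias when present);
#' deterministic given the model.
#'
#' @param model an \linkS4class{RVRModel}.
#' @param Xtest numeric matrix with the training feature count.
#' @return numeric vector of predictions.
#' @export
rvrPredict <- function(model, Xtest) {
  Xtest <- as.matrix(Xtest)
  if (ncol(Xtest) != model@nFeatures)
    stop("Xtest has ", ncol(Xtest), " columns; model expects ",
         model@nFeatures)
  if (model@basis == "intercept")
    return(rep(model@mu[1], nrow(Xtest)))
  hasBias <- any(model@activeSet == 0L)
  muBias <- if (hasBias) model@mu[model@activeSet == 0L] else 0
  muRest <- model@mu[model@activeSet > 0L]
  idx <- model@activeSet[model@activeSet > 0L]
  if (length(idx) == 0L) return(rep(muBias, nrow(Xtest)))
  contrib <- if (model@basis == "kernel")
    Xtest %*% t(model@trainReference) %*% muRest
  else
    Xtest[, idx, drop = FALSE] %*% muRest
  as.numeric(contrib) + muBias
}

#' Back-project kernel weights to voxel (primal) space
#'
#' For the linear kernel, the primal weight vector is
#' w = X_active' mu_active over the retained training samples; predictions
#' through w reproduce kernel predictions exactly. When the model was fitted
#' on a selected subset of a larger voxel space, supply \code{nVoxels} and
#' \code{selected} to re-embed the weights with zeros at unselected voxels.
#'
#' @param model an \linkS4class{RVRModel} with linear-kernel or primal
#'   basis.
#' @param nVoxels length of the full voxel space (default: the model's
#'   feature count).
#' @param selected integer indices of the model's features within the full
#'   voxel space.
#' @return list with \code{w} (length \code{nVoxels}) and \code{intercept}.
#' @export
dualToPrimal <- function(model, nVoxels = model@nFeatures,
                         selected = seq_len(model@nFeatures)) {
  if (length(selected) != model@nFeatures)
    stop("selected must index every model feature")
  hasBias <- any(model@activeSet == 0L)
  muBias <- if (hasBias) model@mu[model@activeSet == 0L] else 0
  w <- numeric(nVoxels)
  if (model@basis == "intercept")
    return(list(w = w, intercept = if (length(model@mu)) model@mu[1] else 0))
  muRest <- model@mu[model@activeSet > 0L]
  idx <- model@activeSet[model@activeSet > 0L]
  if (model@basis == "kernel") {
    if (length(muRest))
      w[selected] <- as.numeric(crossprod(model@trainReference, muRest))
  } else if (model@basis == "primal") {
    w[selected[idx]] <- muRest
  } else {
    stop("unsupported basis for primal back-projection: ", model@basis)
  }
  list(w = w, intercept = muBias)
}

#' Minimum-norm linear regression baseline
#'
#' Ordinary least squares with an intercept via the pseudo-inverse of the
#' centred design: when the system is under-determined the returned weights
#' are the minimum-norm exact solution (zero training residuals).
#'
#' @param X subjects x features matrix; @param y response.
#' @return list with \code{kind = "lr"}, \code{w}, \code{intercept}.
#' @export
lrFit <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (length(y) != nrow(X)) stop("y length must match rows of X")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  sv <- svd(Xc)
  tolv <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tolv
  w <- if (any(pos))
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
  else matrix(0, ncol(X), 1)
  w <- as.numeric(w)
  list(kind = "lr", w = w, intercept = mean(y) - sum(xbar * w))
}

#' @rdname lrFit
#' @param model an \code{\link{lrFit}} result.
#' @param Xtest prediction matrix.
#' @export
lrPredict <- function(model, Xtest) {
  as.numeric(as.matrix(Xtest) %*% model$w) + model$intercept
}

# Regressor adapter registry used by the pipeline. "rvr" and "lr" are
# native; "svr" plugs in an external support vector regression (e1071) —
# SVR internals are deliberately external, only the adapter surface is ours.
resolveRegressor <- function(regressor) {
  if (is.list(regressor)) {
    stopifnot(is.function(regressor$fit), is.function(regressor$predict))
    return(regressor)
  }
  switch(regressor,
    rvr = list(
      fit = function(X, y) rvrFit(X, y),
      predict = rvrPredict,
      primal = function(model, nVoxels, selected)
        dualToPrimal(model, nVoxels, selected)),
    lr = list(
      fit = lrFit,
      predict = lrPredict,
      primal = function(model, nVoxels, selected) {
        w <- numeric(nVoxels); w[selected] <- model$w
        list(w = w, intercept = model$intercept)
      }),
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("the 'svr' adapter requires the e1071 package")
      list(
        fit = function(X, y)
          e1071::svm(x = X, y = y, kernel = "linear", scale = FALSE),
        predict = function(model, Xtest)
          as.numeric(stats::predict(model, Xtest)),
        primal = NULL)
    },
    stop("unknown regressor: ", regressor))
}
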