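#' Cross-validation scheme descriptor
#'
#' @param kind "loocv" (one fold per subject) or "kfold".
#' @param k folds for k-fold (typically 5 or 10); ignored for LOOCV.
#' @param repeats independent repetitions of the k-fold partition
#'   (default 100); ignored for LOOCV.
#' @param seed integer seed controlling fold assignment.
#' @return a list of class \code{"CVScheme"}.
#' @export
cvScheme <- function(kind = c("loocv", "kfold"), k = 5L, repeats = 100L,
                     seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "kfold" && k < 2L) stop("kfold requires k >= 2")
  structure(list(kind = kind, k = as.integer(k),
                 repeats = if (kind == "kfold") as.integer(repeats) else 1L,
                 seed = as.integer(seed)),
            class = "CVScheme")
}

# Fold assignment for one repeat: a list of test-index vectors. K-fold sizes
# differ by at most one; every subject lands in exactly one test fold.
foldAssignments <- function(n, scheme) {
  if (scheme$kind == "loocv")
    return(list(lapply(seq_len(n), identity)))
  if (scheme$k > n) stop("k exceeds number of subjects")
  withSeed(scheme$seed, {
    lapply(seq_len(scheme$repeats), function(rep) {
      lab <- sample(rep_len(seq_len(scheme$k), n))
      folds <- split(seq_len(n), lab)
      if (any(lengths(folds) == 0L)) stop("fold assignment left an empty fold")
      folds
    })
  })
}

#' Selection settings for the in-fold screening step
#'
#' @param mode "bonferroni" or "relaxed" (see \code{\link{selectFeatures}}).
#' @param alpha,relaxedP,minFeatures thresholds passed through.
#' @return a plain list.
#' @export
selectionSettings <- function(mode = c("bonferroni", "relaxed"),
                              alpha = 0.05, relaxedP = 0.001,
                              minFeatures = 10L) {
  list(mode = match.arg(mode), alpha = alpha, relaxedP = relaxedP,
       minFeatures = as.integer(minFeatures))
}

# One fold of the in-fold pipeline for every modality:
# z-normalisation fitted on train -> applied to train and test ->
# correlation screening on train -> threshold selection -> fit -> predict.
# A modality with zero selected features predicts the training mean.
foldCore <- function(featList, y, train, test, selection, reg,
                     computeWeights = FALSE, warnEmpty = TRUE) {
  out <- vector("list", length(featList))
  names(out) <- names(featList)
  for (m in names(featList)) {
    X <- featList[[m]]
    st <- zscoreFit(X[train, , drop = FALSE])
    Xtr <- zscoreApply(X[train, , drop = FALSE], st)
    Xte <- zscoreApply(X[test, , drop = FALSE], st)
    scr <- correlationScreen(Xtr, y[train])
    sel <- selectFeatures(scr$r, scr$p, nFeatures = ncol(X),
                          mode = selection$mode, alpha = selection$alpha,
                          relaxedP = selection$relaxedP,
                          minFeatures = selection$minFeatures)
    if (length(sel$selected) == 0L) {
      if (warnEmpty)
        warning("no features selected for modality '", m,
                "'; predicting the training mean for this fold")
      out[[m]] <- list(pred = rep(mean(y[train]), length(test)),
                       nSelected = 0L, selected = integer(0),
                       w = if (computeWeights) numeric(ncol(X)) else NULL)
      next
    }
    model <- reg$fit(Xtr[, sel$selected, drop = FALSE], y[train])
    pred <- reg$predict(model, Xte[, sel$selected, drop = FALSE])
    w <- NULL
    if (computeWeights) {
      if (is.null(reg$primal))
        stop("the chosen regressor does not expose primal weights")
      w <- reg$primal(model, ncol(X), sel$selected)$w
    }
    out[[m]] <- list(pred = pred, nSelected = length(sel$selected),
                     selected = sel$selected, w = w, model = model,
                     normStats = st, screen = scr)
  }
  out
}

#' Run a single cross-validation fold
#'
#' Executes the full in-fold pipeline (train-only normalisation, screening,
#' selection, model fit, test prediction) for each modality, then fuses
#' mono-modality test predictions by arithmetic averaging for every
#' requested modality combination. Test subjects enter no training
#' computation.
#'
#' @param dataset a \linkS4class{MultimodalDataset}.
#' @param trainIds,testIds disjoint, non-empty subject id vectors.
#' @param modalities modality tags to model (default: all in the dataset).
#' @param regressor "rvr", "lr", "svr", or a list with \code{fit},
#'   \code{predict} (and optionally \code{primal}) functions.
#' @param selection a \code{\link{selectionSettings}} list.
#' @param computeWeights also back-project per-modality primal weights.
#' @return list with \code{perModality} (prediction, selection, weights per
#'   modality) and \code{fused} (named list of fused test predictions, one
#'   per combination).
#' @export
runFold <- function(dataset, trainIds, testIds,
                    modalities = NULL, regressor = "rvr",
                    selection = selectionSettings(),
                    computeWeights = FALSE) {
  ids <- subjectIds(dataset)
  train <- match(trainIds, ids); test <- match(testIds, ids)
  if (anyNA(train) || anyNA(test)) stop("unknown subject ids")
  if (length(intersect(train, test))) stop("train and test sets overlap")
  if (!length(train) || !length(test)) stop("train and test must be non-empty")
  if (is.null(modalities)) modalities <- names(dataset@features)
  reg <- resolveRegressor(regressor)
  feats <- dataset@features[modalities]
  per <- foldCore(feats, dataset@scores, train, test, selection, reg,
                  computeWeights = computeWeights)
  combos <- allCombinations(modalities)
  fused <- lapply(combos, function(cmb) {
    rowMeans(matrix(vapply(cmb, function(m) per[[m]]$pred,
                           numeric(length(test))), nrow = length(test)))
  })
  names(fused) <- vapply(combos, paste, character(1), collapse = "+")
  list(perModality = per, fused = fused)
}

allCombinations <- function(modalities) {
  out <- list()
  for (size in seq_along(modalities))
    out <- c(out, utils::combn(modalities, size, simplify = FALSE))
  out
}

#' Pearson correlation and mean absolute error of predictions
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3 for
#'   a defined correlation).
#' @return list with \code{r} and \code{mae}. Zero-variance predictions
#'   yield \code{r = NA} with a warning.
#' @export
evaluatePredictions <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  mae <- mean(abs(observed - predicted))
  if (length(observed) < 3L || stats::sd(predicted) == 0 ||
      stats::sd(observed) == 0) {
    if (length(observed) >= 3L)
      warning("zero-variance input: correlation undefined, returning NA")
    return(list(r = NA_real_, mae = mae))
  }
  list(r = stats::cor(observed, predicted), mae = mae)
}

# Lean pipeline driver shared by runCV and permutationTest: returns
# out-of-fold predictions per combination (subjects x repeats matrices),
# per-modality selection counts, and (optionally) summed fold weights.
cvDrive <- function(featList, y, assignments, selection, reg,
                    combos, keepWeights = FALSE, warnEmpty = TRUE) {
  n <- length(y)
  comboIds <- vapply(combos, paste, character(1), collapse = "+")
  nRep <- length(assignments)
  preds <- lapply(comboIds, function(i) matrix(NA_real_, n, nRep))
  names(preds) <- comboIds
  nSel <- setNames(numeric(length(featList)), names(featList))
  wSum <- if (keepWeights)
    lapply(featList, function(X) numeric(ncol(X))) else NULL
  nFolds <- 0L
  for (repi in seq_len(nRep)) {
    for (fold in assignments[[repi]]) {
      test <- fold
      train <- setdiff(seq_len(n), test)
      per <- foldCore(featList, y, train, test, selection, reg,
                      computeWeights = keepWeights, warnEmpty = warnEmpty)
      nFolds <- nFolds + 1L
      for (m in names(featList)) {
        nSel[m] <- nSel[m] + per[[m]]$nSelected
        if (keepWeights) wSum[[m]] <- wSum[[m]] + per[[m]]$w
      }
      for (ci in seq_along(combos)) {
        p <- rowMeans(matrix(vapply(combos[[ci]], function(m) per[[m]]$pred,
                                    numeric(length(test))),
                             nrow = length(test)))
        preds[[ci]][test, repi] <- p
      }
    }
  }
  list(preds = preds, nSelectedMean = nSel / nFolds,
       wSum = wSum, nFolds = nFolds)
}

#' Run the full cross-validated multimodal prediction pipeline
#'
#' Orchestrates, per fold: train-statistics z-normalisation, in-fold
#' mass-univariate selection, per-modality model fitting, test prediction,
#' and prediction-averaging fusion over every requested modality
#' combination (with three modalities: three mono, three bi, one
#' tri-modality model). Out-of-fold predictions are assembled so that every
#' subject is predicted exactly once per repeat.
#'
#' @param dataset a \linkS4class{MultimodalDataset}.
#' @param scheme a \code{\link{cvScheme}}.
#' @param modalities tags to model (default all).
#' @param combinations "all" or a list of character vectors of tags.
#' @param regressor as in \code{\link{runFold}}.
#' @param selection a \code{\link{selectionSettings}} list.
#' @param keepWeights accumulate fold-averaged primal weight maps
#'   (default TRUE for LOOCV, FALSE for k-fold).
#' @return named list of \linkS4class{CVResult}, one per combination, with
#'   attribute \code{"weightMaps"} (named list of \linkS4class{WeightMap})
#'   when \code{keepWeights} is TRUE.
#' @export
runCV <- function(dataset, scheme = cvScheme("loocv"), modalities = NULL,
                  combinations = "all", regressor = "rvr",
                  selection = selectionSettings(),
                  keepWeights = scheme$kind == "loocv") {
  if (is.null(modalities)) modalities <- names(dataset@features)
  reg <- resolveRegressor(regressor)
  y <- dataset@scores
  n <- length(y)
  if (n < 4L) stop("need at least 4 subjects")
  combos <- if (identical(combinations, "all"))
    allCombinations(modalities) else combinations
  assignments <- foldAssignments(n, scheme)
  drv <- cvDrive(dataset@features[modalities], y, assignments, selection,
                 reg, combos, keepWeights = keepWeights)
  results <- lapply(seq_along(combos), function(ci) {
    P <- drv$preds[[ci]]
    perRep <- do.call(rbind, lapply(seq_len(ncol(P)), function(repi) {
      ev <- evaluatePredictions(y, P[, repi])
      data.frame(repeat_id = repi, r = ev$r, mae = ev$mae)
    }))
    relevant <- combos[[ci]]
    new("CVResult",
        modelId = paste(relevant, collapse = "+"),
        predicted = P, observed = y,
        r = mean(perRep$r), mae = mean(perRep$mae),
        nSelectedMean = drv$nSelectedMean[relevant],
        perRepeat = perRep,
        scheme = unclass(scheme))
  })
  names(results) <- vapply(combos, paste, character(1), collapse = "+")
  if (keepWeights) {
    wm <- lapply(names(drv$wSum), function(m)
      new("WeightMap", voxelWeights = drv$wSum[[m]] / drv$nFolds,
          modalityTag = m, nFolds = drv$nFolds))
    names(wm) <- names(drv$wSum)
    attr(results, "weightMaps") <- wm
  }
  results
}

#' Permutation test of out-of-fold prediction accuracy
#'
#' Re-runs the entire pipeline — including in-fold normalisation, screening
#' and selection — on score vectors permuted over subjects, once per
#' permutation, building a null distribution of the out-of-fold correlation.
#' The p-value is the proportion of permutations with a strictly higher
#' correlation than the observed one; the standard smoothed estimator
#' (#\{null >= observed\} + 1)/(nPerm + 1) is co-reported.
#'
#' @param dataset a \linkS4class{MultimodalDataset}.
#' @param scheme a \code{\link{cvScheme}}; fold assignments are held fixed
#'   across permutations (the label shuffle is the randomisation).
#' @param modalities tags entering the tested combination.
#' @param combination character vector of tags defining the tested model
#'   (default: all of \code{modalities}, i.e. the fused model).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param regressor,selection as in \code{\link{runCV}}.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(dataset, scheme = cvScheme("loocv"),
                            modalities = NULL, combination = NULL,
                            nPerm = 1000L, seed = 1L,
                            regressor = "rvr",
                            selection = selectionSettings()) {
  if (is.null(modalities)) modalities <- names(dataset@features)
  if (is.null(combination)) combination <- modalities
  reg <- resolveRegressor(regressor)
  y <- dataset@scores
  n <- length(y)
  assignments <- foldAssignments(n, scheme)
  feats <- dataset@features[modalities]
  combos <- list(combination)
  oneRun <- function(yy, warnEmpty = FALSE) {
    drv <- cvDrive(feats, yy, assignments, selection, reg, combos,
                   keepWeights = FALSE, warnEmpty = warnEmpty)
    P <- drv$preds[[1]]
    mean(vapply(seq_len(ncol(P)), function(repi) {
      if (stats::sd(P[, repi]) == 0) return(0)
      stats::cor(yy, P[, repi])
    }, numeric(1)))
  }
  observed <- oneRun(y, warnEmpty = TRUE)
  perms <- withSeed(seed,
    lapply(seq_len(nPerm), function(i) sample.int(n)))
  nullR <- vapply(perms, function(pm) oneRun(y[pm]), numeric(1))
  new("PermutationResult",
      observedR = observed, nullR = nullR,
      pValue = sum(nullR > observed) / nPerm,
      pSmoothed = (sum(nullR >= observed) + 1) / (nPerm + 1),
      seed = as.integer(seed))
}
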