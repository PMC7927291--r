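#' Average per-fold primal weights into a discriminative weight map
#'
#' Elementwise mean of the voxel-space weight vectors across folds. Voxels
#' not selected in a fold contribute 0 for that fold (zero-fill), keeping
#' weights comparable across folds; set \code{selectedFoldsOnly = TRUE} to
#' instead average each voxel over only the folds where it carried a
#' nonzero weight.
#'
#' @param perFold list of numeric vectors (or lists with a \code{w}
#'   element), one per fold, all over the same voxel space.
#' @param modalityTag label for the resulting map.
#' @param selectedFoldsOnly alternative averaging convention (see above).
#' @return a \linkS4class{WeightMap}.
#' @export
averageFoldWeights <- function(perFold, modalityTag = "modality",
                               selectedFoldsOnly = FALSE) {
  if (length(perFold) == 0L) stop("empty fold list")
  ws <- lapply(perFold, function(f) if (is.list(f)) f$w else f)
  p <- length(ws[[1]])
  if (!all(lengths(ws) == p)) stop("folds disagree on voxel space length")
  W <- do.call(rbind, ws)
  avg <- if (selectedFoldsOnly) {
    cnt <- colSums(W != 0)
    ifelse(cnt > 0, colSums(W) / pmax(cnt, 1L), 0)
  } else colMeans(W)
  new("WeightMap", voxelWeights = as.numeric(avg),
      modalityTag = modalityTag, nFolds = length(ws))
}

#' Aggregate a voxel weight map to atlas nodes
#'
#' The discriminative weight of a node is the mean weight over its member
#' voxels.
#'
#' @param weightMap a \linkS4class{WeightMap} (or bare numeric vector).
#' @param atlas an \linkS4class{AtlasLabels} covering the voxel space.
#' @return named numeric vector of node weights.
#' @export
mapToAtlas <- function(weightMap, atlas) {
  w <- if (is(weightMap, "WeightMap")) voxelWeights(weightMap) else weightMap
  if (length(w) != length(atlas@voxelNode))
    stop("atlas covers ", length(atlas@voxelNode),
         " voxels but weight map has ", length(w))
  sums <- tapply(w, atlas@voxelNode, mean)
  nodeW <- setNames(rep(NA_real_, length(atlas@nodeNetwork)),
                    atlas@nodeNames)
  nodeW[as.integer(names(sums))] <- as.numeric(sums)
  empty <- is.na(nodeW)
  if (any(empty)) {
    warning("excluding nodes with no member voxels: ",
            paste(atlas@nodeNames[empty], collapse = ", "))
    nodeW <- nodeW[!empty]
  }
  nodeW
}

#' Positive and negative contribution sums per network
#'
#' For every network, sums the positive node weights and (separately) the
#' negative node weights, the convention used for stacked
#' positive/negative network contribution plots.
#'
#' @param nodeWeights named numeric vector as from \code{\link{mapToAtlas}}
#'   (names must match the atlas node names, in order).
#' @param atlas an \linkS4class{AtlasLabels}.
#' @return data.frame with columns network, positive_sum, negative_sum,
#'   net_sum.
#' @export
networkContributions <- function(nodeWeights, atlas) {
  idx <- match(names(nodeWeights), atlas@nodeNames)
  if (anyNA(idx)) stop("node names not found in atlas")
  net <- atlas@nodeNetwork[idx]
  nNet <- max(atlas@nodeNetwork)
  pos <- vapply(seq_len(nNet), function(k)
    sum(pmax(nodeWeights[net == k], 0)), numeric(1))
  neg <- vapply(seq_len(nNet), function(k)
    sum(pmin(nodeWeights[net == k], 0)), numeric(1))
  data.frame(network = atlas@networkNames[seq_len(nNet)],
             positive_sum = pos, negative_sum = neg,
             net_sum = pos + neg, stringsAsFactors = FALSE)
}

#' Rank the top contributing entries of a weight vector
#'
#' Returns the k largest positive and/or k most negative entries of a voxel
#' weight map or node weight vector, ranked by raw averaged weight. Ties
#' are broken by ascending index.
#'
#' @param weights a \linkS4class{WeightMap}, or a (possibly named) numeric
#'   vector.
#' @param k entries per sign (default 10); truncated with a warning when it
#'   exceeds the available entries.
#' @param sign "positive", "negative" or "both".
#' @return data.frame with columns rank, index, label, weight, sign.
#' @export
topRegions <- function(weights, k = 10L, sign = c("both", "positive",
                                                  "negative")) {
  sign <- match.arg(sign)
  if (k < 1L) stop("k must be >= 1")
  w <- if (is(weights, "WeightMap")) voxelWeights(weights) else weights
  labels <- if (!is.null(names(w))) names(w) else as.character(seq_along(w))
  one <- function(sgn) {
    vals <- if (sgn == "positive") w else -w
    idx <- which(vals > 0)
    if (length(idx) == 0L)
      return(data.frame(rank = integer(0), index = integer(0),
                        label = character(0), weight = numeric(0),
                        sign = character(0), stringsAsFactors = FALSE))
    kk <- min(k, length(idx))
    if (kk < k)
      warning("only ", length(idx), " ", sgn, " entries available; ",
              "truncating to ", kk)
    ord <- idx[order(-vals[idx], idx)][seq_len(kk)]
    data.frame(rank = seq_len(kk), index = ord, label = labels[ord],
               weight = w[ord], sign = sgn, stringsAsFactors = FALSE)
  }
  switch(sign,
         positive = one("positive"),
         negative = one("negative"),
         both = rbind(one("positive"), one("negative")))
}
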