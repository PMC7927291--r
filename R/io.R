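#' Read and write behavioural score tables
#'
#' Scores travel as 2-column tab-separated text: \code{subject_id},
#' \code{score}. Subject ids are mandatory — downstream alignment is by id,
#' never by row order.
#'
#' @param path file path.
#' @return named numeric vector of scores.
#' @export
readScores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(tab)))
    stop("scores file needs columns subject_id and score: ", path)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ids in ", path)
  setNames(as.numeric(tab$score), tab$subject_id)
}

#' @rdname readScores
#' @param scores named numeric vector (names are subject ids).
#' @export
writeScores <- function(scores, path) {
  if (is.null(names(scores))) stop("scores must be named by subject id")
  utils::write.table(
    data.frame(subject_id = names(scores),
               score = sprintf("%.17g", unname(scores))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-modality feature matrices as TSV
#'
#' Wide tab-separated layout: a \code{subject_id} column followed by one
#' column per voxel (\code{v1 ... vP}). Round-trips are lossless at float64
#' (values are written with full precision).
#'
#' @param path file path.
#' @return numeric matrix with subject ids as row names.
#' @export
readFeaturesTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"subject_id" %in% names(tab))
    stop("features file needs a subject_id column: ", path)
  ids <- tab$subject_id
  X <- as.matrix(tab[setdiff(names(tab), "subject_id")])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' @rdname readFeaturesTSV
#' @param X subjects x voxels matrix with subject ids as row names.
#' @export
writeFeaturesTSV <- function(X, path) {
  if (is.null(rownames(X))) stop("feature matrix must have subject row names")
  df <- data.frame(subject_id = rownames(X),
                   format(X, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("subject_id",
                 if (!is.null(colnames(X))) colnames(X)
                 else paste0("v", seq_len(ncol(X))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write feature matrices as 4D NIfTI
#'
#' One 4D NIfTI file per modality with subjects along the 4th axis; the
#' first three axes carry the voxel space (a flat 1-D voxel axis is written
#' as P x 1 x 1). An optional binary mask restricts the voxels read; voxel
#' order follows the file's own array order, internal voxel indices are
#' 1-based positions within the mask.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param mask optional logical/0-1 array matched to the 3D grid.
#' @return subjects x voxels matrix.
#' @export
readFeaturesNIfTI <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L) stop("expected a 4D NIfTI (subjects on axis 4)")
  nSub <- d[4]
  vox <- prod(d[1:3])
  M <- t(matrix(arr, vox, nSub))
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    if (length(keep) != vox) stop("mask size does not match image grid")
    M <- M[, keep, drop = FALSE]
  }
  M
}

#' @rdname readFeaturesNIfTI
#' @param X subjects x voxels matrix.
#' @export
writeFeaturesNIfTI <- function(X, path) {
  arr <- array(t(X), dim = c(ncol(X), 1L, 1L, nrow(X)))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Write and read a full synthetic dataset directory
#'
#' Persists a \linkS4class{MultimodalDataset} as one TSV (or NIfTI) feature
#' file per modality plus a score table, and re-assembles it with
#' subject-id alignment checks. Any subject present in the features but
#' missing from the score table (or vice versa) aborts with the offending
#' ids listed.
#'
#' @param dataset a \linkS4class{MultimodalDataset}.
#' @param dir output directory (created if absent).
#' @param format "tsv" or "nifti".
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeScores(scores(dataset), file.path(dir, "scores.tsv"))
  for (m in modalities(dataset)) {
    X <- featureMatrix(dataset, m)
    rownames(X) <- subjectIds(dataset)
    if (format == "tsv")
      writeFeaturesTSV(X, file.path(dir, paste0("features_", m, ".tsv")))
    else {
      writeFeaturesNIfTI(X, file.path(dir, paste0("features_", m, ".nii.gz")))
      writeScores(setNames(seq_len(nrow(X)), rownames(X)),
                  file.path(dir, paste0("subjects_", m, ".tsv")))
    }
  }
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  sc <- readScores(file.path(dir, "scores.tsv"))
  pat <- if (format == "tsv") "^features_(.*)\\.tsv$"
         else "^features_(.*)\\.nii\\.gz$"
  files <- list.files(dir, pattern = pat)
  if (!length(files)) stop("no feature files found under ", dir)
  feats <- list()
  for (f in files) {
    m <- sub(pat, "\\1", f)
    if (format == "tsv") {
      X <- readFeaturesTSV(file.path(dir, f))
    } else {
      X <- readFeaturesNIfTI(file.path(dir, f))
      ord <- readScores(file.path(dir, paste0("subjects_", m, ".tsv")))
      rownames(X) <- names(ord)[order(ord)]
    }
    missingScore <- setdiff(rownames(X), names(sc))
    missingFeat <- setdiff(names(sc), rownames(X))
    if (length(missingScore) || length(missingFeat))
      stop("subject mismatch for modality '", m, "': ",
           if (length(missingScore))
             paste("no score for", paste(missingScore, collapse = ", ")),
           if (length(missingFeat))
             paste(" no features for", paste(missingFeat, collapse = ", ")))
    feats[[m]] <- X[names(sc), , drop = FALSE]
    rownames(feats[[m]]) <- NULL
  }
  new("MultimodalDataset", subjectIds = names(sc), features = feats,
      scores = unname(sc), truth = NULL, atlas = NULL)
}

#' Read and write run configuration as YAML
#'
#' @param config named list of run settings (all seeds explicit).
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Write pipeline results to disk
#'
#' Per-subject out-of-fold predictions as TSV and a JSON summary (r, MAE,
#' mean selected features, per-repeat statistics) per model combination;
#' weight maps as TSV (voxel_id, weight).
#'
#' @param results named list of \linkS4class{CVResult} from
#'   \code{\link{runCV}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCVResults <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- lapply(results, function(res) {
    list(model = res@modelId, r = res@r, mae = res@mae,
         n_selected_mean = as.list(res@nSelectedMean),
         per_repeat = res@perRepeat)
  })
  jsonlite::write_json(summary, file.path(dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (res in results) {
    df <- data.frame(subject_id = seq_len(nrow(res@predicted)),
                     observed = res@observed, res@predicted)
    names(df) <- c("subject_id", "observed",
                   paste0("predicted_rep", seq_len(ncol(res@predicted))))
    utils::write.table(df,
      file.path(dir, paste0("predictions_", gsub("\\+", "_", res@modelId),
                            ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wm <- attr(results, "weightMaps")
  if (!is.null(wm)) for (m in names(wm))
    utils::write.table(
      data.frame(voxel_id = seq_along(voxelWeights(wm[[m]])),
                 weight = voxelWeights(wm[[m]])),
      file.path(dir, paste0("weights_", m, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a reproducibility manifest
#'
#' Records the configuration (with an md5 of its canonical YAML form),
#' explicit seeds, package and R versions — enough to re-run all
#' deterministic stages bit-identically.
#'
#' @param config named list of run settings.
#' @param seeds named list/vector of every seed used.
#' @param dir output directory.
#' @return manifest path, invisibly.
#' @export
writeManifest <- function(config, seeds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(dir, "config.yaml")
  writeRunConfig(config, cfgPath)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfgPath)),
    seeds = as.list(seeds),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("rvrfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
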