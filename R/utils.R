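# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (config, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}

# Recycle a scalar or per-modality value across modality tags.
perModality <- function(x, tags, name) {
  if (length(x) == 1L && is.null(names(x)))
    return(setNames(rep(x, length(tags)), tags))
  if (is.null(names(x)) && length(x) == length(tags))
    return(setNames(x, tags))
  if (!all(tags %in% names(x)))
    stop(name, " must be a scalar or named per modality: ",
         paste(setdiff(tags, names(x)), collapse = ", "), " missing")
  x[tags]
}
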