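#' Upper-tail probability of Student's t
#'
#' P(T_df > t); monotone decreasing in t.
#'
#' @param t statistic; @param df degrees of freedom (>= 1).
#' @return one-sided p-value.
#' @export
tTailP <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  stats::pt(t, df = df, lower.tail = FALSE)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares r12 = cor(y, a) against r13 = cor(y, b), where a and b are
#' correlated with each other (r23 = cor(a, b)) because all three are
#' measured on the same n subjects — the typical situation when two
#' prediction models are evaluated against the same observed scores. The
#' statistic (Williams' modification, as endorsed by Steiger) is
#'
#'   T2 = (r12 - r13) sqrt( (n-1)(1+r23) /
#'        ( 2 ((n-1)/(n-3)) |R| + rbar^2 (1-r23)^3 ) ),
#'
#' with |R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23 the determinant of
#' the 3x3 correlation matrix and rbar = (r12 + r13)/2, referred to a t
#' distribution on n - 3 degrees of freedom. Swapping r12 and r13 negates
#' T2 and maps the upper-tail p to its complement.
#'
#' @param r12,r13,r23 correlations in \[-1, 1\]; the implied correlation
#'   matrix must be positive definite (|R| > 0).
#' @param n sample size (>= 4).
#' @return a \linkS4class{SteigerResult} with the upper-, lower- and
#'   |T2|-upper-tail probabilities.
#' @export
steigerTest <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23))
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  if (n < 4) stop("need n >= 4 (df = n - 3 >= 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  df <- n - 3
  if (detR <= 0) {
    if (r23 == 1 && r12 == r13) {
      warning("degenerate input: r23 = 1 with r12 = r13; returning T2 = 0")
      return(new("SteigerResult", t2 = 0, df = df, pUpper = 0.5,
                 pLower = 0.5, pAbsUpper = 0.5, r12 = r12, r13 = r13,
                 r23 = r23, n = n))
    }
    stop("implied correlation matrix is not positive definite (|R| = ",
         signif(detR, 4), ")")
  }
  rbar <- (r12 + r13) / 2
  t2 <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
          (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  new("SteigerResult", t2 = t2, df = df,
      pUpper = tTailP(t2, df), pLower = stats::pt(t2, df),
      pAbsUpper = tTailP(abs(t2), df),
      r12 = r12, r13 = r13, r23 = r23, n = n)
}

#' Steiger's test from raw prediction vectors
#'
#' Convenience wrapper that computes (r12, r13, r23) from the observed
#' scores and two prediction vectors, so callers cannot mismatch the
#' correlation ordering. T2 is invariant to affine rescaling of either
#' prediction vector.
#'
#' @param observed observed scores.
#' @param predA,predB predictions of the two models on the same subjects.
#' @return a \linkS4class{SteigerResult}.
#' @export
steigerFromPredictions <- function(observed, predA, predB) {
  n <- length(observed)
  if (length(predA) != n || length(predB) != n)
    stop("all three vectors must have equal length")
  steigerTest(stats::cor(observed, predA), stats::cor(observed, predB),
              stats::cor(predA, predB), n)
}
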