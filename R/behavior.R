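## Behavioral preprocessing: covariate residualization and rank-based
## inverse-normal (quantile) normalization.

#' Residualize behavioral measures against nuisance covariates
#'
#' Per-measure OLS residuals against an intercept plus the supplied
#' covariates (age, gender, race, education, mean FD in the standard
#' pipeline). Categorical covariates are one-hot encoded with the first
#' level dropped.
#'
#' @param Y subjects x measures numeric matrix.
#' @param covariates data.frame with one row per subject.
#' @return matrix of residuals, same shape as `Y`.
#' @export
residualize <- function(Y, covariates) {
  Y <- as.matrix(Y)
  if (nrow(covariates) != nrow(Y))
    stop("covariates must have one row per subject (subject mismatch)")
  if (anyNA(Y) || anyNA(covariates)) stop("missing values are not supported")
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate design matrix is rank deficient")
  Y - X %*% qr.coef(qrX, Y)
}

#' Rank-based inverse-normal (quantile) normalization
#'
#' Maps values to standard normal quantiles at `(rank - 0.5) / n`, with ties
#' receiving their average rank. Invariant to strictly monotone transforms
#' of the input.
#'
#' @param x numeric vector (at least 3 values, not all equal) or a matrix,
#'   normalized column-wise.
#' @return normalized vector or matrix.
#' @examples
#' quantileNormalize(c(3, 1, 2))  # ~ [0.967, -0.967, 0]
#' @export
quantileNormalize <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, quantileNormalize)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 values")
  if (anyNA(x)) stop("missing values are not supported")
  if (stats::sd(x) == 0) stop("constant column cannot be quantile normalized")
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

#' Prepare a behavioral matrix for variance component modelling
#'
#' Residualizes each measure against the subject covariates carried by the
#' object, then quantile normalizes each residualized column (in that
#' order). Categories and covariates are carried over.
#'
#' @param bm a [BehaviorMatrix-class] holding raw measures and covariates.
#' @return A [BehaviorMatrix-class] of processed measures.
#' @export
prepareBehavior <- function(bm) {
  stopifnot(is(bm, "BehaviorMatrix"))
  Y <- behaviorValues(bm)
  cov <- subjectCovariates(bm)
  Yr <- if (ncol(cov)) residualize(Y, cov) else scale(Y, scale = FALSE)
  Yq <- quantileNormalize(Yr)
  BehaviorMatrix(Yq, categories = measureCategories(bm),
                 covariates = if (ncol(cov)) cov else NULL,
                 groundTruth = groundTruth(bm))
}
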