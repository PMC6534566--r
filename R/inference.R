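## Delete-one jackknife engine, model comparison, measure ranking,
## Benjamini-Hochberg FDR, and block-pair contribution tests.

#' Delete-one jackknife of an arbitrary statistic
#'
#' Evaluates `statFun` on every leave-one-subject-out index set, and
#' aggregates: the jackknife estimate is the mean of the leave-one-out
#' values, its variance is `(n-1)/n * sum((v_i - mean)^2)`, and a two-tailed
#' p-value is obtained from the standard normal approximation of
#' `estimate / sqrt(variance)` under the null that the statistic is zero.
#'
#' @param statFun function taking an integer vector of retained subject
#'   indices and returning a numeric vector (or scalar) of statistics.
#' @param n number of subjects.
#' @return list with `estimate`, `variance`, `z`, `p` (each per statistic)
#'   and `leaveOne` (n x statistics matrix of leave-one-out values).
#' @examples
#' # jackknife of the sample mean reproduces the s^2/n variance
#' y <- c(1, 2, 3)
#' deleteOneJackknife(function(i) mean(y[i]), 3)$variance  # 1/3
#' @export
deleteOneJackknife <- function(statFun, n) {
  if (n < 2L) stop("need at least 2 subjects")
  first <- statFun(seq_len(n)[-1L])
  S <- length(first)
  vals <- matrix(NA_real_, n, S)
  colnames(vals) <- names(first)
  vals[1L, ] <- first
  for (i in seq_len(n)[-1L]) {
    vi <- tryCatch(statFun(seq_len(n)[-i]), error = function(e)
      stop("leave-one-out refit failed for subject ", i, ": ",
           conditionMessage(e)))
    vals[i, ] <- vi
  }
  est <- colMeans(vals)
  V <- (n - 1) / n * colSums(sweep(vals, 2, est)^2)
  z <- ifelse(V > 0, est / sqrt(V), ifelse(est == 0, 0, sign(est) * Inf))
  p <- ifelse(V > 0, 2 * stats::pnorm(-abs(z)), ifelse(est == 0, 1, 0))
  list(estimate = est, variance = V, z = z, p = p, leaveOne = vals)
}

.subsetKernels <- function(kernels, idx) {
  lapply(.asKernelList(kernels), function(Fk) Fk[idx, idx, drop = FALSE])
}

.jackAggregate <- function(v, n) {
  est <- mean(v)
  V <- (n - 1) / n * sum((v - est)^2)
  z <- if (V > 0) est / sqrt(V) else if (est == 0) 0 else sign(est) * Inf
  p <- if (V > 0) 2 * stats::pnorm(-abs(z)) else if (est == 0) 1 else 0
  list(estimate = est, variance = V, z = z, p = p)
}

#' Jackknife comparison of variance explained between two models
#'
#' For every leave-one-subject-out sample, both variance component models
#' are refitted (sub-kernels by row/column deletion, Y by row deletion) and
#' the differences in overall M and per-measure M_i (model A minus model B)
#' are recorded. The differences use the untruncated trace ratios: the
#' zero-truncation applied when reporting a single model's M is a
#' nonlinear operation whose bias does not cancel in differences (it
#' systematically favours the model with more components), whereas the raw
#' moment estimates are unbiased and their difference is centered under
#' equality of the models. The delete-one jackknife aggregate gives, for each
#' statistic, an estimate, a variance, a z statistic and a two-tailed normal
#' p-value. When categories are available, category contrasts (mean
#' per-measure difference over task measures, over self measures) and their
#' interaction (task mean minus self mean) are computed from the same
#' leave-one-out values; unclassified measures never enter the contrasts.
#'
#' @param Y a [BehaviorMatrix-class] or subjects x measures matrix
#'   (processed).
#' @param kernelsA,kernelsB kernel or list of kernels defining models A and
#'   B (e.g. dynamic vs static, or combined vs dynamic).
#' @param categories optional per-measure categories; taken from `Y` when it
#'   is a [BehaviorMatrix-class].
#' @return A [JackknifeComparison-class].
#' @export
jackknifeCompare <- function(Y, kernelsA, kernelsB, categories = NULL) {
  if (is(Y, "BehaviorMatrix")) {
    if (is.null(categories)) categories <- unname(measureCategories(Y))
    Y <- behaviorValues(Y)
  }
  Y <- as.matrix(Y)
  N <- nrow(Y)
  Q <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("measure_%02d", seq_len(Q))
  if (N < 30L)
    warning("fewer than 30 subjects: the normal approximation of the ",
            "jackknife z statistic may be unreliable")
  kA <- .asKernelList(kernelsA)
  kB <- .asKernelList(kernelsB)
  for (Fk in c(kA, kB))
    if (!all(dim(Fk) == c(N, N)))
      stop("kernels must be defined on the same subjects as Y")
  statFun <- function(idx) {
    fa <- fitVCM(Y[idx, , drop = FALSE], lapply(kA, function(Fk)
      Fk[idx, idx, drop = FALSE]))
    fb <- fitVCM(Y[idx, , drop = FALSE], lapply(kB, function(Fk)
      Fk[idx, idx, drop = FALSE]))
    c(M = fa@diagnostics$MRaw - fb@diagnostics$MRaw,
      fa@diagnostics$MiRaw - fb@diagnostics$MiRaw)
  }
  jk <- deleteOneJackknife(statFun, N)
  overall <- list(estimate = jk$estimate[1], variance = jk$variance[1],
                  z = jk$z[1], p = jk$p[1])
  pm <- data.frame(measure = colnames(Y),
                   dMi = jk$estimate[-1],
                   se = sqrt(jk$variance[-1]),
                   T = jk$z[-1],
                   p = jk$p[-1],
                   category = if (is.null(categories)) NA_character_
                              else categories,
                   stringsAsFactors = FALSE, row.names = NULL)
  contrasts <- data.frame()
  if (!is.null(categories) && any(categories %in% c("task", "self"))) {
    rows <- list()
    for (cc in c("task", "self")) {
      j <- which(categories == cc) + 1L
      if (length(j)) {
        agg <- .jackAggregate(rowMeans(jk$leaveOne[, j, drop = FALSE]), N)
        rows[[cc]] <- data.frame(contrast = paste0(cc, "_mean"),
                                 estimate = agg$estimate, se = sqrt(agg$variance),
                                 z = agg$z, p = agg$p)
      }
    }
    jt <- which(categories == "task") + 1L
    js <- which(categories == "self") + 1L
    if (length(jt) && length(js)) {
      inter <- rowMeans(jk$leaveOne[, jt, drop = FALSE]) -
               rowMeans(jk$leaveOne[, js, drop = FALSE])
      agg <- .jackAggregate(inter, N)
      rows$interaction <- data.frame(contrast = "interaction",
                                     estimate = agg$estimate,
                                     se = sqrt(agg$variance),
                                     z = agg$z, p = agg$p)
    }
    contrasts <- do.call(rbind, rows)
    rownames(contrasts) <- NULL
  }
  new("JackknifeComparison", overall = overall, perMeasure = pm,
      contrasts = contrasts, leaveOne = jk$leaveOne, nSubjects = as.integer(N))
}

#' Rank measures by how much better model A explains them
#'
#' Orders the per-measure T statistics of a [JackknifeComparison-class] in
#' descending order (ties broken alphabetically by measure name, so the
#' ordering is deterministic), keeping category labels attached.
#'
#' @param comparison a [JackknifeComparison-class].
#' @return data.frame with columns measure, T, dMi, se, p, category, rank.
#' @export
rankMeasures <- function(comparison) {
  stopifnot(is(comparison, "JackknifeComparison"))
  pm <- comparison@perMeasure
  o <- order(-pm$T, pm$measure)
  out <- pm[o, c("measure", "T", "dMi", "se", "p", "category")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure rejecting the hypotheses whose BH-adjusted p-value is
#' at most `q`.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return list with `reject` (logical), `adjusted` (BH-adjusted p-values)
#'   and `nRejected`.
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  reject <- adjusted <= q
  list(reject = reject, adjusted = adjusted, nRejected = sum(reject))
}

#' Block-pair contributions to kernel-explained behavioral covariance
#'
#' Using the additive decomposition of [blockDecompositionKernels()]
#' (`sum_b w_b F_b = F_std`), the contribution of block pair b is measured
#' by the weighted excess of kernel-aligned behavioral covariance over its
#' expectation under exchangeable subjects:
#' `s_b = w_b * mean_j (y_j' F_b y_j - y_j' y_j)` over the selected
#' measures j (entries re-standardized within every jackknife subsample, so
#' `Tr(F_b) = n - 1` and the null expectation is exactly `y_j' y_j`).
#' Contribution shares are the positive parts normalized to 1; each block's
#' statistic is tested with the delete-one jackknife and the resulting
#' two-tailed p-values are FDR-corrected.
#'
#' @param Y a [BehaviorMatrix-class] or subjects x measures matrix
#'   (processed).
#' @param decomposition output of [blockDecompositionKernels()].
#' @param measures optional character or integer selection of measures
#'   (e.g. the task measures); default all.
#' @param q FDR level for flagging contributing pairs.
#' @return data.frame: pair, weight, statistic, share, z, p, pAdjusted,
#'   significant.
#' @export
blockContributions <- function(Y, decomposition, measures = NULL, q = 0.05) {
  if (is(Y, "BehaviorMatrix")) Y <- behaviorValues(Y)
  Y <- as.matrix(Y)
  if (!is.null(measures)) Y <- Y[, measures, drop = FALSE]
  V <- decomposition$Z   # standardized on the full cohort; re-scaled per subsample
  labels <- decomposition$labels
  pairIds <- decomposition$pairs$pair
  N <- nrow(Y)
  if (nrow(V) != N) stop("decomposition and Y subject counts differ")
  cols <- lapply(pairIds, function(pid) which(labels == pid))
  P <- length(labels)
  statFun <- function(idx) {
    Z <- scale(V[idx, , drop = FALSE])
    sdZero <- attr(Z, "scaled:scale") == 0
    if (any(sdZero)) Z[, sdZero] <- 0
    Yc <- scale(Y[idx, , drop = FALSE], scale = FALSE)
    CT <- crossprod(Z, Yc)          # P x m
    yy <- colSums(Yc^2)
    s <- vapply(seq_along(pairIds), function(b) {
      cb <- cols[[b]]
      qf <- colSums(CT[cb, , drop = FALSE]^2) / length(cb)
      mean(qf - yy) * length(cb) / P
    }, numeric(1))
    names(s) <- pairIds
    s
  }
  jk <- deleteOneJackknife(statFun, N)
  pos <- pmax(jk$estimate, 0)
  share <- if (sum(pos) > 0) pos / sum(pos) else pos
  bh <- fdrBH(jk$p, q = q)
  data.frame(pair = pairIds, weight = decomposition$pairs$weight,
             statistic = unname(jk$estimate), share = unname(share),
             z = unname(jk$z), p = unname(jk$p),
             pAdjusted = unname(bh$adjusted),
             significant = unname(bh$reject),
             stringsAsFactors = FALSE, row.names = NULL)
}
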