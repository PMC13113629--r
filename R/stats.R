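## Nonparametric univariate statistics: Spearman correlation, Mann-Whitney
## U, Hodges-Lehmann estimation with Moses order-statistic CIs, Bonferroni
## correction, and ROC analysis with DeLong CIs and Youden operating points.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (Pearson correlation of the
#' rank vectors), on the pairwise-complete subset. The p-value is the
#' two-sided `stats::cor.test` value (exact for small untied samples,
#' t-approximation otherwise).
#'
#' @param x,y Paired numeric vectors; pairs with an `NA` are dropped.
#' @return A list with `rho`, `p`, `n` (pairs used). `rho` is `NA` when
#'   fewer than 3 pairs remain or either vector is constant.
#' @export
spearmanCor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  p <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 10 && !ties))$p.value)
  list(rho = rho, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration of the
#' U distribution) when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction is used. `U` is the U statistic of `x` (number of pairs with
#' `x > y`, ties counting one half), so `U_x + U_y = n1 * n2`.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exactLimit Combined sample size at or below which the exact
#'   distribution is used (no ties); default 20.
#' @return A list with `U`, `p`, `n1`, `n2`.
#' @examples
#' mannWhitney(1:3, 4:6)$p  # exact two-sided p = 0.1
#' @export
mannWhitney <- function(x, y, exactLimit = 20) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exactLimit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Hodges-Lehmann estimate of a location shift
#'
#' Median of all `n1 * n2` pairwise differences `x_i - y_j`; the robust
#' location-shift estimator paired with the Mann-Whitney test.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return The estimate, in the units of the data.
#' @examples
#' hodgesLehmann(c(1, 2, 3), 0)  # 2
#' @export
hodgesLehmann <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  median(as.vector(outer(x, y, "-")))
}

#' Moses order-statistic confidence interval for the Hodges-Lehmann shift
#'
#' Distribution-free CI built from the sorted pairwise differences
#' `D_(1) <= ... <= D_(N)`, `N = n1 * n2`: with `k` the largest integer
#' such that `P(U <= k) <= alpha/2`, the interval is
#' `(D_(k+1), D_(N-k))`. The null U distribution is exact (via
#' `stats::pwilcox`) when `N <= exactLimit`, else the normal approximation
#' with continuity correction. When even `k = 0` fails the tail condition
#' (tiny samples) the degenerate interval `(min D, max D)` is returned.
#' Both endpoints are elements of the pairwise-difference multiset, and
#' the interval is equivariant under adding a constant to both groups.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param level Confidence level in (0, 1); e.g. `1 - 0.05/23` for a
#'   Bonferroni-adjusted family of 23 parameters (displayed as 99.8%).
#' @param exactLimit Largest `N` for the exact U distribution; default 400.
#' @return A list with `low`, `high`, `level`, `k`.
#' @examples
#' hlConfidenceInterval(c(1, 2, 3), 0, level = 0.998)  # degenerate: (1, 3)
#' @export
hlConfidenceInterval <- function(x, y, level, exactLimit = 400) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  d <- sort(as.vector(outer(x, y, "-")))
  N <- n1 * n2
  alpha <- 1 - level
  if (N <= exactLimit) {
    ks <- 0:floor(N / 2)
    keep <- ks[pwilcox(ks, n1, n2) <= alpha / 2]
    k <- if (length(keep)) max(keep) else -1L
  } else {
    mu <- N / 2
    sd <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    k <- floor(mu - 0.5 + qnorm(alpha / 2) * sd)
    if (k >= 0 && pnorm((k + 0.5 - mu) / sd) > alpha / 2) k <- k - 1
  }
  if (k < 0) {
    return(list(low = d[1], high = d[N], level = level, k = -1L))
  }
  list(low = d[k + 1], high = d[N - k], level = level, k = as.integer(k))
}

#' Bonferroni adjustment
#'
#' `p_adjusted = min(1, factor * p_raw)`; monotone in the factor and never
#' above 1.
#'
#' @param pRaw Raw p-value(s).
#' @param factor Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(pRaw, factor) {
  if (factor < 1) stop("factor must be >= 1")
  pmin(1, factor * pRaw)
}

#' Bonferroni correction factors for the parameter inventory
#'
#' The single-vs-hybrid correlation matrix tests every single parameter
#' against every hybrid, so its family is `nSingle * nHybrid`; each
#' biomarker association family tests all parameters once, so its factor
#' is `nSingle + nHybrid`. With the default 9 + 14 inventory these are 126
#' and 23.
#'
#' @param nSingle Number of single-modality parameters; default 9.
#' @param nHybrid Number of hybrid parameters; default 14.
#' @return A list with `factorMatrix` and `factorBiomarker`.
#' @examples
#' correctionFactors(9, 14)  # 126 and 23
#' @export
correctionFactors <- function(nSingle = 9, nHybrid = 14) {
  list(factorMatrix = nSingle * nHybrid, factorBiomarker = nSingle + nHybrid)
}

# DeLong placement variance of the empirical AUC
.delongVar <- function(pos, neg) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(p) mean(psi(p, neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean(psi(pos, q)), numeric(1))
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

#' ROC analysis with DeLong CI and Youden operating point
#'
#' Empirical ROC of oriented scores (`orientation * score`, so that higher
#' oriented scores indicate the positive class): AUC by the trapezoidal
#' rule, its CI from the DeLong variance estimator, and the operating
#' cutoff maximizing the Youden index `J = sensitivity + specificity - 1`.
#' Candidate cutoffs are midpoints between adjacent distinct oriented
#' scores (plus below/above the whole range); ties in `J` are broken
#' toward higher sensitivity, then the lower cutoff. Sensitivity,
#' specificity, PPV and NPV at the cutoff are reported in percent. The
#' orientation is fixed by the caller (feature direction metadata), never
#' auto-flipped, so an AUC below 0.5 is possible and reported honestly.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector; `TRUE` is the positive class.
#' @param orientation +1 if higher scores indicate the positive class,
#'   -1 otherwise.
#' @param level Confidence level for the AUC CI; default 0.95.
#' @return A list with `auc`, `aucCiLow`, `aucCiHigh`, `cutoff` (on the
#'   oriented scale: predict positive when `orientation * score >=
#'   cutoff`), `sensitivity`, `specificity`, `ppv`, `npv` (percent),
#'   `orientation`, `nPos`, `nNeg`.
#' @export
rocAnalysis <- function(scores, labels, orientation = 1, level = 0.95) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) {
    stop("both classes must be present")
  }
  stopifnot(orientation %in% c(-1, 1))
  s <- orientation * scores
  pos <- s[labels]; neg <- s[!labels]
  nPos <- length(pos); nNeg <- length(neg)

  # trapezoidal AUC over the empirical ROC (equals the normalized U
  # statistic with ties counted one half)
  cuts <- sort(unique(s))
  mids <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2,
            cuts[length(cuts)] + 1)
  sens <- vapply(mids, function(ct) mean(pos >= ct), numeric(1))
  fpr <- vapply(mids, function(ct) mean(neg >= ct), numeric(1))
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)

  se <- sqrt(.delongVar(pos, neg))
  z <- qnorm(1 - (1 - level) / 2)
  ciLow <- max(0, auc - z * se)
  ciHigh <- min(1, auc + z * se)

  spec <- 1 - fpr
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(mids[best])]
  tp <- sum(pos >= mids[best]); fp <- sum(neg >= mids[best])
  fn <- nPos - tp; tn <- nNeg - fp
  list(
    auc = auc, aucCiLow = ciLow, aucCiHigh = ciHigh,
    cutoff = mids[best],
    sensitivity = 100 * tp / nPos,
    specificity = 100 * tn / nNeg,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    orientation = orientation, nPos = nPos, nNeg = nNeg
  )
}
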