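## The full univariate battery: correlations, group comparisons and ROC
## analyses of all 23 imaging parameters against the tissue biomarkers.

# the five contrasts; group1 is always the less aggressive class, matching
# the sign convention of the reported Hodges-Lehmann estimates
.batteryContrasts <- function() {
  list(
    list(name = "G1 vs G2", select = function(h) {
      list(g1 = h$grade == "G1", g2 = h$grade == "G2")
    }),
    list(name = "G1 vs G3", select = function(h) {
      list(g1 = h$grade == "G1", g2 = h$grade == "G3")
    }),
    list(name = "G2 vs G3", select = function(h) {
      list(g1 = h$grade == "G2", g2 = h$grade == "G3")
    }),
    list(name = "Ki67: positive vs negative", select = function(h) {
      list(g1 = !h$ki67_pos, g2 = h$ki67_pos)
    }),
    list(name = "Luminal A vs luminal B", select = function(h) {
      list(g1 = h$subtype == "luminalA", g2 = h$subtype == "luminalB")
    })
  )
}

#' Run the univariate statistical battery
#'
#' For every parameter of the 23-entry inventory this computes:
#' \itemize{
#'   \item Spearman correlations with the ER, PgR and Ki67 percentage
#'     values, Bonferroni-corrected with the biomarker family factor
#'     (9 + 14 = 23);
#'   \item the single-vs-hybrid Spearman correlation matrix (9 x 14 pairs),
#'     corrected with factor 126;
#'   \item Mann-Whitney comparisons for the five contrasts (G1 vs G2, G1 vs
#'     G3, G2 vs G3, Ki67 positive vs negative, luminal A vs luminal B)
#'     with factor-23 correction, plus the Hodges-Lehmann estimate and its
#'     Bonferroni-adjusted (99.8%) Moses CI; the estimate is
#'     (less-aggressive group) minus (more-aggressive group);
#'   \item ROC analyses of each contrast with the more aggressive class as
#'     positive and the orientation fixed by the feature direction
#'     metadata.
#' }
#' Pairs or lesions with invalid (`NA`) parameter values are dropped per
#' parameter (pairwise deletion). A contrast with fewer than 2 lesions in
#' either class is skipped with a warning.
#'
#' @param features Feature table from [extractFeatures()].
#' @param histopath Cohort table with derived columns (see
#'   [addHistopathDerived()]); matched to `features` by `lesion_id`.
#' @param ciLevel Confidence level of the Hodges-Lehmann CI; default the
#'   unrounded `1 - 0.05/23` (displayed as 99.8%).
#' @return A list of four `data.frame`s: `correlations`,
#'   `crossCorrelations`, `comparisons`, `roc`.
#' @export
runUnivariateBattery <- function(features, histopath,
                                 ciLevel = 1 - 0.05 / 23) {
  inv <- featureInventory()
  fac <- correctionFactors(sum(inv$kind == "single"),
                           sum(inv$kind == "hybrid"))
  h <- histopath[match(features$lesion_id, histopath$lesion_id), ,
                 drop = FALSE]
  stopifnot(!anyNA(h$lesion_id))

  ## correlations with ER/PgR/Ki67 percentages (factor 23)
  bio <- c(ER = "er_pct", PgR = "pgr_pct", Ki67 = "ki67_pct")
  corRows <- list()
  for (p in inv$name) {
    for (b in names(bio)) {
      sc <- spearmanCor(features[[p]], h[[bio[b]]])
      corRows[[length(corRows) + 1L]] <- data.frame(
        parameter = p, biomarker = b, rho = sc$rho, p_raw = sc$p,
        p_adjusted = bonferroni(sc$p, fac$factorBiomarker),
        correction_factor = fac$factorBiomarker, n = sc$n,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corRows)

  ## single-vs-hybrid correlation matrix (factor 126)
  xRows <- list()
  for (s in inv$name[inv$kind == "single"]) {
    for (hy in inv$name[inv$kind == "hybrid"]) {
      sc <- spearmanCor(features[[s]], features[[hy]])
      xRows[[length(xRows) + 1L]] <- data.frame(
        single = s, hybrid = hy, rho = sc$rho, p_raw = sc$p,
        p_adjusted = bonferroni(sc$p, fac$factorMatrix),
        correction_factor = fac$factorMatrix, n = sc$n,
        stringsAsFactors = FALSE)
    }
  }
  crossCorrelations <- do.call(rbind, xRows)

  ## group comparisons and ROC per contrast
  cmpRows <- list()
  rocRows <- list()
  for (ct in .batteryContrasts()) {
    gr <- ct$select(h)
    g1 <- which(!is.na(gr$g1) & gr$g1)
    g2 <- which(!is.na(gr$g2) & gr$g2)
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("contrast '", ct$name, "' skipped: a class has fewer than ",
              "2 lesions")
      next
    }
    for (i in seq_len(nrow(inv))) {
      p <- inv$name[i]
      x <- features[[p]][g1]   # less aggressive class first
      y <- features[[p]][g2]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2L || length(y) < 2L) next
      mw <- mannWhitney(x, y)
      ci <- hlConfidenceInterval(x, y, level = ciLevel)
      cmpRows[[length(cmpRows) + 1L]] <- data.frame(
        parameter = p, contrast = ct$name,
        n1 = length(x), n2 = length(y),
        U = mw$U, p_raw = mw$p,
        p_adjusted = bonferroni(mw$p, fac$factorBiomarker),
        hle = hodgesLehmann(x, y), ci_low = ci$low, ci_high = ci$high,
        ci_level = ciLevel, stringsAsFactors = FALSE)
      roc <- rocAnalysis(c(x, y),
                         c(rep(FALSE, length(x)), rep(TRUE, length(y))),
                         orientation = inv$direction[i])
      rocRows[[length(rocRows) + 1L]] <- data.frame(
        parameter = p, contrast = ct$name,
        auc = roc$auc, auc_ci_low = roc$aucCiLow,
        auc_ci_high = roc$aucCiHigh, cutoff = roc$cutoff,
        sensitivity = roc$sensitivity, specificity = roc$specificity,
        ppv = roc$ppv, npv = roc$npv, orientation = roc$orientation,
        stringsAsFactors = FALSE)
    }
  }
  list(
    correlations = correlations,
    crossCorrelations = crossCorrelations,
    comparisons = do.call(rbind, cmpRows),
    roc = do.call(rbind, rocRows)
  )
}
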