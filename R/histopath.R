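## Tissue-biomarker dichotomization and surrogate molecular subtype rules.

.SUBTYPES <- c("luminalA", "luminalB", "luminalB_her2pos", "triple_negative",
               "her2pos", "unclassified")

#' Dichotomize tissue biomarkers
#'
#' Applies the fixed cutoffs: ER and PgR are negative exactly when their
#' percentage equals 0; Ki67 is positive when >= 20%; HER2 is negative for
#' score 0 or 1+, positive for 3+, and resolved by FISH amplification for
#' 2+ (an unresolved 2+ leaves HER2 status, and hence the subtype,
#' undefined). Vectorized.
#'
#' @param erPct,pgrPct,ki67Pct Percentages in \[0, 100\].
#' @param her2Score Character vector with values `"0"`, `"1+"`, `"2+"`,
#'   `"3+"`.
#' @param fishAmplified Logical; only consulted where `her2Score == "2+"`.
#' @return A `data.frame` of logical flags `er_pos`, `pgr_pos`, `ki67_pos`,
#'   `her2_pos` (`her2_pos` is `NA` for an unresolved 2+).
#' @examples
#' dichotomize(80, 60, 20, "2+", fishAmplified = TRUE)$ki67_pos  # TRUE
#' @export
dichotomize <- function(erPct, pgrPct, ki67Pct, her2Score,
                        fishAmplified = NA) {
  pct <- c(erPct, pgrPct, ki67Pct)
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100)) {
    stop("percentage values must lie in [0, 100]")
  }
  if (!all(her2Score %in% c("0", "1+", "2+", "3+"))) {
    stop("her2Score must be one of 0, 1+, 2+, 3+")
  }
  n <- max(length(erPct), length(pgrPct), length(ki67Pct),
           length(her2Score))
  fishAmplified <- rep_len(as.logical(fishAmplified), n)
  her2Score <- rep_len(her2Score, n)
  her2 <- rep(NA, n)
  her2[her2Score %in% c("0", "1+")] <- FALSE
  her2[her2Score == "3+"] <- TRUE
  two <- her2Score == "2+"
  her2[two] <- fishAmplified[two]
  data.frame(
    er_pos = rep_len(erPct, n) > 0,
    pgr_pos = rep_len(pgrPct, n) > 0,
    ki67_pos = rep_len(ki67Pct, n) >= 20,
    her2_pos = her2
  )
}

#' Surrogate molecular subtype from dichotomized biomarkers
#'
#' Luminal A: ER and/or PgR positive, HER2 negative, Ki67 < 20%; luminal
#' B: the same with Ki67 >= 20%. The remaining classes follow the standard
#' surrogate conventions (luminal B HER2+: hormone-receptor positive and
#' HER2 positive; triple negative: all three negative; HER2+: hormone
#' receptors negative, HER2 positive); only luminal A and B enter the
#' statistical battery — the others are cohort bookkeeping. An undefined
#' HER2 status yields `"unclassified"`. Vectorized.
#'
#' @param erPos,pgrPos,ki67Pos,her2Pos Logical flags from [dichotomize()].
#' @return Factor with levels `luminalA`, `luminalB`, `luminalB_her2pos`,
#'   `triple_negative`, `her2pos`, `unclassified`.
#' @examples
#' surrogateSubtype(TRUE, TRUE, FALSE, FALSE)  # luminalA
#' surrogateSubtype(TRUE, TRUE, TRUE, FALSE)   # luminalB
#' @export
surrogateSubtype <- function(erPos, pgrPos, ki67Pos, her2Pos) {
  n <- max(length(erPos), length(pgrPos), length(ki67Pos), length(her2Pos))
  erPos <- rep_len(erPos, n); pgrPos <- rep_len(pgrPos, n)
  ki67Pos <- rep_len(ki67Pos, n); her2Pos <- rep_len(her2Pos, n)
  hr <- erPos | pgrPos
  out <- rep("unclassified", n)
  def <- !is.na(her2Pos)
  out[def & hr & !her2Pos & !ki67Pos] <- "luminalA"
  out[def & hr & !her2Pos & ki67Pos] <- "luminalB"
  out[def & hr & her2Pos] <- "luminalB_her2pos"
  out[def & !hr & !her2Pos] <- "triple_negative"
  out[def & !hr & her2Pos] <- "her2pos"
  factor(out, levels = .SUBTYPES)
}

#' Augment a cohort table with dichotomies and subtype
#'
#' Adds `er_pos`, `pgr_pos`, `ki67_pos`, `her2_pos` and `subtype` columns
#' derived from the raw histopathology fields (`er_pct`, `pgr_pct`,
#' `ki67_pct`, `her2_score`, `fish_amplified`).
#'
#' @param cohort Cohort `data.frame` (e.g. from [generateCohort()]).
#' @return The cohort with the derived columns appended.
#' @export
addHistopathDerived <- function(cohort) {
  fish <- if ("fish_amplified" %in% names(cohort)) {
    cohort$fish_amplified
  } else NA
  flags <- dichotomize(cohort$er_pct, cohort$pgr_pct, cohort$ki67_pct,
                       cohort$her2_score, fish)
  cohort[names(flags)] <- flags
  cohort$subtype <- surrogateSubtype(flags$er_pos, flags$pgr_pos,
                                     flags$ki67_pos, flags$her2_pos)
  cohort
}
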