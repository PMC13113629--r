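## End-to-end orchestration: generate -> quantify -> classify -> statistics,
## with lesion-level exclusion accounting.

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort, derives histopathology dichotomies and subtypes,
#' extracts the 23-parameter feature table (feature-level by default;
#' optionally through full image rendering, segmentation and per-modality
#' quantification), logs per-lesion exclusions with machine-readable
#' reasons, and runs the univariate statistical battery. Deterministic
#' under a fixed config seed.
#'
#' @param config A [SyntheticConfig-class].
#' @param outputDir Optional directory; when given, the cohort, feature and
#'   statistics tables are written as CSV together with the effective
#'   configuration.
#' @param renderVolumes If `TRUE`, features are extracted from rendered
#'   NIfTI-style volumes (40%-threshold PET VOI, TIC summary, ADC map)
#'   instead of the cohort's feature-level raw measurements. Slower; meant
#'   for end-to-end validation at small cohort sizes.
#' @param runStats Whether to run the statistical battery; default `TRUE`.
#' @return A list with `cohort`, `features`, `exclusions`, `flow` (the
#'   cohort flow summary), `stats` (see [runUnivariateBattery()]) and
#'   `config`.
#' @examples
#' run <- runPipeline(syntheticConfig(seed = 1, nLesions = 40))
#' run$flow$retained
#' @export
runPipeline <- function(config, outputDir = NULL, renderVolumes = FALSE,
                        runStats = TRUE) {
  stopifnot(is(config, "SyntheticConfig"))
  cohort <- generateCohort(config)
  cohort <- addHistopathDerived(cohort)

  if (renderVolumes) {
    inv <- featureInventory()
    rows <- list(); excl <- list()
    .withSeed(config@seed + 1, {
      for (r in seq_len(nrow(cohort))) {
        fv <- tryCatch({
          vols <- renderLesionVolumes(cohort[r, ], config)
          extractFeaturesFromVolumes(vols)
        }, petmriq_missing_modality = function(e) e)
        if (inherits(fv, "condition")) {
          excl[[length(excl) + 1L]] <- data.frame(
            lesion_id = cohort$lesion_id[r],
            reason = conditionMessage(fv), stringsAsFactors = FALSE)
        } else {
          row <- as.data.frame(as.list(fv$values))
          row$lesion_id <- cohort$lesion_id[r]
          row$curve_type <- fv$curveType
          rows[[length(rows) + 1L]] <- row
        }
      }
    })
    features <- do.call(rbind, rows)[, c("lesion_id", inv$name,
                                         "curve_type")]
    exclusions <- if (length(excl)) do.call(rbind, excl) else
      data.frame(lesion_id = character(0), reason = character(0))
  } else {
    ex <- extractFeatures(cohort)
    features <- ex$features
    exclusions <- ex$exclusions
  }

  flow <- cohortFlowSummary(exclusions, total = nrow(cohort))
  stats <- if (runStats && nrow(features) > 3L) {
    runUnivariateBattery(features,
                         cohort[cohort$lesion_id %in% features$lesion_id, ])
  } else NULL

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cohort, file.path(outputDir, "cohort.csv"), row.names = FALSE)
    write.csv(features, file.path(outputDir, "features.csv"),
              row.names = FALSE)
    write.csv(exclusions, file.path(outputDir, "exclusions.csv"),
              row.names = FALSE)
    if (!is.null(stats)) {
      write.csv(stats$correlations,
                file.path(outputDir, "correlations.csv"), row.names = FALSE)
      write.csv(stats$crossCorrelations,
                file.path(outputDir, "cross_correlations.csv"),
                row.names = FALSE)
      write.csv(stats$comparisons,
                file.path(outputDir, "comparisons.csv"), row.names = FALSE)
      write.csv(stats$roc, file.path(outputDir, "roc.csv"),
                row.names = FALSE)
    }
    writeRunConfig(config, file.path(outputDir, "config.txt"))
  }
  list(cohort = cohort, features = features, exclusions = exclusions,
       flow = flow, stats = stats, config = config)
}

#' Summarise the cohort selection flow
#'
#' Totals the per-lesion exclusions by reason and reports the retained
#' count, mirroring a patient-selection flowchart. Accepts either a
#' per-lesion exclusion table (`lesion_id`, `reason`) plus the input
#' total, or a named vector of exclusion counts.
#'
#' @param exclusions A `data.frame` with a `reason` column (one row per
#'   excluded lesion), or a named numeric vector of counts per reason.
#' @param total Number of lesions entering the flow.
#' @return A list with `total`, `excluded` (named counts), `retained`.
#' @examples
#' cohortFlowSummary(c(`inadequate fat suppression` = 26,
#'                     `not visible in DCE or in PET` = 6,
#'                     `incomplete histopathology` = 1), total = 192)
#' @export
cohortFlowSummary <- function(exclusions, total) {
  counts <- if (is.data.frame(exclusions)) {
    if (nrow(exclusions) == 0L) {
      setNames(integer(0), character(0))
    } else {
      tab <- table(exclusions$reason)
      setNames(as.integer(tab), names(tab))
    }
  } else {
    stopifnot(is.numeric(exclusions))
    exclusions
  }
  nExcl <- sum(counts)
  if (nExcl > total) stop("more exclusions than lesions")
  list(total = total, excluded = counts, retained = total - nExcl)
}

#' Write / read a flat key=value run configuration
#'
#' Serializes a [SyntheticConfig-class] so that a run is reproducible from
#' its persisted configuration.
#'
#' @param config A [SyntheticConfig-class].
#' @param file Path of the key=value text file.
#' @return `writeRunConfig` returns the path invisibly; `readRunConfig`
#'   returns the reconstructed [SyntheticConfig-class].
#' @export
writeRunConfig <- function(config, file) {
  stopifnot(is(config, "SyntheticConfig"))
  num <- function(x) paste(format(x, digits = 17, trim = TRUE),
                           collapse = ",")
  lines <- c(
    paste0("n_lesions=", num(config@nLesions)),
    paste0("grade_proportions=", num(config@gradeProportions)),
    paste0("tic_archetype_mix=", num(config@ticArchetypeMix)),
    paste0("ki67_suv_target_rho=", num(config@ki67SuvTargetRho)),
    paste0("ki67_adc_target_rho=", num(config@ki67AdcTargetRho)),
    paste0("subtype_auc_target=", num(config@subtypeAucTarget)),
    paste0("pet_noise_sd_scale=", num(config@petNoiseSdScale)),
    paste0("mr_rician_sigma=", num(config@mrRicianSigma)),
    paste0("phase_interval_s=", num(config@phaseIntervalS)),
    paste0("seed=", num(config@seed))
  )
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(vals) <- keys
  if (is.null(vals$seed)) stop("config file must set seed")
  argMap <- c(seed = "seed", nLesions = "n_lesions",
              gradeProportions = "grade_proportions",
              ticArchetypeMix = "tic_archetype_mix",
              ki67SuvTargetRho = "ki67_suv_target_rho",
              ki67AdcTargetRho = "ki67_adc_target_rho",
              subtypeAucTarget = "subtype_auc_target",
              petNoiseSdScale = "pet_noise_sd_scale",
              mrRicianSigma = "mr_rician_sigma",
              phaseIntervalS = "phase_interval_s")
  args <- vals[argMap[argMap %in% names(vals)]]
  names(args) <- names(argMap)[argMap %in% names(vals)]
  do.call(syntheticConfig, args)
}
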