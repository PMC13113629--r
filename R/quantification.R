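#' TICSummary: per-phase mean signal intensities of a lesion VOI
#'
#' Mean DCE signal intensity inside the VOI at each of the six phases
#' (`si[1]` = pre-contrast SI0, `si[6]` = fifth post-contrast SI5) and the
#' peak, i.e. the maximum of the six phase means.
#'
#' @slot si Numeric length-6: SI0 ... SI5 (arbitrary units), all finite.
#' @slot siPeak Maximum of `si`.
#' @export
setClass("TICSummary", representation(si = "numeric", siPeak = "numeric"))

setValidity("TICSummary", function(object) {
  if (length(object@si) != 6L || any(!is.finite(object@si))) {
    return("si must be 6 finite phase means (SI0..SI5)")
  }
  if (!isTRUE(all.equal(object@siPeak, max(object@si)))) {
    return("siPeak must equal max(si)")
  }
  TRUE
})

#' Construct a TICSummary from six phase means
#'
#' @param si Numeric length-6, SI0 ... SI5.
#' @return A [TICSummary-class].
#' @export
TICSummary <- function(si) {
  si <- as.numeric(si)
  new("TICSummary", si = si, siPeak = max(si))
}

setMethod("show", "TICSummary", function(object) {
  cat("TICSummary: SI0..SI5 =", paste(format(object@si, digits = 4),
                                      collapse = ", "),
      sprintf("(peak %.4g)\n", object@siPeak))
  invisible(NULL)
})

.ticVec <- function(t) {
  if (is(t, "TICSummary")) t@si
  else if (is.numeric(t) && length(t) == 6L) as.numeric(t)
  else stop("expected a TICSummary or a numeric vector of 6 phase means")
}

#' Summarise a DCE time-intensity curve over a lesion VOI
#'
#' Computes the mean signal intensity inside the mask for each of the six
#' DCE phases and the peak over all six phases (pre-contrast included).
#'
#' @param series A [DceSeries-class].
#' @param mask A [LesionMask-class] on the series grid.
#' @return A [TICSummary-class].
#' @export
ticSummary <- function(series, mask) {
  stopifnot(is(series, "DceSeries"), is(mask, "LesionMask"))
  if (!.sameGrid(series@phases[[1]], mask)) {
    stop("mask must live on the DCE grid")
  }
  if (!any(mask@data)) stop("empty mask")
  si <- vapply(series@phases, function(p) mean(p@data[mask@data]),
               numeric(1))
  TICSummary(si)
}

#' Semi-quantitative DCE time-intensity-curve parameters
#'
#' The five TIC descriptors computed from the six phase means SI0 ... SI5:
#' \describe{
#'   \item{`e1`}{first post-contrast enhancement percentage,
#'     `100 (SI1 - SI0) / SI0`; invalid when SI0 = 0.}
#'   \item{`eser`}{early signal enhancement ratio,
#'     `100 (SI1 - SI0) / (SI2 - SI0)`; invalid when SI2 = SI0.}
#'   \item{`ticSlope`}{late slope percentage,
#'     `100 (SI5 - mean(SI1, SI2)) / mean(SI1, SI2)`; invalid when
#'     mean(SI1, SI2) = 0.}
#'   \item{`sper`}{signal peak enhancement ratio,
#'     `(SIpeak - SI0) / (SI5 - SI0)` with the peak taken over all six
#'     phases; invalid when SI5 = SI0.}
#'   \item{`sfer`}{signal first enhancement ratio,
#'     `(SI1 - SI0) / (SI5 - SI0)`; invalid when SI5 = SI0.}
#' }
#' Invalid values are returned as `NA` rather than clamped; all five are
#' invariant to a common rescaling of the six phase means.
#'
#' @param t A [TICSummary-class] or numeric vector of 6 phase means.
#' @return A single numeric value (`NA` when the denominator degenerates).
#' @examples
#' tic <- TICSummary(c(100, 180, 200, 190, 185, 180))
#' e1(tic)    # 80
#' sper(tic)  # 1.25
#' @name dce-parameters
NULL

#' @rdname dce-parameters
#' @export
e1 <- function(t) {
  si <- .ticVec(t)
  if (si[1] == 0) return(NA_real_)
  100 * (si[2] - si[1]) / si[1]
}

#' @rdname dce-parameters
#' @export
eser <- function(t) {
  si <- .ticVec(t)
  if (si[3] == si[1]) return(NA_real_)
  100 * (si[2] - si[1]) / (si[3] - si[1])
}

#' @rdname dce-parameters
#' @export
ticSlope <- function(t) {
  si <- .ticVec(t)
  m <- mean(si[2:3])
  if (m == 0) return(NA_real_)
  100 * (si[6] - m) / m
}

#' @rdname dce-parameters
#' @export
sper <- function(t) {
  si <- .ticVec(t)
  if (si[6] == si[1]) return(NA_real_)
  (max(si) - si[1]) / (si[6] - si[1])
}

#' @rdname dce-parameters
#' @export
sfer <- function(t) {
  si <- .ticVec(t)
  if (si[6] == si[1]) return(NA_real_)
  (si[2] - si[1]) / (si[6] - si[1])
}

#' Classify a time-intensity curve by its late slope
#'
#' Wash-out if the slope is below -10%, plateau if it lies in the closed
#' interval \[-10, 10\]%, persistent if above 10%. The closed plateau
#' boundaries make the three classes a total partition of the finite
#' slopes; an invalid (`NA`) slope is unclassified.
#'
#' @param slopeValue Slope in percent (from [ticSlope()]).
#' @return `"wash-out"`, `"plateau"`, `"persistent"`, or `NA` for an
#'   invalid slope.
#' @examples
#' classifyTic(-15)  # wash-out
#' classifyTic(-10)  # plateau (boundary is closed)
#' @export
classifyTic <- function(slopeValue) {
  ifelse(!is.finite(slopeValue), NA_character_,
    ifelse(slopeValue < -10, "wash-out",
      ifelse(slopeValue <= 10, "plateau", "persistent")))
}

#' All five DCE parameters plus the curve type
#'
#' @param t A [TICSummary-class] or numeric vector of 6 phase means.
#' @return A list with `e1`, `eser`, `slope`, `sper`, `sfer` (each `NA`
#'   when invalid) and `curveType`.
#' @export
dceParams <- function(t) {
  s <- ticSlope(t)
  list(e1 = e1(t), eser = eser(t), slope = s, sper = sper(t),
       sfer = sfer(t), curveType = classifyTic(s))
}

#' PET SUV statistics over a VOI
#'
#' @param pet A `PET_SUV` [ImageVolume-class].
#' @param mask A [LesionMask-class] on the PET grid.
#' @return A list with `suvMax` and `suvMean`.
#' @export
petParams <- function(pet, mask) {
  stopifnot(is(pet, "ImageVolume"), is(mask, "LesionMask"))
  if (!.sameGrid(pet, mask)) stop("mask must live on the PET grid")
  if (!any(mask@data)) stop("empty mask")
  v <- pet@data[mask@data]
  list(suvMax = max(v), suvMean = mean(v))
}

#' ADC statistics over a VOI
#'
#' Minimum and mean ADC over the valid (non-`NA`) voxels of the VOI.
#' A VOI with no valid ADC voxel cannot be quantified: a classed error
#' (`petmriq_no_valid_adc`) is raised so callers can flag the lesion as
#' excluded.
#'
#' @param adc An `ADC` [ImageVolume-class] (from [adcMap()]).
#' @param mask A [LesionMask-class] on the ADC grid.
#' @return A list with `adcMin` and `adcMean` (10^-6 mm^2/s).
#' @export
adcParams <- function(adc, mask) {
  stopifnot(is(adc, "ImageVolume"), is(mask, "LesionMask"))
  if (!.sameGrid(adc, mask)) stop("mask must live on the ADC grid")
  if (!any(mask@data)) stop("empty mask")
  v <- adc@data[mask@data]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop(structure(class = c("petmriq_no_valid_adc", "error", "condition"),
                   list(message = "no valid ADC voxel in the VOI",
                        call = sys.call())))
  }
  list(adcMin = min(v), adcMean = mean(v))
}

#' Standardized uptake value from activity concentration
#'
#' Body-weight-normalized SUV: `conc * weight / injected`, with activity
#' concentration in kBq/mL, injected dose in MBq and body weight in kg
#' (the kBq/MBq and g/mL unit conventions cancel).
#'
#' @param conc Activity concentration, kBq/mL.
#' @param injected Injected dose, MBq.
#' @param weight Body weight, kg.
#' @return SUV (dimensionless).
#' @examples
#' suvFromActivity(5, 250, 70)  # 1.4
#' @export
suvFromActivity <- function(conc, injected, weight) {
  if (any(conc <= 0) || any(injected <= 0) || any(weight <= 0)) {
    stop("conc, injected and weight must all be positive")
  }
  conc * weight / injected
}

#' The 23-parameter imaging-biomarker inventory
#'
#' Names, kind (single-modality or hybrid) and direction metadata of the 9
#' single and 14 hybrid PET/MRI parameters. Direction is +1 when higher
#' values indicate malignancy/aggressiveness and -1 otherwise; it is -1
#' exactly for `ADCmin` and `ADCmean` (diffusion restriction lowers ADC in
#' aggressive tissue) and +1 for every other parameter. The hybrid rule
#' multiplies SUV by the DCE parameters that increase with enhancement
#' (E1, ESER, SPER, SFER) and divides SUV by those that decrease (Slope,
#' ADCmin, ADCmean).
#'
#' @return A `data.frame` with columns `name`, `label`, `kind`
#'   (`"single"`/`"hybrid"`) and `direction` (+1/-1); 23 rows.
#' @examples
#' table(featureInventory()$kind)  # 14 hybrid, 9 single
#' @export
featureInventory <- function() {
  singles <- data.frame(
    name = c("SUVmax", "SUVmean", "E1", "ESER", "Slope", "SPER", "SFER",
             "ADCmin", "ADCmean"),
    label = c("SUVmax", "SUVmean", "E1", "ESER", "Slope", "SPER", "SFER",
              "ADCmin", "ADCmean"),
    kind = "single",
    stringsAsFactors = FALSE
  )
  suv <- c("SUVmax", "SUVmean")
  prod <- c("E1", "ESER", "SPER", "SFER")
  hybNames <- c(
    paste0(rep(suv, times = 2), "_x_", rep(prod[1:2], each = 2)),
    paste0(suv, "_over_Slope"),
    paste0(rep(suv, times = 2), "_x_", rep(prod[3:4], each = 2)),
    paste0(rep(suv, times = 2), "_over_", rep(c("ADCmin", "ADCmean"),
                                              each = 2))
  )
  hybLabels <- gsub("_x_", " x ", gsub("_over_", " / ", hybNames))
  hybrids <- data.frame(name = hybNames, label = hybLabels, kind = "hybrid",
                        stringsAsFactors = FALSE)
  inv <- rbind(singles, hybrids)
  inv$direction <- ifelse(inv$name %in% c("ADCmin", "ADCmean"), -1L, 1L)
  inv
}

.FEATURE_NAMES <- featureInventory()$name

#' Construct the 14 hybrid PET/MRI parameters
#'
#' Products of SUV with the enhancement-increasing DCE parameters and
#' ratios of SUV to the decreasing ones (Slope, ADCmin, ADCmean). An
#' invalid (`NA`) component, or a zero divisor, makes the corresponding
#' hybrid invalid.
#'
#' @param pet List with `suvMax`, `suvMean` (from [petParams()]).
#' @param dce List from [dceParams()].
#' @param adc List with `adcMin`, `adcMean` (from [adcParams()]).
#' @return Named numeric vector of the 14 hybrid values.
#' @export
hybridParams <- function(pet, dce, adc) {
  safeDiv <- function(num, den) {
    ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
  }
  c(
    SUVmax_x_E1 = pet$suvMax * dce$e1,
    SUVmean_x_E1 = pet$suvMean * dce$e1,
    SUVmax_x_ESER = pet$suvMax * dce$eser,
    SUVmean_x_ESER = pet$suvMean * dce$eser,
    SUVmax_over_Slope = safeDiv(pet$suvMax, dce$slope),
    SUVmean_over_Slope = safeDiv(pet$suvMean, dce$slope),
    SUVmax_x_SPER = pet$suvMax * dce$sper,
    SUVmean_x_SPER = pet$suvMean * dce$sper,
    SUVmax_x_SFER = pet$suvMax * dce$sfer,
    SUVmean_x_SFER = pet$suvMean * dce$sfer,
    SUVmax_over_ADCmin = safeDiv(pet$suvMax, adc$adcMin),
    SUVmean_over_ADCmin = safeDiv(pet$suvMean, adc$adcMin),
    SUVmax_over_ADCmean = safeDiv(pet$suvMax, adc$adcMean),
    SUVmean_over_ADCmean = safeDiv(pet$suvMean, adc$adcMean)
  )
}

#' Assemble the 23-entry feature vector for one lesion
#'
#' Combines the PET, DCE and ADC measurements of a lesion into the full
#' parameter inventory. A lesion missing a whole modality cannot enter the
#' analysis: a classed error (`petmriq_missing_modality`) carrying the
#' exclusion reason is raised.
#'
#' @param pet List with `suvMax`, `suvMean`, or `NULL` if the lesion is not
#'   visible on PET.
#' @param tic A [TICSummary-class] / numeric length-6, or `NULL` if not
#'   visible on DCE.
#' @param adc List with `adcMin`, `adcMean`, or `NULL` if DWI was unusable.
#' @return A list with `values` (named numeric length-23), `valid`
#'   (logical length-23) and `curveType`.
#' @export
assembleFeatures <- function(pet, tic, adc) {
  if (is.null(pet) || is.null(tic)) {
    stop(structure(class = c("petmriq_missing_modality", "error",
                             "condition"),
                   list(message = "lesion not visible in DCE or in PET",
                        call = sys.call())))
  }
  if (is.null(adc)) {
    stop(structure(class = c("petmriq_missing_modality", "error",
                             "condition"),
                   list(message = "unusable DW images",
                        call = sys.call())))
  }
  d <- dceParams(tic)
  singles <- c(SUVmax = pet$suvMax, SUVmean = pet$suvMean,
               E1 = d$e1, ESER = d$eser, Slope = d$slope, SPER = d$sper,
               SFER = d$sfer, ADCmin = adc$adcMin, ADCmean = adc$adcMean)
  values <- c(singles, hybridParams(pet, d, adc))
  stopifnot(identical(names(values), .FEATURE_NAMES))
  list(values = values, valid = !is.na(values), curveType = d$curveType)
}

#' Extract the feature table from cohort raw measurements
#'
#' Applies [assembleFeatures()] to every lesion of a cohort table carrying
#' feature-level raw measurements (`suv_max`, `suv_mean`, `adc_min`,
#' `adc_mean`, `si0` ... `si5`, as produced by [generateCohort()]).
#' Lesions with a missing modality (any `NA` SUV, TIC or ADC block) are
#' excluded with a reason instead of failing the run.
#'
#' @param cohort Cohort `data.frame`.
#' @return A list with `features` (data.frame: `lesion_id`, 23 parameter
#'   columns, `curve_type`) and `exclusions` (data.frame: `lesion_id`,
#'   `reason`).
#' @export
extractFeatures <- function(cohort) {
  siCols <- paste0("si", 0:5)
  stopifnot(all(c("lesion_id", "suv_max", "suv_mean", "adc_min", "adc_mean",
                  siCols) %in% names(cohort)))
  inv <- featureInventory()
  n <- nrow(cohort)
  vals <- matrix(NA_real_, n, nrow(inv), dimnames = list(NULL, inv$name))
  curveType <- character(n)
  keep <- logical(n)
  excl <- list()
  siMat <- as.matrix(cohort[siCols])
  for (r in seq_len(n)) {
    si <- siMat[r, ]
    pet <- if (anyNA(c(cohort$suv_max[r], cohort$suv_mean[r]))) NULL else
      list(suvMax = cohort$suv_max[r], suvMean = cohort$suv_mean[r])
    tic <- if (anyNA(si)) NULL else si
    adc <- if (anyNA(c(cohort$adc_min[r], cohort$adc_mean[r]))) NULL else
      list(adcMin = cohort$adc_min[r], adcMean = cohort$adc_mean[r])
    fv <- tryCatch(assembleFeatures(pet, tic, adc),
                   petmriq_missing_modality = function(e) e)
    if (inherits(fv, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        lesion_id = cohort$lesion_id[r], reason = conditionMessage(fv),
        stringsAsFactors = FALSE)
      next
    }
    vals[r, ] <- fv$values
    curveType[r] <- fv$curveType
    keep[r] <- TRUE
  }
  features <- cbind(
    data.frame(lesion_id = cohort$lesion_id[keep],
               stringsAsFactors = FALSE),
    as.data.frame(vals[keep, , drop = FALSE]))
  features$curve_type <- curveType[keep]
  rownames(features) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(lesion_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(features = features, exclusions = exclusions)
}

#' Extract one lesion's features from rendered volumes
#'
#' Image-level feature extraction: PET statistics over the 40%-threshold
#' VOI seeded by the truth mask, TIC summary and ADC statistics over the
#' truth mask (the modalities are scanner-co-registered, so mask transfer
#' is the identity).
#'
#' @param volumes List as returned by [renderLesionVolumes()] (elements
#'   `pet`, `dce`, `dwiB0`, `dwiB1000`, `mask`).
#' @param thresholdFraction PET segmentation threshold; default 0.40.
#' @return As [assembleFeatures()], plus the PET VOI under `petVoi`.
#' @export
extractFeaturesFromVolumes <- function(volumes, thresholdFraction = 0.40) {
  voi <- segmentPetVoi(volumes$pet, searchRegion = volumes$mask,
                       thresholdFraction = thresholdFraction)
  pet <- petParams(volumes$pet, voi)
  tic <- ticSummary(volumes$dce, volumes$mask)
  adc <- adcParams(adcMap(volumes$dwiB0, volumes$dwiB1000), volumes$mask)
  out <- assembleFeatures(pet, tic, adc)
  out$petVoi <- voi
  out
}
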