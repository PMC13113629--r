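#' SyntheticConfig: parameters of the synthetic PET/MRI cohort generator
#'
#' Configuration for [generateCohort()] and [renderLesionVolumes()]. The
#' defaults emulate the composition of the study cohort this package's
#' analysis battery is designed for: 159 invasive ductal carcinoma lesions
#' with grade proportions 52/76/31, a Ki67 marginal dichotomizing to 44.7%
#' positive at the 20% cutoff, near-saturated ER/PgR positivity, rare HER2
#' 3+, a rank correlation of 0.4607 between Ki67 and SUVmean and -0.2833
#' between Ki67 and ADCmin, and 90 s DCE phase spacing.
#'
#' @slot nLesions Number of lesions to generate (>= 2).
#' @slot gradeProportions Probabilities of grades G1, G2, G3 (sum to 1).
#' @slot ticArchetypeMix Probabilities of the wash-out, plateau and
#'   persistent time-intensity-curve archetypes (sum to 1).
#' @slot ki67SuvTargetRho Target Spearman correlation between Ki67 % and
#'   SUVmean, in \[-1, 1\].
#' @slot ki67AdcTargetRho Target Spearman correlation between Ki67 % and
#'   ADCmin, in \[-1, 1\].
#' @slot subtypeAucTarget Target AUC of an SUV-type score for luminal A vs
#'   luminal B, in (0.5, 1). The latent structure implied by
#'   `ki67SuvTargetRho` already yields ~0.72; an extra shift is applied only
#'   if the requested target exceeds the implied value.
#' @slot petNoiseSdScale PET noise level: Gaussian SD per voxel is
#'   `petNoiseSdScale * sqrt(signal)` (SUV units).
#' @slot mrRicianSigma Rician noise sigma for all MR volumes (signal units).
#' @slot phaseIntervalS Seconds between DCE phases.
#' @slot seed Integer RNG seed (mandatory; fixed seed implies byte-identical
#'   output).
#' @export
setClass("SyntheticConfig",
  representation(
    nLesions = "numeric",
    gradeProportions = "numeric",
    ticArchetypeMix = "numeric",
    ki67SuvTargetRho = "numeric",
    ki67AdcTargetRho = "numeric",
    subtypeAucTarget = "numeric",
    petNoiseSdScale = "numeric",
    mrRicianSigma = "numeric",
    phaseIntervalS = "numeric",
    seed = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  if (object@nLesions < 2) return("nLesions must be >= 2")
  for (nm in c("gradeProportions", "ticArchetypeMix")) {
    p <- slot(object, nm)
    if (length(p) != 3L || any(p < 0)) {
      return(sprintf("%s must be 3 non-negative probabilities", nm))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      return(sprintf("%s must sum to 1 (within 1e-9)", nm))
    }
  }
  for (nm in c("ki67SuvTargetRho", "ki67AdcTargetRho")) {
    r <- slot(object, nm)
    if (abs(r) > 1) return(sprintf("%s must lie in [-1, 1]", nm))
  }
  if (object@subtypeAucTarget <= 0.5 || object@subtypeAucTarget >= 1) {
    return("subtypeAucTarget must lie in (0.5, 1)")
  }
  if (object@petNoiseSdScale < 0 || object@mrRicianSigma < 0) {
    return("noise scales must be non-negative")
  }
  if (object@phaseIntervalS <= 0) return("phaseIntervalS must be positive")
  if (length(object@seed) != 1L || !is.finite(object@seed) ||
      object@seed != round(object@seed)) {
    return("seed must be a single integer")
  }
  TRUE
})

# latent loading of Ki67 on the shared aggressiveness axis; the rank-
# correlation targets are converted to latent Pearson correlations via the
# bivariate-normal identity rho_latent = 2 sin(pi * rho_spearman / 6) and
# split between the Ki67 channel (.KI67_LOADING) and the SUV/ADC channels.
.KI67_LOADING <- 0.8
.KI67_POS_RATE <- 71 / 159      # Ki67 >= 20% rate the marginal is pinned to
.KI67_CUTOFF <- 20
.KI67_CV <- 14.3 / 21           # coefficient of variation of the Ki67 marginal

.latentRho <- function(spearman) 2 * sin(pi * spearman / 6)

# log-normal Ki67 marginal: sigma from the reported cv, mu pinned so that
# P(Ki67 >= 20) equals the reported positive rate
.ki67Marginal <- function() {
  sigma <- sqrt(log(1 + .KI67_CV^2))
  mu <- log(.KI67_CUTOFF) - sigma * qnorm(1 - .KI67_POS_RATE)
  list(mu = mu, sigma = sigma)
}

# analytic luminal A vs B AUC of an SUV-type latent score given the latent
# correlation rho between the Ki67 and SUV channels (normal approximation
# within the two Ki67-truncated groups)
.impliedSubtypeAuc <- function(rho, delta = 0) {
  q <- qnorm(1 - .KI67_POS_RATE)
  mPos <- dnorm(q) / (1 - pnorm(q))
  mNeg <- -dnorm(q) / pnorm(q)
  vPos <- 1 + q * mPos - mPos^2
  vNeg <- 1 - q * (dnorm(q) / pnorm(q)) - mNeg^2
  sPooled <- sqrt(rho^2 * (vPos + vNeg) + 2 * (1 - rho^2))
  list(auc = pnorm((rho * (mPos - mNeg) + delta) / sPooled),
       shift = mPos - mNeg, sd = sPooled)
}

#' Construct a SyntheticConfig
#'
#' @param seed Integer RNG seed (mandatory).
#' @param nLesions Cohort size; default 159.
#' @param gradeProportions G1/G2/G3 probabilities; default `c(52, 76, 31)/159`.
#' @param ticArchetypeMix Wash-out/plateau/persistent probabilities; default
#'   `c(0.38, 0.23, 0.39)` (0.39 matching the 62/159 persistent rate the
#'   battery must tolerate; the wash-out/plateau split is a typical
#'   malignant-lesion choice).
#' @param ki67SuvTargetRho Target Spearman(Ki67, SUVmean); default 0.4607.
#' @param ki67AdcTargetRho Target Spearman(Ki67, ADCmin); default -0.2833.
#' @param subtypeAucTarget Target luminal A vs B AUC; default 0.720.
#' @param petNoiseSdScale PET noise scale; default 0.1.
#' @param mrRicianSigma MR Rician sigma; default 10 (baseline SI ~300, i.e.
#'   SNR ~30).
#' @param phaseIntervalS DCE phase interval in seconds; default 90.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(seed = 1, nLesions = 20)
#' cohort <- generateCohort(cfg)
#' table(cohort$grade)
#' @export
syntheticConfig <- function(seed,
                            nLesions = 159,
                            gradeProportions = c(52, 76, 31) / 159,
                            ticArchetypeMix = c(0.38, 0.23, 0.39),
                            ki67SuvTargetRho = 0.4607,
                            ki67AdcTargetRho = -0.2833,
                            subtypeAucTarget = 0.720,
                            petNoiseSdScale = 0.1,
                            mrRicianSigma = 10,
                            phaseIntervalS = 90) {
  if (missing(seed)) stop("seed is mandatory")
  new("SyntheticConfig",
      nLesions = nLesions, gradeProportions = gradeProportions,
      ticArchetypeMix = ticArchetypeMix,
      ki67SuvTargetRho = ki67SuvTargetRho,
      ki67AdcTargetRho = ki67AdcTargetRho,
      subtypeAucTarget = subtypeAucTarget,
      petNoiseSdScale = petNoiseSdScale, mrRicianSigma = mrRicianSigma,
      phaseIntervalS = phaseIntervalS, seed = seed)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Generate a synthetic lesion cohort
#'
#' Draws a cohort of latent lesions and their feature-level raw measurements.
#' A single latent aggressiveness score per lesion drives tumour grade
#' (thresholded noisy copy), the Ki67 proliferation index (log-normal
#' marginal), SUV (log-linear increasing) and the ADC floor (linear
#' decreasing); the latent loadings are chosen so that the configured
#' Spearman targets are met in expectation. ER/PgR are near-saturated
#' positive, HER2 3+ is rare, and the time-intensity-curve archetype is
#' drawn independently of aggressiveness (no DCE effect is encoded).
#'
#' @param config A [SyntheticConfig-class].
#' @return A `data.frame` with one row per lesion: identifiers, latent
#'   fields (`aggressiveness`, `grade`, `tic_archetype`, `true_suv_peak`,
#'   `true_adc_floor`), histopathology (`ki67_pct`, `er_pct`, `pgr_pct`,
#'   `her2_score`, `fish_amplified`), and raw imaging measurements
#'   (`suv_max`, `suv_mean`, `adc_min`, `adc_mean`, `si0` ... `si5`).
#' @examples
#' cohort <- generateCohort(syntheticConfig(seed = 7, nLesions = 50))
#' cor(cohort$ki67_pct, cohort$suv_mean, method = "spearman")
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  rho1 <- .latentRho(config@ki67SuvTargetRho)
  rho2 <- .latentRho(config@ki67AdcTargetRho)
  if (max(abs(rho1), abs(rho2)) > .KI67_LOADING) {
    stop("correlation target too large for the latent model (|2 sin(pi r/6)| ",
         "must not exceed ", .KI67_LOADING, ")")
  }
  if (any(config@gradeProportions == 0)) {
    stop("degenerate config: a grade proportion of 0 is incompatible with ",
         "the grade effect built into the latent model")
  }
  n <- as.integer(config@nLesions)
  .withSeed(config@seed, {
    a <- rnorm(n)                        # shared aggressiveness axis

    # grade: noisy copy of the axis cut at the configured proportions
    gGamma <- 0.7
    gz <- gGamma * a + sqrt(1 - gGamma^2) * rnorm(n)
    cuts <- qnorm(cumsum(config@gradeProportions)[1:2])
    grade <- factor(ifelse(gz < cuts[1], "G1",
                    ifelse(gz < cuts[2], "G2", "G3")),
                    levels = c("G1", "G2", "G3"))

    # correlated latent channels
    lamK <- .KI67_LOADING
    zK <- lamK * a + sqrt(1 - lamK^2) * rnorm(n)
    lamS <- rho1 / lamK
    zS <- lamS * a + sqrt(max(0, 1 - lamS^2)) * rnorm(n)
    lamA <- rho2 / lamK
    zA <- lamA * a + sqrt(max(0, 1 - lamA^2)) * rnorm(n)

    marg <- .ki67Marginal()
    ki67 <- pmin(100, exp(marg$mu + marg$sigma * zK))

    # optional extra luminal-B separation beyond what the correlation
    # structure already implies (delta floored at zero)
    imp <- .impliedSubtypeAuc(rho1)
    delta <- max(0, imp$sd * qnorm(config@subtypeAucTarget) -
                    rho1 * imp$shift)
    zS <- zS + delta * (ki67 >= .KI67_CUTOFF)

    # SUV: log-linear in the SUV channel; SUVmean is the exact monotone
    # transform (the calibrated quantity), SUVmax adds mild VOI-shape noise
    suvMean <- exp(log(3.0) + 0.45 * zS)
    suvMax <- suvMean * 1.6 * exp(0.08 * rnorm(n))

    # ADC: linear decreasing in aggressiveness via its (negative) loading
    adcMin <- pmax(400, 1100 + 190 * zA)
    adcMean <- adcMin + runif(n, 100, 350)

    # hormone receptors: near-saturated positivity
    er <- ifelse(runif(n) < 156 / 159,
                 pmin(100, pmax(1, rnorm(n, 83, 22.4))), 0)
    pgr <- ifelse(runif(n) < 157 / 159,
                  pmin(100, pmax(1, rnorm(n, 60, 33.9))), 0)
    her2 <- sample(c("0", "1+", "2+", "3+"), n, replace = TRUE,
                   prob = c(123, 17, 5, 14) / 159)
    # in the emulated cohort no 2+ lesion was FISH-amplified
    fish <- ifelse(her2 == "2+", FALSE, NA)

    archetype <- sample(c("wash-out", "plateau", "persistent"), n,
                        replace = TRUE, prob = config@ticArchetypeMix)

    # time-intensity curves: fast wash-in, then archetype-specific late slope
    si0 <- pmax(100, rnorm(n, 300, 30))
    e1pct <- runif(n, 120, 220)
    si1 <- si0 * (1 + e1pct / 100)
    si2 <- si1 * (1 + runif(n, -0.03, 0.10))
    lateSlope <- numeric(n)
    lateSlope[archetype == "wash-out"] <-
      runif(sum(archetype == "wash-out"), -35, -14)
    lateSlope[archetype == "plateau"] <-
      runif(sum(archetype == "plateau"), -7, 7)
    lateSlope[archetype == "persistent"] <-
      runif(sum(archetype == "persistent"), 14, 45)
    m12 <- (si1 + si2) / 2
    si5 <- m12 * (1 + lateSlope / 100)
    si3 <- si2 + (si5 - si2) * 0.4
    si4 <- si2 + (si5 - si2) * 0.75

    data.frame(
      lesion_id = sprintf("L%03d", seq_len(n)),
      aggressiveness = a,
      grade = grade,
      ki67_pct = ki67,
      er_pct = er,
      pgr_pct = pgr,
      her2_score = her2,
      fish_amplified = fish,
      tic_archetype = archetype,
      true_suv_peak = suvMax,
      true_adc_floor = adcMin,
      suv_max = suvMax,
      suv_mean = suvMean,
      adc_min = adcMin,
      adc_mean = adcMean,
      si0 = si0, si1 = si1, si2 = si2, si3 = si3, si4 = si4, si5 = si5,
      stringsAsFactors = FALSE
    )
  })
}

.ricianNoise <- function(x, sigma) {
  if (sigma == 0) return(x)
  sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
}

#' Render multiparametric lesion volumes for one synthetic lesion
#'
#' Builds small co-registered 3D phantoms for one lesion of a generated
#' cohort: a PET SUV volume (hot ellipsoid peaking at `true_suv_peak` over a
#' low background, zero-mean Gaussian noise with SD proportional to
#' `sqrt(signal)`), a six-phase DCE series whose VOI-mean curve follows the
#' lesion's archetype, a DWI pair consistent with `true_adc_floor` under the
#' two-point mono-exponential model (Rician noise), and the ground-truth
#' ellipsoid mask. The ADC profile equals `true_adc_floor` at the lesion
#' core and increases towards the rim.
#'
#' @param lesion One row of the cohort returned by [generateCohort()] (a
#'   one-row `data.frame` or a list with the same fields).
#' @param config The [SyntheticConfig-class] used for the cohort (noise
#'   scales and phase interval are read from it).
#' @param gridDim Grid size per axis (max 32); default 24.
#' @param spacing Isotropic voxel size in mm; default 2.
#' @param radiiMm Ellipsoid semi-axes in mm; default `c(9, 7, 6)`.
#' @return A list with elements `pet` ([ImageVolume-class]), `dce`
#'   ([DceSeries-class]), `dwiB0`, `dwiB1000` (ImageVolumes) and `mask`
#'   (the truth [LesionMask-class]).
#' @export
renderLesionVolumes <- function(lesion, config, gridDim = c(24, 24, 24),
                                spacing = 2, radiiMm = c(9, 7, 6)) {
  stopifnot(is(config, "SyntheticConfig"))
  if (is.data.frame(lesion)) {
    stopifnot(nrow(lesion) == 1L)
    lesion <- as.list(lesion)
  }
  if (length(gridDim) == 1L) gridDim <- rep(gridDim, 3L)
  gridDim <- as.integer(gridDim)
  if (any(gridDim > 32L)) stop("gridDim is capped at 32 voxels per axis")
  centreIdx <- ceiling(gridDim / 2)
  rVox <- radiiMm / spacing
  if (any(centreIdx - rVox < 1) || any(centreIdx + rVox > gridDim)) {
    stop("grid too small to contain the lesion ellipsoid")
  }

  idx <- expand.grid(i = seq_len(gridDim[1]), j = seq_len(gridDim[2]),
                     k = seq_len(gridDim[3]))
  rho2 <- ((idx$i - centreIdx[1]) / rVox[1])^2 +
          ((idx$j - centreIdx[2]) / rVox[2])^2 +
          ((idx$k - centreIdx[3]) / rVox[3])^2
  inside <- rho2 <= 1
  arr <- function(x) array(x, dim = gridDim)

  petNoise <- function(x) {
    if (config@petNoiseSdScale == 0) return(x)
    x + rnorm(length(x), 0, config@petNoiseSdScale * sqrt(pmax(x, 0)))
  }

  # PET: profile >= 45% of the peak everywhere inside the lesion, so the
  # whole ellipsoid survives the 40% fixed threshold at zero noise
  suvPeak <- lesion$true_suv_peak
  pet <- ifelse(inside, suvPeak * (0.45 + 0.55 * (1 - rho2)), 0.5)
  petVol <- ImageVolume(arr(petNoise(pet)), spacing = spacing,
                        modality = "PET_SUV")

  siBg <- 280
  siLesion <- c(lesion$si0, lesion$si1, lesion$si2, lesion$si3,
                lesion$si4, lesion$si5)
  phases <- lapply(1:6, function(p) {
    v <- ifelse(inside, siLesion[p], siBg)
    ImageVolume(arr(.ricianNoise(v, config@mrRicianSigma)),
                spacing = spacing, modality = "DCE_SI")
  })
  dce <- DceSeries(phases, phaseInterval = config@phaseIntervalS)

  # DWI: ADC = floor at the core, rising quadratically to the rim
  adcTrue <- ifelse(inside, lesion$true_adc_floor + 350 * rho2, 1900)
  s0 <- ifelse(inside, 1400, 700)
  s1000 <- s0 * exp(-adcTrue / 1000)
  dwiB0 <- ImageVolume(arr(.ricianNoise(s0, config@mrRicianSigma)),
                       spacing = spacing, modality = "DWI")
  dwiB1000 <- ImageVolume(arr(.ricianNoise(s1000, config@mrRicianSigma)),
                          spacing = spacing, modality = "DWI")

  mask <- LesionMask(arr(inside), spacing = spacing, provenance = "truth")
  list(pet = petVol, dce = dce, dwiB0 = dwiB0, dwiB1000 = dwiB1000,
       mask = mask)
}

#' Analytic Ki67-positive rate of the generator's marginal
#'
#' Probability that a generated Ki67 percentage reaches the 20% positivity
#' cutoff, computed from the log-normal marginal the generator uses.
#'
#' @return A probability.
#' @export
ki67PositiveRate <- function() {
  marg <- .ki67Marginal()
  unname(1 - pnorm((log(.KI67_CUTOFF) - marg$mu) / marg$sigma))
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort table as CSV and, optionally, per-lesion NIfTI volumes
#' (PET, six DCE phases, two DWI volumes, truth mask) sharing one affine.
#'
#' @param cohort Cohort `data.frame` from [generateCohort()].
#' @param dir Output directory (created if needed).
#' @param config [SyntheticConfig-class]; required when `renderVolumes`.
#' @param renderVolumes Whether to render and write NIfTI volumes.
#' @return Invisibly, the path of the cohort CSV.
#' @export
writeCohort <- function(cohort, dir, config = NULL, renderVolumes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (renderVolumes) {
    stopifnot(!is.null(config))
    paths <- character(nrow(cohort))
    for (r in seq_len(nrow(cohort))) {
      vols <- renderLesionVolumes(cohort[r, ], config)
      sub <- file.path(dir, cohort$lesion_id[r])
      dir.create(sub, showWarnings = FALSE)
      writeImageVolume(vols$pet, file.path(sub, "pet_suv.nii"))
      for (p in 1:6) {
        writeImageVolume(dcePhase(vols$dce, p),
                         file.path(sub, sprintf("dce_phase%d.nii", p - 1)))
      }
      writeImageVolume(vols$dwiB0, file.path(sub, "dwi_b0.nii"))
      writeImageVolume(vols$dwiB1000, file.path(sub, "dwi_b1000.nii"))
      writeLesionMask(vols$mask, file.path(sub, "mask_truth.nii"))
      paths[r] <- sub
    }
    cohort$volume_dir <- paths
  }
  csv <- file.path(dir, "cohort.csv")
  write.csv(cohort, csv, row.names = FALSE)
  invisible(csv)
}
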