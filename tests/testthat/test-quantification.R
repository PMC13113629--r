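test_that("TIC summary equals direct voxel means, peak over all six phases", {
  set.seed(12)
  arrs <- replicate(6, array(runif(4^3, 50, 400), c(4, 4, 4)),
                    simplify = FALSE)
  ser <- DceSeries(lapply(arrs, ImageVolume, modality = "DCE_SI"))
  m <- array(FALSE, c(4, 4, 4)); m[sample(64, 10)] <- TRUE
  mask <- LesionMask(m, provenance = "manual")
  t <- ticSummary(ser, mask)
  manual <- vapply(arrs, function(a) mean(a[m]), numeric(1))
  expect_equal(t@si, manual, tolerance = 1e-12)
  expect_equal(t@siPeak, max(manual))
  # constant series and single-voxel masks are exact
  const <- DceSeries(lapply(1:6, function(i)
    ImageVolume(array(7, c(4, 4, 4)), modality = "DCE_SI")))
  expect_equal(ticSummary(const, mask)@si, rep(7, 6))
  single <- array(FALSE, c(4, 4, 4)); single[2, 3, 1] <- TRUE
  ts <- ticSummary(ser, LesionMask(single, provenance = "manual"))
  expect_equal(ts@si, vapply(arrs, function(a) a[2, 3, 1], numeric(1)))
})

test_that("DCE formula examples evaluate as printed", {
  tic <- function(si0, si1, si2 = si1, si5 = si1, si3 = si1, si4 = si1) {
    c(si0, si1, si2, si3, si4, si5)
  }
  expect_equal(e1(tic(100, 200)), 100)
  expect_equal(e1(tic(100, 100)), 0)
  expect_equal(e1(tic(50, 175)), 250)
  expect_true(is.na(e1(tic(0, 10))))
  expect_equal(eser(c(100, 150, 200, 150, 150, 150)), 50)
  expect_equal(eser(c(100, 200, 200, 200, 200, 200)), 100)
  expect_true(is.na(eser(c(100, 150, 100, 150, 150, 150))))
  expect_equal(ticSlope(c(100, 150, 170, 150, 150, 144)), -10)
  expect_equal(ticSlope(c(100, 150, 170, 150, 150, 160)), 0)
  expect_equal(ticSlope(c(100, 100, 100, 110, 120, 125)), 25)
  expect_equal(sper(c(100, 180, 200, 190, 185, 180)), 1.25)
  expect_equal(sper(c(100, 120, 140, 160, 170, 180)), 1)  # peak at SI5
  expect_true(is.na(sper(c(100, 180, 200, 190, 185, 100))))
  expect_equal(sfer(c(100, 180, 190, 185, 182, 180)), 1)
  expect_equal(sfer(c(100, 150, 160, 180, 190, 200)), 0.5)
  expect_equal(sfer(c(100, 100, 160, 180, 190, 200)), 0)
})

test_that("DCE parameters are invariant to common SI rescaling", {
  set.seed(4)
  for (i in 1:50) {
    si <- runif(6, 50, 500)
    k <- runif(1, 0.1, 20)
    for (f in list(e1, eser, ticSlope, sper, sfer)) {
      expect_equal(f(si), f(k * si), tolerance = 1e-9)
    }
  }
})

test_that("SFER equals SPER when the peak is at the first post-contrast phase", {
  si <- c(100, 300, 250, 220, 210, 205)  # peak at SI1
  expect_equal(sfer(si), sper(si), tolerance = 1e-12)
})

test_that("TIC classification partitions the slope axis with closed plateau bounds", {
  expect_identical(classifyTic(-15), "wash-out")
  expect_identical(classifyTic(0), "plateau")
  expect_identical(classifyTic(-10), "plateau")
  expect_identical(classifyTic(10), "plateau")
  expect_identical(classifyTic(10.0001), "persistent")
  expect_true(is.na(classifyTic(NA_real_)))
  set.seed(6)
  sl <- runif(200, -60, 60)
  cl <- classifyTic(sl)
  expect_true(all(cl %in% c("wash-out", "plateau", "persistent")))
  expect_identical(cl == "wash-out", sl < -10)
  expect_identical(cl == "persistent", sl > 10)
})

test_that("VOI statistics match hand computation, invalid ADC voxels excluded", {
  a <- array(0, c(3, 3, 3)); a[1:3] <- c(2, 4, 9)
  m <- array(FALSE, c(3, 3, 3)); m[1:3] <- TRUE
  mask <- LesionMask(m, provenance = "manual")
  p <- petParams(ImageVolume(a, modality = "PET_SUV"), mask)
  expect_equal(p$suvMax, 9); expect_equal(p$suvMean, 5)
  const <- petParams(ImageVolume(array(5, c(3, 3, 3)),
                                 modality = "PET_SUV"),
                     LesionMask(array(TRUE, c(3, 3, 3)),
                                provenance = "manual"))
  expect_equal(const$suvMax, const$suvMean)
  adcArr <- array(NA_real_, c(3, 3, 3)); adcArr[1:3] <- c(800, NA, 1200)
  ap <- adcParams(ImageVolume(adcArr, modality = "ADC"), mask)
  expect_equal(ap$adcMin, 800); expect_equal(ap$adcMean, 1000)
})

test_that("SUV normalization follows the body-weight convention", {
  expect_equal(suvFromActivity(5, 250, 70), 1.4)
  expect_equal(suvFromActivity(10, 700, 70), 1)   # conc = injected/weight
  w <- 62
  expect_equal(suvFromActivity(3.7, 3.7 * w, w), 1)  # uniform distribution
  expect_error(suvFromActivity(-1, 10, 70), "positive")
})

test_that("the inventory has 9 single and 14 hybrid entries with ADC-only negative direction", {
  inv <- featureInventory()
  expect_equal(nrow(inv), 23)
  expect_equal(sum(inv$kind == "single"), 9)
  expect_equal(sum(inv$kind == "hybrid"), 14)
  expect_identical(inv$name[inv$direction == -1], c("ADCmin", "ADCmean"))
})

test_that("hybrid parameters equal hand-computed products and ratios", {
  pet <- list(suvMax = 5, suvMean = 2)
  d <- dceParams(c(100, 250, 260, 240, 230, 220))
  adc <- list(adcMin = 1000, adcMean = 1250)
  h <- hybridParams(pet, d, adc)
  expect_equal(unname(h["SUVmax_over_ADCmin"]), 0.005)
  expect_equal(unname(h["SUVmean_x_E1"]), 2 * d$e1)
  expect_equal(unname(h["SUVmax_x_ESER"]), 5 * d$eser)
  expect_equal(unname(h["SUVmean_over_Slope"]), 2 / d$slope)
  expect_equal(unname(h["SUVmax_x_SPER"]), 5 * d$sper)
  expect_equal(unname(h["SUVmean_x_SFER"]), 2 * d$sfer)
  expect_equal(unname(h["SUVmean_over_ADCmean"]), 2 / 1250)
  # zero slope invalidates the SUV/Slope hybrids only
  d0 <- dceParams(c(100, 250, 250, 250, 250, 250))
  expect_equal(d0$slope, 0)
  h0 <- hybridParams(pet, d0, adc)
  expect_true(all(is.na(h0[c("SUVmax_over_Slope", "SUVmean_over_Slope")])))
  expect_false(anyNA(h0[setdiff(names(h0),
                                c("SUVmax_over_Slope",
                                  "SUVmean_over_Slope"))]))
})

test_that("feature assembly yields 23 entries and flags missing modalities", {
  pet <- list(suvMax = 5, suvMean = 2)
  adc <- list(adcMin = 1000, adcMean = 1250)
  tic <- c(100, 250, 260, 240, 230, 220)
  fv <- assembleFeatures(pet, tic, adc)
  expect_length(fv$values, 23)
  expect_true(all(fv$valid))
  expect_error(assembleFeatures(NULL, tic, adc),
               class = "petmriq_missing_modality")
  expect_error(assembleFeatures(pet, NULL, adc),
               "not visible in DCE or in PET")
  expect_error(assembleFeatures(pet, tic, NULL), "unusable DW")
})

test_that("image-level feature extraction matches the feature-level raw values", {
  cfg <- syntheticConfig(seed = 14, nLesions = 3, petNoiseSdScale = 0,
                         mrRicianSigma = 0)
  co <- generateCohort(cfg)
  vols <- renderLesionVolumes(co[2, ], cfg)
  fv <- extractFeaturesFromVolumes(vols)
  expect_equal(unname(fv$values["SUVmax"]), co$suv_max[2])
  expect_equal(unname(fv$values["ADCmin"]), co$true_adc_floor[2],
               tolerance = 1e-6)
  expect_equal(unname(fv$values["E1"]),
               100 * (co$si1[2] - co$si0[2]) / co$si0[2], tolerance = 1e-9)
  expect_identical(fv$curveType, co$tic_archetype[2])
})
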