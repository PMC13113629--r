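test_that("uniform region segments to the whole connected region", {
  a <- array(3, c(6, 6, 6))
  voi <- segmentPetVoi(ImageVolume(a, modality = "PET_SUV"))
  expect_equal(maskSize(voi), 6^3)
  expect_identical(provenance(voi), "PET_threshold")
})

test_that("a disconnected secondary hot spot above threshold is excluded", {
  a <- array(1, c(12, 12, 12))          # gap value 1 < 0.4 * 10
  a[3, 3, 3] <- 10
  a[3, 3, 4] <- 9
  a[9, 9, 9] <- 6                        # 6 >= 4 but disconnected
  voi <- segmentPetVoi(ImageVolume(a, modality = "PET_SUV"))
  d <- voxelData(voi)
  expect_true(d[3, 3, 3] && d[3, 3, 4])
  expect_false(d[9, 9, 9])
  expect_equal(sum(d), 2)
})

test_that("threshold VOI equals the flood-fill oracle on random phantoms", {
  set.seed(99)
  for (i in 1:100) {
    vol <- randomPetPhantom()
    voi <- segmentPetVoi(vol)
    expect_identical(voxelData(voi), floodFillVoiOracle(vol))
  }
})

test_that("VOI always contains the regional maximum and only suprathreshold voxels", {
  set.seed(7)
  for (i in 1:20) {
    vol <- randomPetPhantom()
    v <- voxelData(vol)
    voi <- voxelData(segmentPetVoi(vol))
    expect_true(voi[which.max(v)])
    expect_true(all(v[voi] >= 0.40 * max(v)))
  }
})

test_that("search region restricts the segmentation", {
  a <- array(1, c(10, 10, 10))
  a[2, 2, 2] <- 10; a[8, 8, 8] <- 20
  reg <- array(FALSE, c(10, 10, 10)); reg[1:4, 1:4, 1:4] <- TRUE
  vol <- ImageVolume(a, modality = "PET_SUV")
  voi <- segmentPetVoi(vol, LesionMask(reg, provenance = "manual"))
  expect_true(voxelData(voi)[2, 2, 2])
  expect_false(voxelData(voi)[8, 8, 8])
})

test_that("DCE subtraction is voxel-wise post minus pre and linear", {
  set.seed(3)
  mk <- function(f) ImageVolume(array(f, c(5, 5, 5)), modality = "DCE_SI")
  arrs <- replicate(6, array(runif(125, 50, 400), c(5, 5, 5)),
                    simplify = FALSE)
  ser <- DceSeries(lapply(arrs, ImageVolume, modality = "DCE_SI"))
  sub2 <- dceSubtraction(ser, postIndex = 2)
  expect_equal(voxelData(sub2), arrs[[3]] - arrs[[1]])
  # identical phases subtract to zero
  same <- DceSeries(lapply(rep(arrs[1], 6), ImageVolume,
                           modality = "DCE_SI"))
  expect_true(all(voxelData(dceSubtraction(same)) == 0))
  # linearity: subtraction of scaled phases = scaled subtraction
  serScaled <- DceSeries(lapply(arrs, function(a)
    ImageVolume(3 * a, modality = "DCE_SI")))
  expect_equal(voxelData(dceSubtraction(serScaled, 4)),
               3 * voxelData(dceSubtraction(ser, 4)), tolerance = 1e-12)
  expect_error(dceSubtraction(ser, postIndex = 6), "1..5")
})

test_that("identity rigid transform leaves a mask unchanged", {
  m <- array(FALSE, c(8, 8, 8)); m[3:5, 4:6, 2:4] <- TRUE
  mask <- LesionMask(m, spacing = 2, provenance = "manual")
  target <- ImageVolume(array(0, c(8, 8, 8)), spacing = 2,
                        modality = "PET_SUV")
  out <- applyRigidToMask(mask, RigidTransform(), target)
  expect_identical(voxelData(out), m)
})

test_that("integer-pitch translation shifts indices and preserves cardinality", {
  m <- array(FALSE, c(8, 8, 8)); m[3:5, 4:6, 2:4] <- TRUE
  mask <- LesionMask(m, spacing = 2, provenance = "manual")
  target <- ImageVolume(array(0, c(8, 8, 8)), spacing = 2,
                        modality = "PET_SUV")
  out <- applyRigidToMask(mask, RigidTransform(translation = c(2, 0, 0)),
                          target)
  expect_equal(sum(voxelData(out)), sum(m))
  expect_identical(voxelData(out)[4:6, 4:6, 2:4], m[3:5, 4:6, 2:4])
  # moving the mask entirely off-grid errors
  expect_error(
    applyRigidToMask(mask, RigidTransform(translation = c(100, 0, 0)),
                     target),
    "off the target grid")
})

test_that("small rotation about a single-voxel sphere's centre is invariant", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  mask <- LesionMask(m, spacing = 2, provenance = "manual")
  target <- ImageVolume(array(0, c(9, 9, 9)), spacing = 2,
                        modality = "PET_SUV")
  out <- applyRigidToMask(mask, RigidTransform(rotation = c(3, -2, 5)),
                          target)
  expect_identical(voxelData(out), m)
})

test_that("ADC map inverts the mono-exponential decay", {
  mk <- function(v) ImageVolume(array(v, c(4, 4, 4)), modality = "DWI")
  expect_equal(unique(as.vector(voxelData(adcMap(mk(1000),
                                                 mk(1000 * exp(-1)))))),
               1000, tolerance = 1e-9)
  expect_equal(unique(as.vector(voxelData(adcMap(mk(500), mk(500))))), 0)
  # higher signal at higher b-value: invalid, excluded from VOI statistics
  bad <- adcMap(mk(100), mk(200))
  expect_true(all(is.na(voxelData(bad))))
  mask <- LesionMask(array(TRUE, c(4, 4, 4)), provenance = "manual")
  expect_error(adcParams(bad, mask), class = "petmriq_no_valid_adc")
  # partial invalidity: statistics over the valid voxels only
  s0 <- array(1000, c(4, 4, 4)); s1 <- 1000 * exp(-c(0.8, 1.2))
  a1 <- array(c(s1, rep(1000 * exp(-1), 62)), c(4, 4, 4))
  a1[2, 2, 2] <- -5
  adc <- adcMap(mk2 <- ImageVolume(s0, modality = "DWI"),
                ImageVolume(a1, modality = "DWI"))
  p <- adcParams(adc, mask)
  expect_equal(p$adcMin, 800, tolerance = 1e-9)
  expect_error(adcMap(mk(1), mk(1), bLow = 1000, bHigh = 1000), "exceed")
})

test_that("ADC map is invariant to common scaling of both DWI volumes", {
  set.seed(21)
  s0 <- array(runif(64, 500, 1500), c(4, 4, 4))
  s1 <- s0 * exp(-runif(64, 0.3, 1.8))
  a <- adcMap(ImageVolume(s0, modality = "DWI"),
              ImageVolume(s1, modality = "DWI"))
  b <- adcMap(ImageVolume(7.5 * s0, modality = "DWI"),
              ImageVolume(7.5 * s1, modality = "DWI"))
  expect_equal(voxelData(a), voxelData(b), tolerance = 1e-9)
})
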