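## Lesion VOI production: fixed-threshold PET segmentation, DCE subtraction,
## rigid mask transfer, ADC map computation.

# 26-connected synchronous dilation of `seed` restricted to `domain`;
# returns the connected component of `domain` containing `seed`
.connectedComponent26 <- function(seed, domain) {
  d <- dim(domain)
  comp <- seed
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  shiftArr <- function(a, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
    out
  }
  repeat {
    grown <- comp
    for (s in seq_len(nrow(shifts))) {
      grown <- grown | shiftArr(comp, shifts$dx[s], shifts$dy[s],
                                shifts$dz[s])
    }
    grown <- grown & domain
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Fixed-threshold PET lesion segmentation
#'
#' Segments a lesion VOI on a PET SUV volume as the set of voxels with
#' uptake at or above `thresholdFraction` times the maximum uptake within
#' the search region, restricted to the 26-connected component containing
#' the maximum voxel. The default fraction is 0.40 (the 40%-of-maximum
#' fixed-threshold rule). Ties at the regional maximum are seeded at the
#' first maximal voxel in array (lexicographic index) order; all tied
#' maxima that are connected to it end up in the VOI. Deterministic.
#'
#' @param pet A `PET_SUV` [ImageVolume-class].
#' @param searchRegion Optional [LesionMask-class] restricting the search
#'   (the reproducible stand-in for interactive manual adjustment); `NULL`
#'   searches the whole volume.
#' @param thresholdFraction Fraction of the regional maximum; default 0.40.
#' @return A [LesionMask-class] with provenance `"PET_threshold"`.
#' @examples
#' a <- array(1, c(8, 8, 8)); a[4, 4, 4] <- 10; a[4, 4, 5] <- 6
#' voi <- segmentPetVoi(ImageVolume(a, modality = "PET_SUV"))
#' maskSize(voi)
#' @export
segmentPetVoi <- function(pet, searchRegion = NULL, thresholdFraction = 0.40) {
  stopifnot(is(pet, "ImageVolume"))
  if (thresholdFraction <= 0 || thresholdFraction > 1) {
    stop("thresholdFraction must lie in (0, 1]")
  }
  v <- pet@data
  region <- if (is.null(searchRegion)) {
    array(TRUE, dim(v))
  } else {
    stopifnot(is(searchRegion, "LesionMask"))
    if (!.sameGrid(pet, searchRegion)) {
      stop("search region must live on the PET grid")
    }
    searchRegion@data
  }
  if (!any(region)) stop("empty search region")
  if (any(!is.finite(v[region]))) {
    stop("PET values must be finite within the search region")
  }
  regionMax <- max(v[region])
  thresholded <- region & (v >= thresholdFraction * regionMax)
  if (!any(thresholded)) stop("no voxel reaches the threshold") # unreachable
  seedIdx <- which(region & v == regionMax)[1]  # lexicographic first maximum
  seed <- array(FALSE, dim(v))
  seed[seedIdx] <- TRUE
  comp <- .connectedComponent26(seed, thresholded)
  LesionMask(comp, spacing = pet@spacing, origin = pet@origin,
             provenance = "PET_threshold")
}

#' DCE subtraction image
#'
#' Voxel-wise difference between a post-contrast phase and the pre-contrast
#' phase, used to visualise enhancing lesions; the default subtracts the
#' second post-contrast phase.
#'
#' @param series A [DceSeries-class].
#' @param postIndex Post-contrast phase index, 1 to 5; default 2.
#' @return A `DCE_SI` [ImageVolume-class] with the grid metadata of the
#'   series.
#' @export
dceSubtraction <- function(series, postIndex = 2) {
  stopifnot(is(series, "DceSeries"))
  if (postIndex < 1 || postIndex > 5) stop("postIndex must be in 1..5")
  pre <- series@phases[[1]]
  post <- series@phases[[postIndex + 1]]
  ImageVolume(post@data - pre@data, spacing = pre@spacing,
              origin = pre@origin, modality = "DCE_SI")
}

.rotationMatrix <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to a lesion mask
#'
#' Resamples a binary mask onto the grid of a target volume after a known
#' rigid-body motion, using nearest-neighbour interpolation (pull
#' resampling: each target voxel centre is mapped through the inverse
#' motion and sampled in the source mask). Rotation is about the world
#' centre of the source grid. With the identity transform and a shared
#' grid the input mask is returned unchanged.
#'
#' @param mask Source [LesionMask-class].
#' @param t A [RigidTransform-class] mapping source to target world space.
#' @param target [ImageVolume-class] (or [LesionMask-class]) defining the
#'   output grid.
#' @return A binary [LesionMask-class] on the target grid, provenance
#'   `"transferred"`.
#' @export
applyRigidToMask <- function(mask, t, target) {
  stopifnot(is(mask, "LesionMask"), is(t, "RigidTransform"))
  stopifnot(is(target, "ImageVolume") || is(target, "LesionMask"))
  identityT <- all(t@rotation == 0) && all(t@translation == 0)
  if (identityT && .sameGrid(mask, target)) return(mask)

  dTgt <- dim(target@data)
  dSrc <- dim(mask@data)
  centre <- mask@origin + (dSrc - 1) / 2 * mask@spacing
  R <- .rotationMatrix(t@rotation)

  idx <- as.matrix(expand.grid(i = seq_len(dTgt[1]), j = seq_len(dTgt[2]),
                               k = seq_len(dTgt[3])))
  world <- sweep(sweep(idx - 1, 2, target@spacing, "*"), 2, target@origin, "+")
  # inverse motion: p_src = R^T (p_tgt - translation - centre) + centre
  src <- sweep(world, 2, t@translation + centre, "-") %*% R
  src <- sweep(src, 2, centre, "+")
  srcIdx <- round(sweep(sweep(src, 2, mask@origin, "-"), 2,
                        mask@spacing, "/")) + 1
  ok <- srcIdx[, 1] >= 1 & srcIdx[, 1] <= dSrc[1] &
        srcIdx[, 2] >= 1 & srcIdx[, 2] <= dSrc[2] &
        srcIdx[, 3] >= 1 & srcIdx[, 3] <= dSrc[3]
  vals <- logical(nrow(srcIdx))
  vals[ok] <- mask@data[srcIdx[ok, , drop = FALSE]]
  if (!any(vals)) stop("transform moves the entire mask off the target grid")
  LesionMask(array(vals, dTgt), spacing = target@spacing,
             origin = target@origin, provenance = "transferred")
}

#' Compute an ADC map from a two-point DWI acquisition
#'
#' Voxel-wise apparent diffusion coefficient under the mono-exponential
#' model, `ADC = ln(S_low / S_high) / (b_high - b_low)`, expressed in
#' 10^-6 mm^2/s. Voxels with a non-positive signal at either b-value, or a
#' negative ADC (higher signal at the higher b-value), are flagged invalid
#' (`NA`) and excluded from downstream VOI statistics.
#'
#' @param dwiBLow,dwiBHigh DWI [ImageVolume-class]s at the low and high
#'   b-value (same grid).
#' @param bLow,bHigh b-values in s/mm^2; defaults 0 and 1000.
#' @return An `ADC` [ImageVolume-class] in 10^-6 mm^2/s.
#' @examples
#' s0 <- ImageVolume(array(1000, c(4, 4, 4)), modality = "DWI")
#' s1 <- ImageVolume(array(1000 * exp(-1), c(4, 4, 4)), modality = "DWI")
#' range(voxelData(adcMap(s0, s1)))  # 1000 everywhere
#' @export
adcMap <- function(dwiBLow, dwiBHigh, bLow = 0, bHigh = 1000) {
  stopifnot(is(dwiBLow, "ImageVolume"), is(dwiBHigh, "ImageVolume"))
  if (bHigh <= bLow) stop("bHigh must exceed bLow")
  if (!.sameGrid(dwiBLow, dwiBHigh)) {
    stop("DWI volumes must share grid dimensions, spacing and origin")
  }
  sLow <- dwiBLow@data
  sHigh <- dwiBHigh@data
  adc <- array(NA_real_, dim(sLow))
  valid <- !is.na(sLow) & !is.na(sHigh) & sLow > 0 & sHigh > 0
  adc[valid] <- log(sLow[valid] / sHigh[valid]) / (bHigh - bLow) * 1e6
  adc[!is.na(adc) & adc < 0] <- NA_real_   # negative ADC flagged invalid
  ImageVolume(adc, spacing = dwiBLow@spacing, origin = dwiBLow@origin,
              modality = "ADC")
}
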