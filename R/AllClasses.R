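#' @import methods
#' @importFrom stats cor cor.test median pnorm qnorm dnorm rnorm runif var
#'   setNames wilcox.test pwilcox
#' @importFrom utils read.csv write.csv
NULL

.MODALITIES <- c("PET_SUV", "DCE_SI", "DWI", "ADC")
.PROVENANCES <- c("PET_threshold", "manual", "truth", "transferred")

#' ImageVolume: a 3D scalar volume with grid geometry
#'
#' Container for a single imaging volume (PET SUV map, one DCE phase, a DWI
#' volume, or an ADC map) on a regular 3D grid. Voxel values may be `NA` to
#' flag invalid voxels (used by ADC maps where a diffusion signal was
#' non-positive); all non-`NA` values must be finite.
#'
#' World coordinates of voxel `(i, j, k)` (1-based array index) are
#' `origin + (index - 1) * spacing`, per axis, in millimetres.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing Numeric length-3, voxel pitch in mm per axis (positive).
#' @slot origin Numeric length-3, world position of the first voxel centre (mm).
#' @slot modality One of `"PET_SUV"`, `"DCE_SI"`, `"DWI"`, `"ADC"`.
#'
#' @seealso [ImageVolume()] for the constructor, [LesionMask-class],
#'   [DceSeries-class]
#' @export
setClass("ImageVolume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    modality = "character"
  )
)

setValidity("ImageVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (length(d) == 0L) return("data must be non-empty")
  if (!all(is.finite(d) | is.na(d))) return("voxel values must be finite or NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 strictly positive values")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be 3 finite values")
  }
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES) {
    return(sprintf("modality must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  }
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel pitch in mm (length 1 recycled, or length 3).
#' @param origin World coordinate of the first voxel centre in mm.
#' @param modality One of `"PET_SUV"`, `"DCE_SI"`, `"DWI"`, `"ADC"`.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- ImageVolume(array(1, c(4, 4, 4)), spacing = 2, modality = "PET_SUV")
#' dim(voxelData(vol))
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        modality = "PET_SUV") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' DceSeries: a six-phase dynamic contrast-enhanced MRI series
#'
#' Exactly six [ImageVolume-class] phases on a shared grid: index 1 is the
#' pre-contrast phase, indices 2-6 the post-contrast phases, acquired
#' `phaseInterval` seconds apart.
#'
#' @slot phases List of 6 `ImageVolume`s with identical grid geometry.
#' @slot phaseInterval Seconds between consecutive phases (positive).
#' @export
setClass("DceSeries",
  representation(phases = "list", phaseInterval = "numeric")
)

setValidity("DceSeries", function(object) {
  ph <- object@phases
  if (length(ph) != 6L) return("a DCE series has exactly 6 phases")
  if (!all(vapply(ph, is, logical(1), class2 = "ImageVolume"))) {
    return("all phases must be ImageVolume objects")
  }
  ref <- ph[[1]]
  for (p in ph[-1]) {
    if (!identical(dim(p@data), dim(ref@data)) ||
        !isTRUE(all.equal(p@spacing, ref@spacing)) ||
        !isTRUE(all.equal(p@origin, ref@origin))) {
      return("all phases must share grid dimensions, spacing and origin")
    }
  }
  if (length(object@phaseInterval) != 1L || !is.finite(object@phaseInterval) ||
      object@phaseInterval <= 0) {
    return("phaseInterval must be a single positive number of seconds")
  }
  TRUE
})

#' Construct a DceSeries
#'
#' @param phases List of six [ImageVolume-class] objects (pre-contrast first).
#' @param phaseInterval Seconds between phases; the acquisition protocol
#'   emulated here uses 90 s.
#' @return A [DceSeries-class] object.
#' @export
DceSeries <- function(phases, phaseInterval = 90) {
  new("DceSeries", phases = phases, phaseInterval = phaseInterval)
}

#' LesionMask: a binary lesion volume of interest
#'
#' A binary VOI on the grid of its reference modality, with a provenance tag
#' recording how it was obtained: `"PET_threshold"` (40%-of-maximum
#' segmentation), `"manual"`, `"truth"` (synthetic ground truth), or
#' `"transferred"` (resampled from another grid).
#'
#' @slot data 3D logical array; must contain at least one `TRUE` voxel.
#' @slot spacing,origin Grid geometry, as in [ImageVolume-class].
#' @slot provenance Provenance tag.
#' @export
setClass("LesionMask",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    provenance = "character"
  )
)

setValidity("LesionMask", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("mask must be a 3D array")
  if (!is.logical(d)) return("mask values must be logical")
  if (anyNA(d)) return("mask values must not be NA")
  if (!any(d)) return("mask must be non-empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 strictly positive values")
  }
  if (length(object@provenance) != 1L ||
      !object@provenance %in% .PROVENANCES) {
    return(sprintf("provenance must be one of %s",
                   paste(.PROVENANCES, collapse = ", ")))
  }
  TRUE
})

#' Construct a LesionMask
#'
#' @param data 3D logical (or 0/1 numeric) array with at least one TRUE voxel.
#' @param spacing,origin Grid geometry in mm (defaults match [ImageVolume()]).
#' @param provenance One of `"PET_threshold"`, `"manual"`, `"truth"`,
#'   `"transferred"`.
#' @param reference Optional [ImageVolume-class] whose geometry is copied.
#' @return A [LesionMask-class] object.
#' @export
LesionMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       provenance = "manual", reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(is(reference, "ImageVolume"))
    spacing <- reference@spacing
    origin <- reference@origin
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  storage.mode(data) <- "logical"
  new("LesionMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), provenance = provenance)
}

#' RigidTransform: rotation plus translation in world space
#'
#' A rigid-body motion given as three rotation angles (degrees, applied as
#' Rz Ry Rx about a centre point) and a translation in mm. Used only to
#' *apply* a known transform when transferring a mask between grids — e.g.
#' re-aligning a DWI b = 1000 segmentation onto the b = 0 grid — never to
#' estimate one.
#'
#' @slot rotation Numeric length-3, rotation angles in degrees (x, y, z).
#' @slot translation Numeric length-3, translation in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || any(!is.finite(object@rotation))) {
    return("rotation must be 3 finite angles in degrees")
  }
  if (length(object@translation) != 3L || any(!is.finite(object@translation))) {
    return("translation must be 3 finite values in mm")
  }
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation Angles in degrees about the x, y, z axes.
#' @param translation Translation in mm per axis.
#' @return A [RigidTransform-class]; the default is the identity.
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation))
}

## ---- generics & accessors ----

#' @rdname ImageVolume-class
#' @param object,x An ImageVolume or LesionMask.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname ImageVolume-class
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)

#' @rdname LesionMask-class
#' @param x A LesionMask.
#' @export
setMethod("voxelData", "LesionMask", function(x) x@data)

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ImageVolume-class
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname LesionMask-class
#' @export
setMethod("voxelSpacing", "LesionMask", function(x) x@spacing)

#' @rdname ImageVolume-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname ImageVolume-class
#' @export
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @rdname LesionMask-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname LesionMask-class
#' @export
setMethod("provenance", "LesionMask", function(x) x@provenance)

#' @rdname DceSeries-class
#' @param x A DceSeries.
#' @param i Phase index, 1 (pre-contrast) to 6.
#' @export
setGeneric("dcePhase", function(x, i) standardGeneric("dcePhase"))

#' @rdname DceSeries-class
#' @export
setMethod("dcePhase", "DceSeries", function(x, i) {
  stopifnot(i >= 1, i <= 6)
  x@phases[[i]]
})

#' Number of voxels in a mask
#' @param x A [LesionMask-class].
#' @return Integer voxel count.
#' @export
maskSize <- function(x) {
  stopifnot(is(x, "LesionMask"))
  sum(x@data)
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s] %d x %d x %d, spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  v <- object@data[!is.na(object@data)]
  if (length(v)) {
    cat(sprintf("  range: %.4g .. %.4g; invalid voxels: %d\n",
                min(v), max(v), sum(is.na(object@data))))
  }
  invisible(NULL)
})

setMethod("show", "LesionMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LesionMask (%s) %d x %d x %d, %d voxels, %.2f mL\n",
              object@provenance, d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@spacing) / 1000))
  invisible(NULL)
})

setMethod("show", "DceSeries", function(object) {
  d <- dim(object@phases[[1]]@data)
  cat(sprintf(
    "DceSeries: 6 phases (1 pre + 5 post-contrast), %d x %d x %d, %g s apart\n",
    d[1], d[2], d[3], object@phaseInterval))
  invisible(NULL)
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation (%s) deg, translation (%s) mm\n",
              paste(format(object@rotation), collapse = ", "),
              paste(format(object@translation), collapse = ", ")))
  invisible(NULL)
})

# shared guard: two volumes/masks live on the same grid
.sameGrid <- function(a, b) {
  identical(dim(a@data), dim(b@data)) &&
    isTRUE(all.equal(a@spacing, b@spacing)) &&
    isTRUE(all.equal(a@origin, b@origin))
}
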