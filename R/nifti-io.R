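#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti. The affine written is diagonal in the voxel
#' spacing with the grid origin (world position of the first voxel centre)
#' as translation; reading recovers spacing from the voxel dimensions and
#' origin from the qform/sform translation.
#'
#' @param x An [ImageVolume-class] or [LesionMask-class].
#' @param file Path of a `.nii` / `.nii.gz` file.
#' @param modality Modality tag to attach on read (NIfTI stores none).
#' @param provenance Provenance tag to attach to a mask on read.
#' @return `readImageVolume` returns an [ImageVolume-class];
#'   `readLesionMask` a [LesionMask-class]; the writers return the file
#'   path invisibly.
#' @name nifti-io
NULL

.volumeAffine <- function(x) {
  structure(rbind(cbind(diag(x@spacing), x@origin), c(0, 0, 0, 1)),
            code = 2L)
}

#' @rdname nifti-io
#' @export
writeImageVolume <- function(x, file) {
  stopifnot(is(x, "ImageVolume"))
  im <- RNifti::asNifti(x@data)
  RNifti::pixdim(im) <- x@spacing
  im <- RNifti::`qform<-`(im, value = .volumeAffine(x))
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' @rdname nifti-io
#' @export
readImageVolume <- function(file, modality = "PET_SUV") {
  im <- RNifti::readNifti(file)
  aff <- RNifti::xform(im)
  ImageVolume(array(as.numeric(im), dim = dim(im)),
              spacing = RNifti::pixdim(im)[1:3],
              origin = aff[1:3, 4], modality = modality)
}

#' @rdname nifti-io
#' @export
writeLesionMask <- function(x, file) {
  stopifnot(is(x, "LesionMask"))
  im <- RNifti::asNifti(array(as.integer(x@data), dim = dim(x@data)))
  RNifti::pixdim(im) <- x@spacing
  im <- RNifti::`qform<-`(im, value = .volumeAffine(x))
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' @rdname nifti-io
#' @export
readLesionMask <- function(file, provenance = "manual") {
  im <- RNifti::readNifti(file)
  aff <- RNifti::xform(im)
  LesionMask(array(as.numeric(im) > 0.5, dim = dim(im)),
             spacing = RNifti::pixdim(im)[1:3],
             origin = aff[1:3, 4], provenance = provenance)
}
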