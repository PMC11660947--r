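#' @include AllClasses.R
NULL

#' @rdname GradientScheme-class
#' @param object,x a GradientScheme
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname GradientScheme-class
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname TensorField-class
#' @param x a TensorField
#' @export
setGeneric("tensorArray", function(x) standardGeneric("tensorArray"))

#' @rdname TensorField-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname TensorField-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname FlagMap-class
#' @param x a FlagMap
#' @export
setGeneric("flagArray", function(x) standardGeneric("flagArray"))

#' @rdname FlagMap-class
#' @export
setGeneric("flagThreshold", function(x) standardGeneric("flagThreshold"))

#' @rdname ROISpec-class
#' @param x an ROISpec
#' @export
setGeneric("roiVoxels", function(x) standardGeneric("roiVoxels"))

#' Eigen-decomposition of a diffusion tensor
#'
#' @param tensor a [DiffusionTensor-class], or a symmetric 3 x 3 matrix,
#'   or a named numeric(6).
#' @return an [EigenSystem-class] with descending eigenvalues and a
#'   sign-fixed orthonormal basis.
#' @export
setGeneric("eigenSystem", function(tensor) standardGeneric("eigenSystem"))

#' @rdname GradientScheme-class
setMethod("bValues", "GradientScheme", function(x) x@bValues)
#' @rdname GradientScheme-class
setMethod("directions", "GradientScheme", function(x) x@directions)

#' @rdname TensorField-class
setMethod("tensorArray", "TensorField", function(x) x@tensors)
#' @rdname TensorField-class
setMethod("brainMask", "TensorField", function(x) x@mask)
#' @rdname TensorField-class
setMethod("siteLabels", "TensorField", function(x) x@labels)

#' @rdname FlagMap-class
setMethod("flagArray", "FlagMap", function(x) x@flags)
#' @rdname FlagMap-class
setMethod("flagThreshold", "FlagMap", function(x) x@threshold)

#' @rdname ROISpec-class
setMethod("roiVoxels", "ROISpec", function(x) x@voxels)

setMethod("show", "GradientScheme", function(object) {
  b <- object@bValues
  cat("GradientScheme:", length(b), "measurements (",
      sum(b == 0), "x b=0,", sum(b > 0), "x b>0 )\n")
  cat("  b-values (s/mm^2):", paste(unique(b), collapse = ", "), "\n")
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@tensors)
  cat("TensorField:", paste(d[1:3], collapse = " x "), "voxels,",
      sum(object@mask), "in mask\n")
  cat("  voxel size (mm):", paste(object@voxelSize, collapse = " x "),
      " orientation:", paste(object@orientation, collapse = ""), "\n")
  if (any(object@qc)) cat("  QC-flagged voxels:", sum(object@qc), "\n")
})

setMethod("show", "EigenSystem", function(object) {
  cat("EigenSystem: lambda = (",
      paste(signif(object@values, 4), collapse = ", "), ") um^2/ms\n")
})

setMethod("show", "FlagMap", function(object) {
  cat("FlagMap:", sum(object@flags), "of", length(object@flags),
      "voxels flagged at lambda2/lambda3 >", object@threshold, "\n")
})

setMethod("show", "ROISpec", function(object) {
  cat("ROISpec:", object@site, object@hemisphere, "(", object@mode, "),",
      nrow(object@voxels), "voxels at slice", object@voxels[1, 3], "\n")
})

setMethod("show", "ROIDiffusivities", function(object) {
  cat(sprintf("ROIDiffusivities [%s %s, %s]: Dxx=%.4f Dyy=%.4f Dzz=%.4f FA=%.3f MD=%.4f (%d incl, %d excl)\n",
      object@site, object@hemisphere, object@mode, object@dxx, object@dyy,
      object@dzz, object@fa, object@md, object@nIncluded, object@nExcluded))
})

setMethod("show", "ALPSResult", function(object) {
  cat(sprintf("ALPSResult: %s hemisphere, %s ALPS = %.4f\n",
      object@hemisphere, object@mode, object@alps))
})

setMethod("show", "CrossingConfig", function(object) {
  cat(sprintf(
    "CrossingConfig: Drad=%.3f Dpv=%.3f fXp=%.3f fXa=%.3f Dxx,cross=%.3f (r=%.3f)\n",
    object@drad, object@dpv, object@fxp, object@fxa, object@dxxCross,
    object@dxxCross / object@drad))
})

setMethod("show", "AlpsPhantom", function(object) {
  d <- dim(object@dwi)
  cat("AlpsPhantom:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "measurements; true ALPS =",
      signif(object@truth@trueAlps, 6), "\n")
})
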