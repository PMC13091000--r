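## Generics, accessors and show methods.

#' Extract the Dxx/Dyy/Dzz component maps of a tensor volume
#'
#' @param x a [TensorVolume].
#' @param ... ignored.
#' @return named list of [ScalarMap]s: \code{Dxx}, \code{Dyy}, \code{Dzz}.
#' @export
setGeneric("tensorComponents", function(x, ...) standardGeneric("tensorComponents"))

#' Fractional anisotropy map
#'
#' @param x a [TensorVolume].
#' @param ... ignored.
#' @return a [ScalarMap] with FA in [0,1] (NA where the tensor is invalid).
#' @export
setGeneric("faMap", function(x, ...) standardGeneric("faMap"))

#' Principal diffusion direction map
#'
#' @param x a [TensorVolume].
#' @param ... passed to methods.
#' @return a [VectorMap]: unit eigenvector of the largest eigenvalue, sign
#'   fixed so the first nonzero component is nonnegative.
#' @export
setGeneric("principalDirection", function(x, ...) standardGeneric("principalDirection"))

#' Reorient a volume to the canonical anatomical axes
#'
#' Brings the voxel grid to the +x right-left / +y anterior-posterior /
#' +z inferior-superior convention by axis permutations and flips derived
#' from the affine; tensor components are rotated accordingly.  Affines
#' oblique beyond \code{tol} degrees trigger a warning and the nearest-axis
#' permutation is applied.
#'
#' @param x a [TensorVolume], [ScalarMap] or [VectorMap].
#' @param ... methods may take \code{tol} (degrees, default 1e-3).
#' @return object of the same class on the canonical grid.
#' @export
setGeneric("reorientToCanonical", function(x, ...) standardGeneric("reorientToCanonical"))

#' @rdname alpsAccessors
#' @export
setGeneric("alpsLeft", function(x) standardGeneric("alpsLeft"))
#' @rdname alpsAccessors
#' @export
setGeneric("alpsRight", function(x) standardGeneric("alpsRight"))
#' @rdname alpsAccessors
#' @export
setGeneric("alpsBilateral", function(x) standardGeneric("alpsBilateral"))
#' @rdname alpsAccessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' Accessors for ALPS measurements
#'
#' @param x an [AlpsMeasurement].
#' @return numeric index value (NA when invalid) or character flags.
#' @name alpsAccessors
NULL

#' @describeIn alpsAccessors left-hemisphere index
setMethod("alpsLeft", "AlpsMeasurement", function(x) x@alps_left)
#' @describeIn alpsAccessors right-hemisphere index
setMethod("alpsRight", "AlpsMeasurement", function(x) x@alps_right)
#' @describeIn alpsAccessors bilateral mean index
setMethod("alpsBilateral", "AlpsMeasurement", function(x) x@alps_bilateral)
#' @describeIn alpsAccessors quality-control flags
setMethod("qcFlags", "AlpsMeasurement", function(x) x@qc_flags)

#' Model coefficient table
#'
#' @param object an [LmmFit] or [OlsFit].
#' @param ... ignored.
#' @return data.frame of fixed-effect estimates with inference columns.
#' @export
setGeneric("coefTable", function(object, ...) standardGeneric("coefTable"))

#' @describeIn coefTable fixed effects of a mixed-model fit
setMethod("coefTable", "LmmFit", function(object, ...) object@coefficients)
#' @describeIn coefTable coefficients of an OLS fit
setMethod("coefTable", "OlsFit", function(object, ...) object@coefficients)

## -- show methods -----------------------------------------------------------

setMethod("show", "GradientTable", function(object) {
  nb0 <- sum(object@bvals == 0)
  cat(sprintf("GradientTable: %d volumes (%d b=0, %d diffusion-weighted; b max = %g s/mm^2)\n",
              length(object@bvals), nb0, length(object@bvals) - nb0,
              max(object@bvals)))
})

setMethod("show", "TensorVolume", function(object) {
  d <- dim(object@components)
  cat(sprintf("TensorVolume: %d x %d x %d grid, %d/%d valid voxels\n",
              d[1], d[2], d[3], sum(object@valid), prod(d[1:3])))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d spherical ROIs\n", nrow(object@rois)))
  print(object@rois, row.names = FALSE)
})

setMethod("show", "AlpsMeasurement", function(object) {
  cat("AlpsMeasurement\n")
  cat(sprintf("  left: %s  right: %s  bilateral: %s\n",
              format(object@alps_left, digits = 4),
              format(object@alps_right, digits = 4),
              format(object@alps_bilateral, digits = 4)))
  cat("  qc:", paste(object@qc_flags, collapse = ", "), "\n")
})

setMethod("show", "LmmFit", function(object) {
  cat(sprintf("Linear mixed-effects fit (%s model%s): %d obs, %d participants\n",
              object@model_used,
              if (object@converged) "" else ", NOT converged",
              object@n_obs, object@n_participants))
  cat("  ", object@formula, "\n")
  print(format(object@coefficients, digits = 3), row.names = FALSE)
})

setMethod("show", "OlsFit", function(object) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.3f\n", object@n, object@r_squared))
  cat("  ", object@formula, "\n")
  print(format(object@coefficients, digits = 3), row.names = FALSE)
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("2x2 contingency test: %s, p = %.4g\n",
              object@test_used, object@p))
  print(object@counts)
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("IQR filter: %d values in, %d removed (+%d non-finite)\n",
              object@n_input, object@n_removed, object@n_nonfinite))
  print(format(object@bounds, digits = 4), row.names = FALSE)
})
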