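# Constructors, accessors and show methods for the S4 containers.

#' Construct an SH basis specification
#'
#' @param maxOrder even non-negative integer truncation order.
#' @param convention normalization label; only `"real-sym-orthonormal"`
#'   (the package's documented real symmetric orthonormal variant) is
#'   currently defined.
#' @return an [SHBasis-class] object.
#' @examples
#' SHBasis(8)
#' @export
SHBasis <- function(maxOrder = 8L, convention = "real-sym-orthonormal") {
  if (length(maxOrder) != 1L || !is.finite(maxOrder) || maxOrder < 0 ||
      maxOrder != as.integer(maxOrder) || as.integer(maxOrder) %% 2L != 0L)
    stop("maxOrder must be a single even non-negative integer")
  new("SHBasis", maxOrder = as.integer(maxOrder), convention = convention)
}

#' Construct an SH coefficient field
#'
#' @param data 4D numeric array (X, Y, Z, n_coef).
#' @param basis an [SHBasis-class]; default order-8 basis.
#' @param voxelSize voxel edge lengths in mm.
#' @param kind `"signal"` or `"fodf"`.
#' @return an [SHField-class] object.
#' @export
SHField <- function(data, basis = SHBasis(8L), voxelSize = c(2, 2, 2),
                    kind = c("fodf", "signal")) {
  kind <- match.arg(kind)
  new("SHField", data = data, basis = basis,
      voxelSize = as.numeric(voxelSize), kind = kind)
}

#' @rdname SHBasis
#' @param x object with an SH basis.
#' @export
setGeneric("maxOrder", function(x) standardGeneric("maxOrder"))

#' @rdname SHBasis
#' @export
setMethod("maxOrder", "SHBasis", function(x) x@maxOrder)

#' @rdname SHBasis
#' @export
setMethod("maxOrder", "SHField", function(x) x@basis@maxOrder)

#' @rdname SHBasis
#' @export
setMethod("maxOrder", "ResponseFunction", function(x) x@maxOrder)

#' Accessors for package containers
#'
#' `coefArray` returns the 4D coefficient array of an [SHField-class];
#' `shBasis` its basis; `directions` and `bValue` the geometry of a
#' [GradientScheme-class]; `nDirections` its direction count; `wmMask` the
#' white-matter mask of a [Phantom-class] or [DWIVolume-class];
#' `dwiData` the raw 4D signal array; `gtFodf` the ground-truth fODF field
#' of a phantom; `zonalCoeffs` the per-order kernel coefficients of a
#' [ResponseFunction-class]; `accValues` the 3D array of an [ACCMap-class].
#'
#' @param x the container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coefArray", function(x) standardGeneric("coefArray"))
#' @rdname accessors
#' @export
setMethod("coefArray", "SHField", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("shBasis", function(x) standardGeneric("shBasis"))
#' @rdname accessors
#' @export
setMethod("shBasis", "SHField", function(x) x@basis)

#' @rdname accessors
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))
#' @rdname accessors
#' @export
setMethod("directions", "GradientScheme", function(x) x@directions)

#' @rdname accessors
#' @export
setGeneric("bValue", function(x) standardGeneric("bValue"))
#' @rdname accessors
#' @export
setMethod("bValue", "GradientScheme", function(x) x@bValue)

#' @rdname accessors
#' @export
setGeneric("nDirections", function(x) standardGeneric("nDirections"))
#' @rdname accessors
#' @export
setMethod("nDirections", "GradientScheme", function(x) nrow(x@directions))

#' @rdname accessors
#' @export
setGeneric("nB0", function(x) standardGeneric("nB0"))
#' @rdname accessors
#' @export
setMethod("nB0", "GradientScheme", function(x) x@nB0)

#' @rdname accessors
#' @export
setGeneric("wmMask", function(x) standardGeneric("wmMask"))
#' @rdname accessors
#' @export
setMethod("wmMask", "Phantom", function(x) x@wmMask)
#' @rdname accessors
#' @export
setMethod("wmMask", "DWIVolume", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("dwiData", function(x) standardGeneric("dwiData"))
#' @rdname accessors
#' @export
setMethod("dwiData", "DWIVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("gradientScheme", function(x) standardGeneric("gradientScheme"))
#' @rdname accessors
#' @export
setMethod("gradientScheme", "DWIVolume", function(x) x@scheme)

#' @rdname accessors
#' @export
setGeneric("gtFodf", function(x) standardGeneric("gtFodf"))
#' @rdname accessors
#' @export
setMethod("gtFodf", "Phantom", function(x) x@gtFodf)

#' @rdname accessors
#' @export
setGeneric("zonalCoeffs", function(x) standardGeneric("zonalCoeffs"))
#' @rdname accessors
#' @export
setMethod("zonalCoeffs", "ResponseFunction", function(x) x@zonal)

#' @rdname accessors
#' @export
setGeneric("accValues", function(x) standardGeneric("accValues"))
#' @rdname accessors
#' @export
setMethod("accValues", "ACCMap", function(x) x@data)

setMethod("show", "SHBasis", function(object) {
  cat(sprintf("SHBasis: even orders <= %d (%d coefficients), convention '%s'\n",
              object@maxOrder, nCoeffs(object@maxOrder), object@convention))
})

setMethod("show", "SHField", function(object) {
  d <- dim(object@data)
  cat(sprintf("SHField (%s): %d x %d x %d grid, %d coefficients (order %d), voxel %.3g mm\n",
              object@kind, d[1], d[2], d[3], d[4], object@basis@maxOrder,
              object@voxelSize[1]))
})

setMethod("show", "GradientScheme", function(object) {
  cat(sprintf("GradientScheme: %d directions at b=%g s/mm^2 + %d b0\n",
              nrow(object@directions), object@bValue, object@nB0))
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("DWIVolume: %d x %d x %d grid, %d volumes (b=%g, %d b0)%s\n",
              d[1], d[2], d[3], d[4], object@scheme@bValue, object@scheme@nB0,
              if (length(object@mask)) sprintf(", mask (%d voxels)", sum(object@mask)) else ""))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d x %d x %d, %d WM voxels, fODF order %d\n",
              object@shape[1], object@shape[2], object@shape[3],
              sum(object@wmMask), object@gtFodf@basis@maxOrder))
})

setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf("ResponseFunction: even orders 0..%d, zonal = [%s], s0 = %.4g\n",
              object@maxOrder,
              paste(sprintf("%.4g", object@zonal), collapse = ", "), object@s0))
})

setMethod("show", "ACCMap", function(object) {
  v <- object@data[!is.na(object@data)]
  cat(sprintf("ACCMap (%s vs %s): %d defined voxels, %d undefined, mean %.4f\n",
              object@provenance[1], object@provenance[2], length(v),
              object@nUndefined, if (length(v)) mean(v) else NA_real_))
})
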