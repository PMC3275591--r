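#' @name accessors
#' @title Accessors for pipeline objects
#' @description Small accessor generics shared across the image containers.
#' @param object one of the package's S4 objects.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("bVectors", function(object) standardGeneric("bVectors"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("brainVolume", function(object) standardGeneric("brainVolume"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(object) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("scalarMap", function(object, which) standardGeneric("scalarMap"))

setMethod("bValues", "GradientScheme", function(object) object@bvals)
setMethod("bVectors", "GradientScheme", function(object) object@bvecs)
setMethod("bValues", "DWIVolume", function(object) object@scheme@bvals)
setMethod("bVectors", "DWIVolume", function(object) object@scheme@bvecs)

setMethod("voxelSize", "DWIVolume", function(object) object@voxelSize)
setMethod("voxelSize", "BrainMask", function(object) object@voxelSize)
setMethod("voxelSize", "TensorField", function(object) object@voxelSize)
setMethod("voxelSize", "ScalarMapSet", function(object) object@voxelSize)
setMethod("voxelSize", "StatMap", function(object) object@voxelSize)

setMethod("imageData", "DWIVolume", function(object) object@data)
setMethod("maskArray", "BrainMask", function(object) object@mask)
setMethod("validMask", "TensorField", function(object) object@validMask)
setMethod("validMask", "ScalarMapSet", function(object) object@validMask)

#' @rdname accessors
setMethod("brainVolume", "BrainMask", function(object)
    sum(object@mask) * prod(object@voxelSize))

setMethod("eigenValues", "TensorField", function(object) object@evals)
setMethod("eigenVectors", "TensorField", function(object) object@evecs)

#' @rdname accessors
#' @param which one of \code{"fa"}, \code{"adc"}, \code{"axial"},
#'   \code{"radial"}, \code{"linearity"}, \code{"planarity"},
#'   \code{"sphericity"}.
setMethod("scalarMap", "ScalarMapSet", function(object, which) {
    which <- match.arg(which, c("fa", "adc", "axial", "radial",
                                "linearity", "planarity", "sphericity"))
    slot(object, which)
})

setMethod("show", "GradientScheme", function(object) {
    nb0 <- sum(object@bvals == 0)
    cat("GradientScheme:", length(object@bvals), "measurements (",
        length(object@bvals) - nb0, "weighted,", nb0, "b=0 ), b up to",
        max(object@bvals), "s/mm^2\n")
})

setMethod("show", "DWIVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("DWIVolume: %d x %d x %d grid, %d measurements, voxel %s mm\n",
        d[1], d[2], d[3], d[4],
        paste(format(object@voxelSize, digits = 3), collapse = " x ")))
})

setMethod("show", "BrainMask", function(object) {
    cat(sprintf("BrainMask: %d voxels in brain (%.1f mm^3)\n",
        sum(object@mask), brainVolume(object)))
})

setMethod("show", "TensorField", function(object) {
    cat(sprintf("TensorField: %s grid, %d valid voxels, %d clamped\n",
        paste(dim(object@validMask), collapse = " x "),
        sum(object@validMask), object@nClamped))
})

setMethod("show", "ScalarMapSet", function(object) {
    v <- object@validMask
    cat(sprintf("ScalarMapSet: FA/ADC/axial/radial + Westin shape maps, %d valid voxels; mean FA %.3f\n",
        sum(v), mean(object@fa[v])))
})

setMethod("show", "StatMap", function(object) {
    cat(sprintf("StatMap (%s): %d voxels tested, %d at p<0.05, %d at p<0.01\n",
        object@method, sum(object@mask),
        sum(object@sig05, na.rm = TRUE), sum(object@sig01, na.rm = TRUE)))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s grid, %d regions, %d effect region(s), noise sigma %.3g (%s)\n",
        paste(object@gridShape, collapse = "x"), length(object@regions),
        sum(object@groupEffect > 0), object@noiseSigma, object@noiseModel))
})

setMethod("show", "CohortDataset", function(object) {
    tb <- table(object@manifest$group)
    cat(sprintf("CohortDataset: %d subjects (%s)\n",
        nrow(object@manifest),
        paste(sprintf("%s n=%d", names(tb), tb), collapse = ", ")))
})
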