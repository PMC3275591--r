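#' Isotropic diffusion-weighted image
#'
#' Averages the diffusion-weighted (b > 0) measurements voxel-wise into a
#' single high-SNR volume (iDWI).  The b = 0 reference is excluded from the
#' average.  The iDWI drives brain extraction and brain-volume estimation.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @return 3D numeric array with a \code{voxelSize} attribute.
#' @export
computeIDWI <- function(dwi) {
    dw <- dwi@scheme@bvals > 0
    if (!any(dw)) stop("scheme has no diffusion-weighted measurement")
    d <- dim(dwi@data)
    m <- matrix(dwi@data, nrow = prod(d[1:3]))
    idwi <- array(rowMeans(m[, dw, drop = FALSE]), d[1:3])
    structure(idwi, voxelSize = dwi@voxelSize)
}

#' Brain extraction from the iDWI
#'
#' Segments brain from background in four steps: (1) min-max normalise the
#' iDWI to [0, 1]; (2) binarise at \code{thresholdFraction} (background is
#' assumed below this fraction of the maximum); (3) fill internal holes by
#' 3D morphological closing; (4) remove isolated islands by 3D morphological
#' opening, then keep the largest 26-connected component.  The structuring
#' element is the 6-connected unit ball applied \code{closingRadius} /
#' \code{openingRadius} times.
#'
#' @param idwi 3D array from [computeIDWI()] (or any scalar volume), with a
#'   \code{voxelSize} attribute, or supply \code{voxelSize}.
#' @param thresholdFraction fraction of the normalised maximum below which a
#'   voxel is background.  Default 0.05.
#' @param closingRadius,openingRadius structuring-element radii in voxels.
#' @param voxelSize mm, overriding the attribute.
#' @return A \linkS4class{BrainMask}; its volume in mm^3 is available via
#'   [brainVolume()].
#' @export
computeBrainMask <- function(idwi, thresholdFraction = 0.05,
                             closingRadius = 1L, openingRadius = 1L,
                             voxelSize = attr(idwi, "voxelSize")) {
    if (is.null(voxelSize))
        stop("voxelSize must be supplied (or attached to the iDWI)")
    rng <- range(idwi)
    if (diff(rng) == 0) stop("iDWI is constant; cannot normalise")
    normd <- (idwi - rng[1]) / diff(rng)
    m <- array(normd > thresholdFraction, dim(idwi))
    m <- closing3d(m, closingRadius)
    m <- opening3d(m, openingRadius)
    if (any(m)) m <- largestComponent26(m)
    if (!any(m))
        stop("empty brain mask after morphology (threshold ",
             thresholdFraction, ", max normalised intensity 1); ",
             "lower thresholdFraction or the opening radius")
    new("BrainMask", mask = m, voxelSize = as.numeric(voxelSize))
}
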