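## S4 containers for the pipeline.  All image-like slots are plain numeric /
## logical arrays in voxel (i, j, k) order; gradients are interpreted in image
## coordinates (no scanner-frame reorientation).  Voxel indices are 1-based at
## the R surface.

#' Diffusion gradient scheme
#'
#' The acquisition scheme: one b-value (s/mm^2) and one unit gradient
#' direction per measurement.  At least one measurement must be unweighted
#' (b = 0); directions of weighted measurements must have unit norm within
#' 1e-3.
#'
#' @slot bvals numeric vector of b-values, s/mm^2.
#' @slot bvecs 3 x K matrix of gradient directions, columns aligned with
#'   \code{bvals}.
#' @exportClass GradientScheme
setClass("GradientScheme",
    representation(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientScheme", function(object) {
    msg <- character()
    if (ncol(object@bvecs) != length(object@bvals))
        msg <- c(msg, "bvals and bvecs disagree in length")
    if (nrow(object@bvecs) != 3L)
        msg <- c(msg, "bvecs must have 3 rows")
    if (any(object@bvals < 0))
        msg <- c(msg, "negative b-values")
    if (!any(object@bvals == 0))
        msg <- c(msg, "scheme must contain at least one b = 0 measurement")
    dw <- object@bvals > 0
    if (any(dw)) {
        nrms <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
        if (any(abs(nrms - 1) > 1e-3))
            msg <- c(msg, "diffusion-weighted directions must be unit vectors (|norm - 1| <= 1e-3)")
    }
    if (length(msg)) msg else TRUE
})

#' 4D diffusion-weighted volume
#'
#' @slot data 4D numeric array indexed (x, y, z, measurement).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot scheme a \linkS4class{GradientScheme} whose length matches the
#'   fourth array dimension.
#' @exportClass DWIVolume
setClass("DWIVolume",
    representation(data = "array", voxelSize = "numeric",
                   scheme = "GradientScheme"))

setValidity("DWIVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "data must be a 4D array")
    else if (dim(object@data)[4L] != length(object@scheme@bvals))
        msg <- c(msg, "measurement axis length does not match the gradient scheme")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
    if (length(msg)) msg else TRUE
})

#' Binary brain mask
#'
#' @slot mask logical 3D array, TRUE inside the brain.
#' @slot voxelSize numeric length-3, mm.
#' @exportClass BrainMask
setClass("BrainMask",
    representation(mask = "array", voxelSize = "numeric"))

setValidity("BrainMask", function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
        msg <- c(msg, "mask must be a logical 3D array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
    if (length(msg)) msg else TRUE
})

#' Per-voxel diffusion tensor field
#'
#' Eigenvalues are sorted descending; negative fitted eigenvalues are clamped
#' to zero with the number of affected voxels recorded in \code{nClamped}.
#' \code{evecs} may be empty when eigenvectors were not requested.
#'
#' @slot evals array (x, y, z, 3) of eigenvalues, mm^2/s, descending.
#' @slot evecs array (x, y, z, 3, 3); \code{evecs[x,y,z,,j]} is the unit
#'   eigenvector of eigenvalue j, or a zero-length array.
#' @slot tensors array (x, y, z, 6) of unique tensor components in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#' @slot s0 3D array, fitted (or programmed) unweighted signal.
#' @slot validMask logical 3D array of voxels with a usable tensor.
#' @slot voxelSize numeric length-3, mm.
#' @slot nClamped integer, voxels where an eigenvalue was clamped to 0.
#' @exportClass TensorField
setClass("TensorField",
    representation(evals = "array", evecs = "array", tensors = "array",
                   s0 = "array", validMask = "array", voxelSize = "numeric",
                   nClamped = "integer"))

setValidity("TensorField", function(object) {
    msg <- character()
    d <- dim(object@evals)
    if (length(d) != 4L || d[4L] != 3L)
        msg <- c(msg, "evals must be (x, y, z, 3)")
    if (!identical(dim(object@validMask), d[1:3]))
        msg <- c(msg, "validMask grid does not match evals")
    if (length(object@tensors) &&
        !identical(dim(object@tensors), c(d[1:3], 6L)))
        msg <- c(msg, "tensors must be (x, y, z, 6)")
    if (length(msg)) msg else TRUE
})

#' Scalar diffusion map set
#'
#' The seven per-voxel scalar summaries of a tensor field: FA, ADC, axial
#' and radial diffusivity, and the Westin shape coefficients (linearity,
#' planarity, sphericity), each on the tensor grid.  Shape coefficients are
#' normalised by the trace so they sum to one wherever the trace is
#' positive; zero-trace voxels carry 0 in all three and are flagged in
#' \code{degenerate}.
#'
#' @slot fa,adc,axial,radial,linearity,planarity,sphericity 3D numeric arrays.
#' @slot validMask logical 3D array inherited from the tensor fit.
#' @slot degenerate logical 3D array flagging zero-trace voxels.
#' @slot voxelSize numeric length-3, mm.
#' @exportClass ScalarMapSet
setClass("ScalarMapSet",
    representation(fa = "array", adc = "array", axial = "array",
                   radial = "array", linearity = "array", planarity = "array",
                   sphericity = "array", validMask = "array",
                   degenerate = "array", voxelSize = "numeric"))

#' Voxel-wise statistical map
#'
#' @slot statistic 3D array of the test statistic (t or Spearman rho);
#'   NA outside the analysis mask or where undefined.
#' @slot p 3D array of two-sided p-values.
#' @slot sig01,sig05 logical 3D arrays, significance at p < 0.01 / p < 0.05.
#' @slot direction 3D array of the effect sign (+1, -1, 0).
#' @slot mask logical 3D analysis mask.
#' @slot method character, "t" or "spearman".
#' @slot voxelSize numeric length-3, mm.
#' @exportClass StatMap
setClass("StatMap",
    representation(statistic = "array", p = "array", sig01 = "array",
                   sig05 = "array", direction = "array", mask = "array",
                   method = "character", voxelSize = "numeric"))

setValidity("StatMap", function(object) {
    msg <- character()
    if (!identical(dim(object@p), dim(object@statistic)))
        msg <- c(msg, "p and statistic grids differ")
    s01 <- object@sig01 & !is.na(object@sig01)
    s05 <- object@sig05 & !is.na(object@sig05)
    if (any(s01 & !s05))
        msg <- c(msg, "p<0.01 mask must be nested inside the p<0.05 mask")
    if (length(msg)) msg else TRUE
})

#' Synthetic phantom specification
#'
#' Describes the geometry and generative law of a two-group DWI phantom
#' cohort: tissue regions with baseline eigenvalues and fibre directions,
#' per-group regional FA deficits, between-subject variability, Rician noise
#' scale, and couplings between behavioural scores and regional FA.
#'
#' @slot gridShape integer length-3 voxel counts.
#' @slot voxelSize numeric length-3, mm.
#' @slot regions named list; each element has \code{id}, \code{mask}
#'   (logical 3D array), \code{tissue} ("background", "GM" or "WM"),
#'   \code{direction} (unit 3-vector, or "isotropic" for random per-voxel
#'   orientation), and \code{evals} (baseline eigenvalues, mm^2/s,
#'   descending); optionally \code{jitterGroup} (regions sharing a label
#'   share one per-subject anisotropy factor) and \code{jitterSd} (that
#'   factor's sd, defaulting to \code{subjectSd["region"]}).
#' @slot groupEffect named numeric: region id -> FA reduction applied to the
#'   IUGR group (trace-preserving).
#' @slot subjectSd named numeric with elements \code{adc} (relative sd of a
#'   per-subject global diffusivity factor), \code{anisotropy} (relative sd
#'   of a per-subject global anisotropy factor) and \code{region} (relative
#'   sd of independent per-region anisotropy factors).
#' @slot noiseSigma numeric, Rician noise scale relative to \code{s0}.
#' @slot noiseModel character, "rician" (default) or "gaussian".
#' @slot s0 numeric, unweighted signal amplitude.
#' @slot couplings list of couplings, each with \code{score}, \code{region}
#'   (one or more region ids; the coupled quantity is the subject's true
#'   mean FA over their union) and \code{target} (latent Pearson correlation
#'   before discretisation); the score registry controls the output scale.
#' @slot birthWeight list with per-group birth-weight law, elements
#'   \code{control} and \code{IUGR}, each \code{c(mean, sd)} in grams.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(gridShape = "integer", voxelSize = "numeric",
                   regions = "list", groupEffect = "numeric",
                   subjectSd = "numeric", noiseSigma = "numeric",
                   noiseModel = "character", s0 = "numeric",
                   couplings = "list", birthWeight = "list"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    occupied <- array(FALSE, object@gridShape)
    for (rg in object@regions) {
        if (!identical(dim(rg$mask), object@gridShape))
            msg <- c(msg, sprintf("region '%s' mask grid mismatch", rg$id))
        else {
            if (any(occupied & rg$mask))
                msg <- c(msg, sprintf("region '%s' overlaps another region", rg$id))
            occupied <- occupied | rg$mask
        }
        if (!rg$tissue %in% c("background", "GM", "WM"))
            msg <- c(msg, sprintf("region '%s': unknown tissue class", rg$id))
        ev <- rg$evals
        if (any(diff(ev) > 1e-12) || any(ev < 0))
            msg <- c(msg, sprintf("region '%s': eigenvalues must be >= 0 and sorted descending", rg$id))
        if (rg$tissue != "background" && any(ev <= 0))
            msg <- c(msg, sprintf("region '%s': tissue eigenvalues must be positive", rg$id))
    }
    ids <- vapply(object@regions, `[[`, "", "id")
    if (anyDuplicated(ids))
        msg <- c(msg, "duplicate region ids")
    if (length(object@groupEffect) &&
        !all(names(object@groupEffect) %in% ids))
        msg <- c(msg, "groupEffect names must be region ids")
    for (cp in object@couplings) {
        if (abs(cp$target) > 1)
            msg <- c(msg, "coupling target correlation must lie in [-1, 1]")
        if (!all(cp$region %in% ids))
            msg <- c(msg, sprintf("coupling region(s) '%s' not all region ids",
                                  paste(cp$region, collapse = ",")))
    }
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (!object@noiseModel %in% c("rician", "gaussian"))
        msg <- c(msg, "noiseModel must be 'rician' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort bundle
#'
#' A generated two-group cohort: per-subject DWI volumes and ground truth,
#' plus the manifest (id, group, birth weight, behavioural scores) and the
#' generating specification.
#'
#' @slot subjects named list; each element holds \code{id}, \code{group},
#'   \code{dwi} (\linkS4class{DWIVolume}) and \code{truth} (list with the
#'   true FA map, per-region true mean FA, brain and effect-region masks).
#' @slot manifest data.frame, one row per subject.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @slot scheme the \linkS4class{GradientScheme} used.
#' @slot achievedCouplings data.frame of target vs achieved score-FA
#'   correlations (after discretisation).
#' @exportClass CohortDataset
setClass("CohortDataset",
    representation(subjects = "list", manifest = "data.frame",
                   spec = "PhantomSpec", scheme = "GradientScheme",
                   achievedCouplings = "data.frame"))
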