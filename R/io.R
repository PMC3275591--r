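#' Read a diffusion-weighted volume with its gradient table
#'
#' Loads a 4D NIfTI image and FSL-style \code{.bval}/\code{.bvec} tables and
#' cross-validates them: the measurement count must agree between image and
#' tables, weighted directions must be unit vectors, and at least one
#' measurement must be unweighted.
#'
#' @param imagePath path to a 4D NIfTI (.nii or .nii.gz).
#' @param bvalPath,bvecPath paths to the gradient tables.
#' @return A \linkS4class{DWIVolume}.
#' @seealso [writeDWI()], [readBvalBvec()]
#' @export
readDWI <- function(imagePath, bvalPath, bvecPath) {
    img <- RNifti::readNifti(imagePath)
    scheme <- readBvalBvec(bvalPath, bvecPath)
    a <- array(as.numeric(img), dim = dim(img))
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    if (dim(a)[4L] != length(scheme@bvals))
        stop("image has ", dim(a)[4L], " volumes but gradient table has ",
             length(scheme@bvals), " measurements")
    vs <- RNifti::pixdim(img)[1:3]
    new("DWIVolume", data = a, voxelSize = as.numeric(vs), scheme = scheme)
}

#' Write a diffusion-weighted volume and its gradient table
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param imagePath output NIfTI path.
#' @param bvalPath,bvecPath output gradient-table paths; default to the
#'   image path with extensions swapped.
#' @return Invisibly, the image path.
#' @export
writeDWI <- function(dwi, imagePath,
                     bvalPath = sub("\\.nii(\\.gz)?$", ".bval", imagePath),
                     bvecPath = sub("\\.nii(\\.gz)?$", ".bvec", imagePath)) {
    writeNiftiArray(dwi@data, dwi@voxelSize, imagePath)
    writeBvalBvec(dwi@scheme, bvalPath, bvecPath)
    invisible(imagePath)
}

## NIfTI array writers/readers used throughout: plain arrays + pixdim.
writeNiftiArray <- function(a, voxelSize, path, datatype = "auto") {
    img <- RNifti::asNifti(a)
    nd <- length(dim(a))
    RNifti::pixdim(img) <- c(voxelSize, rep(1, max(0, nd - 3)))[seq_len(nd)]
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

readNiftiArray <- function(path) {
    img <- RNifti::readNifti(path)
    structure(array(as.numeric(img), dim = dim(img)),
              voxelSize = as.numeric(RNifti::pixdim(img))[seq_len(min(3, length(dim(img))))])
}

#' Write / read a brain mask as NIfTI
#'
#' Masks are stored as uint8 volumes.
#' @param mask a \linkS4class{BrainMask}.
#' @param path NIfTI path.
#' @export
writeMask <- function(mask, path) {
    writeNiftiArray(array(as.integer(mask@mask), dim(mask@mask)),
                    mask@voxelSize, path, datatype = "uint8")
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
    a <- readNiftiArray(path)
    new("BrainMask", mask = array(a > 0, dim(a)),
        voxelSize = attr(a, "voxelSize"))
}

#' Read a subject manifest
#'
#' The manifest is a CSV with one row per subject: \code{id}, \code{group}
#' (\code{control} or \code{IUGR}), \code{birth_weight} (g) and one column
#' per behavioural score named as in [scoreRegistry()].  Empty score cells
#' become \code{NA} (explicit missing values, propagated to statistics by
#' pairwise deletion) - they are never silently zero.
#'
#' @param csvPath path to the manifest CSV.
#' @return data.frame with validated columns; score columns are numeric.
#' @export
readManifest <- function(csvPath) {
    m <- read.csv(csvPath, stringsAsFactors = FALSE)
    req <- c("id", "group")
    if (!all(req %in% names(m)))
        stop("manifest must contain columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(m$id))
        stop("duplicated subject id(s): ",
             paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
    bad <- setdiff(unique(m$group), c("control", "IUGR"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "),
             " (expected 'control' or 'IUGR')")
    known <- scoreRegistry()$name
    for (sc in intersect(known, names(m)))
        m[[sc]] <- suppressWarnings(as.numeric(m[[sc]]))
    if ("birth_weight" %in% names(m))
        m$birth_weight <- as.numeric(m$birth_weight)
    m
}

#' @rdname readManifest
#' @param manifest data.frame as returned by [readManifest()] or generated
#'   with a cohort.
#' @export
writeManifest <- function(manifest, csvPath) {
    write.csv(manifest, csvPath, row.names = FALSE, na = "")
    invisible(csvPath)
}
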