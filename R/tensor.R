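#' Fit the diffusion tensor per voxel
#'
#' Log-linear least squares: for each voxel inside the mask with strictly
#' positive signal in every channel, solve
#' log S_k = log S0 - b_k g_k' D g_k for the six unique tensor components
#' plus log S0 (ordinary least squares by default; weighted least squares
#' with weights proportional to the squared predicted signal as an option).
#' The tensor is eigen-decomposed per voxel; eigenvalues are sorted
#' descending and negative eigenvalues are clamped to zero, with the number
#' of affected voxels reported in the \code{nClamped} slot.  Voxels with a
#' non-positive signal in any channel are excluded from the valid mask.
#'
#' @param dwi a \linkS4class{DWIVolume}; the scheme needs >= 6 non-collinear
#'   weighted directions and >= 1 b = 0 measurement.
#' @param mask a \linkS4class{BrainMask} restricting the fit.
#' @param method "ols" (default) or "wls".
#' @param storeVectors keep per-voxel eigenvectors (needed for fibre
#'   direction checks; off saves memory).
#' @param excludeNegative drop voxels with a negative fitted eigenvalue
#'   from the valid mask instead of clamping them to zero.  Either way the
#'   affected voxel count is reported.
#' @return A \linkS4class{TensorField}.
#' @export
fitTensors <- function(dwi, mask, method = c("ols", "wls"),
                       storeVectors = TRUE, excludeNegative = FALSE) {
    method <- match.arg(method)
    checkSameGrid(dwi@data, mask@mask)
    b <- dwi@scheme@bvals
    g <- dwi@scheme@bvecs
    if (sum(b > 0) < 6)
        stop("need at least 6 diffusion-weighted measurements")
    X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
               -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
               -2 * b * g[2, ] * g[3, ])
    if (qr(X)$rank < 7L)
        stop("gradient directions are collinear: design matrix is rank-deficient")
    d <- dim(dwi@data)
    nv <- prod(d[1:3])
    S <- matrix(dwi@data, nv, d[4])
    pos <- rowSums(S <= 0) == 0
    valid <- as.vector(mask@mask) & pos
    vi <- which(valid)
    logS <- log(S[vi, , drop = FALSE])
    Cmat <- solve(crossprod(X), t(X))          # 7 x K
    B <- logS %*% t(Cmat)
    if (method == "wls") {
        ## one reweighting pass: weights = squared predicted signals
        for (r in seq_len(nrow(B))) {
            w <- as.vector(exp(X %*% B[r, ]))^2
            Xw <- X * w
            B[r, ] <- solve(crossprod(X, Xw), crossprod(Xw, logS[r, ]))
        }
    }
    eig <- .eig3SymBatch(B[, 2:7, drop = FALSE], storeVectors)
    ev <- eig$values
    clamped <- rowSums(ev < 0) > 0
    if (excludeNegative) {
        drop <- vi[clamped]
        valid[drop] <- FALSE
        keep <- !clamped
        vi <- vi[keep]
        B <- B[keep, , drop = FALSE]
        ev <- ev[keep, , drop = FALSE]
        if (storeVectors) eig$vectors <- eig$vectors[keep, , drop = FALSE]
    }
    ev[ev < 0] <- 0
    evalsArr <- array(0, c(d[1:3], 3))
    for (j in 1:3) {
        tmp <- numeric(nv); tmp[vi] <- ev[, j]
        evalsArr[, , , j] <- array(tmp, d[1:3])
    }
    tensArr <- array(0, c(d[1:3], 6))
    for (j in 1:6) {
        tmp <- numeric(nv); tmp[vi] <- B[, j + 1]
        tensArr[, , , j] <- array(tmp, d[1:3])
    }
    vecArr <- array(0, c(0, 0, 0, 0, 0))
    if (storeVectors) {
        vecs <- matrix(0, nv, 9)
        vecs[vi, ] <- eig$vectors
        vecArr <- array(vecs, c(d[1:3], 3, 3))
    }
    s0 <- numeric(nv); s0[vi] <- exp(B[, 1])
    new("TensorField", evals = evalsArr, evecs = vecArr, tensors = tensArr,
        s0 = array(s0, d[1:3]), validMask = array(valid, d[1:3]),
        voxelSize = dwi@voxelSize, nClamped = as.integer(sum(clamped)))
}

#' Scalar and shape maps of a tensor field
#'
#' From the sorted eigenvalues (l1 >= l2 >= l3):
#' ADC = (l1+l2+l3)/3; axial = l1; radial = (l2+l3)/2;
#' FA = sqrt(3/2) sqrt(sum (li - lbar)^2) / sqrt(sum li^2);
#' Westin coefficients normalised by the trace so they partition shape:
#' linearity = (l1-l2)/(l1+l2+l3), planarity = 2(l2-l3)/(l1+l2+l3),
#' sphericity = 3 l3/(l1+l2+l3); the three sum to one wherever the trace is
#' positive.  Zero-trace voxels get 0 in all shape maps and are flagged.
#'
#' @param tf a \linkS4class{TensorField}.
#' @return A \linkS4class{ScalarMapSet}.
#' @export
scalarMaps <- function(tf) {
    d <- dim(tf@validMask)
    nv <- prod(d)
    ev <- matrix(tf@evals, nv, 3)
    tr <- rowSums(ev)
    adc <- tr / 3
    axial <- ev[, 1]
    radial <- (ev[, 2] + ev[, 3]) / 2
    fa <- faFromEvals(ev)
    safeTr <- ifelse(tr > 0, tr, 1)
    cl <- ifelse(tr > 0, (ev[, 1] - ev[, 2]) / safeTr, 0)
    cp <- ifelse(tr > 0, 2 * (ev[, 2] - ev[, 3]) / safeTr, 0)
    cs <- ifelse(tr > 0, 3 * ev[, 3] / safeTr, 0)
    degen <- array(tf@validMask & array(tr == 0, d), d)
    as3d <- function(x) array(x, d)
    new("ScalarMapSet", fa = as3d(fa), adc = as3d(adc), axial = as3d(axial),
        radial = as3d(radial), linearity = as3d(cl), planarity = as3d(cp),
        sphericity = as3d(cs), validMask = tf@validMask,
        degenerate = degen, voxelSize = tf@voxelSize)
}

#' White-matter mask by FA threshold
#'
#' White matter is approximated as the brain voxels whose FA exceeds a
#' threshold (default 0.20, the value that best discriminates white-matter
#' structures in ex vivo neonatal brain).  No morphology is applied.
#'
#' @param fa 3D FA array (e.g. \code{scalarMap(maps, "fa")}).
#' @param brain a \linkS4class{BrainMask}.
#' @param threshold FA threshold in (0, 1).
#' @return A \linkS4class{BrainMask} of the white-matter voxels.
#' @export
wmMaskFromFA <- function(fa, brain, threshold = 0.20) {
    stopifnot(threshold >= 0, threshold < 1)
    checkSameGrid(fa, brain@mask)
    m <- brain@mask & (fa > threshold)
    if (!any(m))
        warning("white-matter mask is empty at FA threshold ", threshold)
    new("BrainMask", mask = m, voxelSize = brain@voxelSize)
}
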