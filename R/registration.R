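## Spatial transforms for VBA.  Affines are 4x4 matrices acting on 1-based
## voxel coordinates of the TEMPLATE grid, returning the coordinate in the
## SOURCE image to sample from (pull-back convention).  Dense warps are
## (x, y, z, 3) voxel-displacement fields added to the template coordinate.

## Trilinear interpolation of src at an n x 3 coordinate matrix.
interp3 <- function(src, xyz) {
    d <- dim(src)
    x0 <- floor(xyz[, 1]); y0 <- floor(xyz[, 2]); z0 <- floor(xyz[, 3])
    fx <- xyz[, 1] - x0; fy <- xyz[, 2] - y0; fz <- xyz[, 3] - z0
    inside <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 &
              z0 >= 1 & z0 <= d[3] - 1
    out <- rep(NA_real_, nrow(xyz))
    if (!any(inside)) return(out)
    x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
    fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
    at <- function(dx, dy, dz)
        src[cbind(x0 + dx, y0 + dy, z0 + dz)]
    out[inside] <-
        at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
        at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
        at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
        at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
        at(1, 1, 0) * fx * fy * (1 - fz) +
        at(1, 0, 1) * fx * (1 - fy) * fz +
        at(0, 1, 1) * (1 - fx) * fy * fz +
        at(1, 1, 1) * fx * fy * fz
    out
}

nearest3 <- function(src, xyz) {
    d <- dim(src)
    ix <- round(xyz)
    inside <- ix[, 1] >= 1 & ix[, 1] <= d[1] & ix[, 2] >= 1 &
              ix[, 2] <= d[2] & ix[, 3] >= 1 & ix[, 3] <= d[3]
    out <- rep(NA_real_, nrow(xyz))
    out[inside] <- src[ix[inside, , drop = FALSE]]
    out
}

templateCoords <- function(d) {
    cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
          rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
          rep(seq_len(d[3]), each = d[1] * d[2]))
}

#' Apply a spatial transform to a volume
#'
#' Resamples \code{src} onto a template grid.  \code{transform} is either a
#' 4x4 affine mapping template voxel coordinates to source voxel
#' coordinates, or a dense displacement field (array (x, y, z, 3), voxel
#' units, added to the template coordinate).  Scalar maps use trilinear
#' interpolation; masks and label maps should use nearest-neighbour.
#' Voxels mapping outside the source are filled with \code{fill}.
#'
#' @param src 3D numeric array.
#' @param transform 4x4 matrix, displacement-field array, or NULL
#'   (identity).
#' @param targetDim template grid (defaults to the source grid).
#' @param interpolation "trilinear" or "nearest".
#' @param fill value for out-of-source voxels.
#' @return 3D array on the template grid.
#' @export
applyTransform <- function(src, transform = NULL, targetDim = dim(src),
                           interpolation = c("trilinear", "nearest"),
                           fill = 0) {
    interpolation <- match.arg(interpolation)
    if (is.null(transform)) {
        if (!identical(dim(src), as.integer(targetDim)) &&
            !identical(dim(src), targetDim))
            stop("identity transform requires matching grids")
        return(src)
    }
    co <- templateCoords(targetDim)
    if (is.matrix(transform) && identical(dim(transform), c(4L, 4L))) {
        xyz <- cbind(co, 1) %*% t(transform)
        xyz <- xyz[, 1:3, drop = FALSE]
    } else if (is.array(transform) &&
               length(dim(transform)) == 4L && dim(transform)[4L] == 3L) {
        if (!identical(dim(transform)[1:3], as.integer(targetDim)))
            stop("displacement field grid does not match the template grid")
        xyz <- co + matrix(transform, ncol = 3)
    } else stop("transform must be a 4x4 affine or an (x,y,z,3) warp field")
    vals <- if (interpolation == "trilinear") interp3(src, xyz)
            else nearest3(src, xyz)
    vals[is.na(vals)] <- fill
    array(vals, targetDim)
}

## Affine matrix from 12 parameters: translation (voxels), rotation about
## the grid centre (radians), log-scales, shears.
affineFromParams <- function(p, centre) {
    cx <- cos(p[4]); sx <- sin(p[4])
    cy <- cos(p[5]); sy <- sin(p[5])
    cz <- cos(p[6]); sz <- sin(p[6])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    S <- diag(exp(p[7:9]))
    Sh <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
    A3 <- Rz %*% Ry %*% Rx %*% Sh %*% S
    A <- diag(4)
    A[1:3, 1:3] <- A3
    A[1:3, 4] <- centre - A3 %*% centre + p[1:3]
    A
}

## Mutual information between two vectors, equal-width histogram.
mutualInfo <- function(a, b, nbins = 32) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 100) return(-Inf)
    cutIdx <- function(v) {
        r <- range(v)
        if (diff(r) == 0) return(rep(1L, length(v)))
        pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins))
    }
    ia <- cutIdx(a); ib <- cutIdx(b)
    joint <- tabulate((ia - 1L) * nbins + ib, nbins * nbins) / length(a)
    pa <- tabulate(ia, nbins) / length(a)
    pb <- tabulate(ib, nbins) / length(b)
    nz <- joint > 0
    pp <- outer(pb, pa)   # note: joint index is (ib, ia)
    sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Affine registration by mutual information
#'
#' Estimates the 12-parameter affine (translation, rotation, scale, shear)
#' aligning \code{source} to \code{target} by maximising the mutual
#' information of their joint intensity histogram, with Nelder-Mead over
#' the parameters and trilinear resampling.  Intended for same-modality
#' FA volumes on comparable grids; elastic/diffeomorphic registration is
#' out of scope and is consumed as precomputed warp fields instead.
#'
#' @param source,target 3D arrays (e.g. FA volumes).
#' @param maxit Nelder-Mead iteration budget.
#' @param nbins histogram bins for the mutual-information estimate.
#' @return list with \code{affine} (4x4, template-to-source, i.e. usable
#'   directly in [applyTransform()] with \code{target} as template),
#'   \code{mi} achieved, and \code{par}.
#' @export
registerAffine <- function(source, target, maxit = 150, nbins = 32) {
    checkSameGrid(source, target)
    ctr <- (dim(source) + 1) / 2
    tgt <- as.vector(target)
    obj <- function(p) {
        A <- affineFromParams(p, ctr)
        res <- applyTransform(source, A, dim(target), fill = NA)
        -mutualInfo(as.vector(res), tgt, nbins)
    }
    scales <- c(rep(1, 3), rep(0.05, 3), rep(0.05, 3), rep(0.05, 3))
    ## stage 1: rigid (translation + rotation), stage 2: full affine
    rigid <- optim(rep(0, 6), function(p6) obj(c(p6, rep(0, 6))),
                   method = "Nelder-Mead",
                   control = list(maxit = maxit, parscale = scales[1:6]))
    fit <- optim(c(rigid$par, rep(0, 6)), obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = scales))
    list(affine = affineFromParams(fit$par, ctr), mi = -fit$value,
         par = fit$par)
}
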