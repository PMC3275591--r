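#' Registered per-subject map stack
#'
#' Per-subject scalar maps resampled onto one template grid, with the
#' analysis mask (intersection of resampled brain masks) and per-subject
#' transform provenance.
#'
#' @slot maps named list of 3D arrays, one per subject.
#' @slot mask logical 3D analysis mask.
#' @slot template template subject id (or "reference").
#' @slot provenance named character: "identity", "affine", "warp" or
#'   "internal_affine" per subject.
#' @slot voxelSize numeric length-3, mm.
#' @exportClass RegisteredStack
setClass("RegisteredStack",
    representation(maps = "list", mask = "array", template = "character",
                   provenance = "character", voxelSize = "numeric"))

setMethod("show", "RegisteredStack", function(object) {
    cat(sprintf("RegisteredStack: %d subjects on template '%s', %d analysis voxels\n",
        length(object@maps), object@template, sum(object@mask)))
})

#' Build a registered stack of subject maps
#'
#' Brings each subject's scalar map and brain mask onto the template grid.
#' If \code{transforms} are supplied (4x4 affines or dense warp fields,
#' template-to-subject pull-back convention) they are applied with
#' trilinear interpolation for the maps and nearest-neighbour for the
#' masks.  If absent and all subjects share the template grid, identity is
#' used.  With \code{register = "affine"} an internal mutual-information
#' affine registration of each subject's map to the template map is
#' estimated.  The analysis mask is the intersection of all resampled
#' brain masks.
#'
#' @param maps named list of per-subject 3D arrays (one metric).
#' @param masks named list of per-subject \linkS4class{BrainMask} or
#'   logical arrays.
#' @param template subject id naming the template, must be in \code{maps}.
#' @param transforms optional named list of per-subject transforms
#'   (NULL entries mean identity).
#' @param register "none" (identity/supplied transforms only) or "affine".
#' @param registerOn optional named list of volumes to drive the internal
#'   registration (defaults to \code{maps}; typically FA).
#' @param voxelSize mm.
#' @param maxit iteration budget for internal registration.
#' @return A \linkS4class{RegisteredStack}.
#' @export
buildStack <- function(maps, masks, template, transforms = NULL,
                       register = c("none", "affine"), registerOn = NULL,
                       voxelSize = c(1, 1, 1), maxit = 150) {
    register <- match.arg(register)
    stopifnot(template %in% names(maps))
    tDim <- dim(maps[[template]])
    out <- vector("list", length(maps))
    names(out) <- names(maps)
    prov <- setNames(character(length(maps)), names(maps))
    amask <- array(TRUE, tDim)
    if (is.null(registerOn)) registerOn <- maps
    for (id in names(maps)) {
        m <- maps[[id]]
        bm <- masks[[id]]
        if (methods::is(bm, "BrainMask")) bm <- bm@mask
        tr <- transforms[[id]]
        if (!is.null(tr)) {
            prov[id] <- if (is.matrix(tr)) "affine" else "warp"
        } else if (id == template) {
            tr <- NULL; prov[id] <- "identity"
        } else if (register == "affine") {
            reg <- registerAffine(registerOn[[id]], registerOn[[template]],
                                  maxit = maxit)
            tr <- reg$affine
            prov[id] <- "internal_affine"
        } else {
            if (!identical(dim(m), tDim))
                stop("subject '", id, "' is on a different grid and no ",
                     "transform was supplied")
            prov[id] <- "identity"
        }
        out[[id]] <- applyTransform(m, tr, tDim, "trilinear", fill = 0)
        bmr <- applyTransform(array(as.numeric(bm), dim(bm)), tr, tDim,
                              "nearest", fill = 0)
        amask <- amask & (bmr > 0)
    }
    new("RegisteredStack", maps = out, mask = amask,
        template = as.character(template), provenance = prov,
        voxelSize = as.numeric(voxelSize))
}

#' Masked Gaussian smoothing
#'
#' Discrete Gaussian sampled at voxel centres, truncated to a
#' \code{kernel} x \code{kernel} x \code{kernel} window and renormalised to
#' sum one.  Smoothing is masked: weights are renormalised over in-mask
#' voxels so background values never bleed into the brain.  Out-of-mask
#' voxels are returned as 0.
#'
#' @param map 3D array.
#' @param mask logical 3D array (default: everywhere).
#' @param kernel odd kernel width in voxels (default 3).
#' @param sigma Gaussian standard deviation in voxels (default 1).
#' @return smoothed 3D array.
#' @export
smoothMap <- function(map, mask = NULL, kernel = 3, sigma = 1) {
    stopifnot(kernel %% 2 == 1)
    if (is.null(mask)) mask <- array(TRUE, dim(map))
    r <- (kernel - 1) / 2
    off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
    w <- exp(-(off$dx^2 + off$dy^2 + off$dz^2) / (2 * sigma^2))
    w <- w / sum(w)
    num <- array(0, dim(map))
    den <- array(0, dim(map))
    m0 <- map
    m0[!mask] <- 0
    mnum <- array(as.numeric(mask), dim(map))
    for (i in seq_len(nrow(off))) {
        num <- num + w[i] * shift3d(m0, off$dx[i], off$dy[i], off$dz[i], 0)
        den <- den + w[i] * shift3d(mnum, off$dx[i], off$dy[i], off$dz[i], 0)
    }
    out <- array(0, dim(map))
    out[mask] <- num[mask] / den[mask]
    out
}

## Assemble a StatMap from flat statistic/p vectors over mask voxels.
makeStatMap <- function(stat, p, dirn, mask, method, voxelSize) {
    d <- dim(mask)
    toArr <- function(v, init = NA_real_) {
        a <- array(init, d); a[mask] <- v; a
    }
    pArr <- toArr(p)
    new("StatMap", statistic = toArr(stat), p = pArr,
        sig01 = array(!is.na(pArr) & pArr < 0.01, d),
        sig05 = array(!is.na(pArr) & pArr < 0.05, d),
        direction = toArr(dirn), mask = mask, method = method,
        voxelSize = voxelSize)
}

#' Voxel-wise two-sample t-test
#'
#' Pooled-variance two-sided t-test at every analysis-mask voxel, control
#' vs IUGR, across the subjects of a registered stack.  Voxels with zero
#' variance in both groups are flagged undefined (NA statistic and p).
#' The direction volume is +1 where the control mean exceeds the IUGR
#' mean.
#'
#' @param stack a \linkS4class{RegisteredStack}.
#' @param manifest data.frame with \code{id} and \code{group}; subjects are
#'   matched to stack maps by id.
#' @return A \linkS4class{StatMap} with significance masks at p < 0.01 and
#'   p < 0.05.
#' @export
voxelwiseGroupTest <- function(stack, manifest) {
    ids <- names(stack@maps)
    grp <- manifest$group[match(ids, manifest$id)]
    if (anyNA(grp)) stop("stack subject(s) missing from manifest")
    if (sum(grp == "control") < 2 || sum(grp == "IUGR") < 2)
        stop("need >= 2 subjects per group")
    X <- vapply(stack@maps, function(m) m[stack@mask],
                numeric(sum(stack@mask)))
    xc <- X[, grp == "control", drop = FALSE]
    xi <- X[, grp == "IUGR", drop = FALSE]
    n1 <- ncol(xc); n2 <- ncol(xi)
    m1 <- rowMeans(xc); m2 <- rowMeans(xi)
    v1 <- rowSums((xc - m1)^2) / (n1 - 1)
    v2 <- rowSums((xi - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    tstat[se == 0] <- NA
    p <- 2 * pt(-abs(tstat), n1 + n2 - 2)
    makeStatMap(tstat, p, sign(m1 - m2), stack@mask, "t", stack@voxelSize)
}

#' Voxel-wise Spearman correlation with a behavioural score
#'
#' At every analysis-mask voxel, the Spearman correlation (mid-ranks,
#' t-approximation p) between the subjects' map values and a behavioural
#' score.  Subjects with a missing score are dropped.  The statistic volume
#' holds rho; use \code{statistic > 0.2} style thresholds for display
#' masks and the p < 0.01 mask for region reporting.
#'
#' @param stack a \linkS4class{RegisteredStack}.
#' @param score score column name in the manifest.
#' @param manifest data.frame with \code{id} and the score column.
#' @return A \linkS4class{StatMap} (method "spearman").
#' @export
voxelwiseCorrelation <- function(stack, score, manifest) {
    ids <- names(stack@maps)
    sc <- manifest[[score]][match(ids, manifest$id)]
    keep <- !is.na(sc)
    if (sum(keep) < 4)
        stop("need >= 4 subjects with a non-missing '", score, "' score")
    sc <- sc[keep]
    if (sd(sc) == 0) stop("score '", score, "' is constant across subjects")
    X <- vapply(stack@maps[keep], function(m) m[stack@mask],
                numeric(sum(stack@mask)))
    n <- ncol(X)
    R <- rowRanksAvg(X)
    rs <- rank(sc, ties.method = "average")
    R <- R - (n + 1) / 2
    rsc <- rs - (n + 1) / 2
    num <- as.vector(R %*% rsc)
    den <- sqrt(rowSums(R^2) * sum(rsc^2))
    rho <- ifelse(den > 0, num / den, NA)
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tstat), n - 2)
    p[!is.na(rho) & abs(rho) >= 1] <- 0
    makeStatMap(rho, p, sign(rho), stack@mask, "spearman", stack@voxelSize)
}

#' Display mask for a correlation map
#'
#' The conventional rendering mask for voxel-wise correlation volumes:
#' voxels whose |rho| exceeds a threshold (default 0.2), within the
#' analysis mask.
#'
#' @param statmap a \linkS4class{StatMap} from [voxelwiseCorrelation()].
#' @param threshold absolute correlation cutoff.
#' @return logical 3D array.
#' @export
correlationDisplayMask <- function(statmap, threshold = 0.2) {
    stopifnot(statmap@method == "spearman")
    m <- statmap@mask & !is.na(statmap@statistic) &
         abs(statmap@statistic) > threshold
    array(m, dim(statmap@mask))
}

#' Multi-template consensus of voxel-wise results
#'
#' Repeating the voxel-based analysis with every subject as registration
#' template and intersecting the significant regions discards the
#' variability produced by the arbitrary template choice.  A voxel is kept
#' iff it is significant (at \code{alpha}, 0.01 or 0.05) in at least
#' \code{consensusFraction} of the per-template results; the default 1.0 is
#' the strict intersection.  Per-voxel support counts are always returned
#' so any other fraction is recoverable.
#'
#' @param results list of \linkS4class{StatMap}s, one per template, on one
#'   common reporting grid.
#' @param alpha 0.01 or 0.05, selecting which significance mask to combine.
#' @param consensusFraction fraction of templates required.
#' @return list with \code{consensus} (logical array), \code{support}
#'   (integer array of per-voxel counts), \code{nTemplates}, \code{alpha}
#'   and \code{fraction}.
#' @export
multiTemplateConsensus <- function(results, alpha = 0.01,
                                   consensusFraction = 1.0) {
    stopifnot(length(results) >= 2)
    if (!alpha %in% c(0.01, 0.05))
        stop("alpha must be 0.01 or 0.05 (the precomputed mask levels)")
    d <- dim(results[[1]]@mask)
    for (r in results)
        if (!identical(dim(r@mask), d))
            stop("per-template results are not on one common grid")
    slotName <- if (alpha == 0.01) "sig01" else "sig05"
    support <- array(0L, d)
    for (r in results)
        support <- support + array(as.integer(slot(r, slotName)), d)
    need <- ceiling(consensusFraction * length(results))
    list(consensus = support >= pmax(need, 1L), support = support,
         nTemplates = length(results), alpha = alpha,
         fraction = consensusFraction)
}
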