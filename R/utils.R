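## Internal array / tensor helpers.

## Shift a 3D array by integer offsets, padding with `fill`.
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
    d <- dim(a)
    out <- array(fill, d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
    out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
    out
}

## FA from an n x 3 eigenvalue matrix.  Zero tensors get FA = 0.
faFromEvals <- function(ev) {
    ev <- matrix(ev, ncol = 3)
    m <- rowMeans(ev)
    num <- rowSums((ev - m)^2)
    den <- rowSums(ev^2)
    fa <- sqrt(1.5 * num / pmax(den, .Machine$double.xmin))
    fa[den == 0] <- 0
    fa
}

## Deviation-scale factor that takes eigenvalues with FA f0 to target FA f,
## holding the trace fixed: lambda' = mean + s * (lambda - mean).
## Derived from FA = sqrt(3/2) * s*d / sqrt(3*mbar^2 + s^2 d^2) with
## d = ||lambda - mean||.
faScaleFactor <- function(ev, targetFA) {
    ev <- matrix(ev, ncol = 3)
    m <- rowMeans(ev)
    d <- sqrt(rowSums((ev - m)^2))
    f <- pmin(pmax(targetFA, 0), 1 - 1e-9)
    s <- sqrt(3) * m * f / (d * sqrt(1.5 - f^2))
    s[d == 0 & f == 0] <- 1
    s
}

## Ellipsoid membership on a voxel grid (1-based centre, semi-axes in voxels).
ellipsoidMask <- function(gridShape, centre, semiAxes) {
    x <- ((seq_len(gridShape[1]) - centre[1]) / semiAxes[1])^2
    y <- ((seq_len(gridShape[2]) - centre[2]) / semiAxes[2])^2
    z <- ((seq_len(gridShape[3]) - centre[3]) / semiAxes[3])^2
    outer(outer(x, y, `+`), z, `+`) <= 1
}

## Cylinder along one axis: radius in voxels, restricted to `within`.
cylinderMask <- function(gridShape, axis, centre, radius, within = NULL) {
    ax <- setdiff(1:3, axis)
    centre[is.na(centre)] <- 0
    co <- lapply(1:3, function(i) seq_len(gridShape[i]))
    r2 <- outer(outer((co[[1]] - centre[1])^2 * (1 %in% ax),
                      (co[[2]] - centre[2])^2 * (2 %in% ax), `+`),
                (co[[3]] - centre[3])^2 * (3 %in% ax), `+`)
    m <- r2 <= radius^2
    if (!is.null(within)) m <- m & within
    m
}

## Stop unless all arrays share one grid.
checkSameGrid <- function(...) {
    dims <- lapply(list(...), function(a) {
        d <- dim(a)
        if (length(d) == 4L) d[1:3] else d
    })
    for (i in seq_along(dims)[-1])
        if (!identical(dims[[1]], dims[[i]]))
            stop("inputs do not share a common voxel grid", call. = FALSE)
    invisible(TRUE)
}

## Flatten (x,y,z,K) to voxels-by-K for a logical mask.
flattenMasked <- function(a4, mask) {
    d <- dim(a4)
    m <- matrix(a4, nrow = prod(d[1:3]), ncol = d[4])
    m[as.vector(mask), , drop = FALSE]
}

## Rank rows of a matrix with mid-ranks (ties averaged).
rowRanksAvg <- function(m) {
    t(apply(m, 1L, rank, ties.method = "average"))
}

## Deterministic child seed derived from a base seed and a label:
## polynomial rolling hash mod a Mersenne prime, kept in 32-bit range.
childSeed <- function(seed, label) {
    h <- as.numeric(seed) %% 2147483647
    for (c in utf8ToInt(as.character(label)))
        h <- (h * 131 + c) %% 2147483647
    as.integer(h)
}
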