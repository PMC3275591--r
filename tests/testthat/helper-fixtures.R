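## Shared fixtures and brute-force oracles for the suite.

## Cache expensive cohort fixtures across test files within one run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
    .fixtures[[name]]
}

## Small single-region isotropic spec on a tiny grid, no jitter, no noise.
tinySpec <- function(evals = c(0.44, 0.44, 0.44) * 1e-3, direction = "isotropic",
                     grid = c(8L, 8L, 8L), noiseSigma = 0, deltaFA = 0) {
    mask <- array(FALSE, grid)
    mask[3:6, 3:6, 3:6] <- TRUE
    regions <- list(r1 = list(id = "r1", mask = mask, tissue = "GM",
                              direction = direction,
                              evals = sort(evals, decreasing = TRUE)))
    ge <- if (deltaFA > 0) c(r1 = deltaFA) else setNames(numeric(0), character(0))
    new("PhantomSpec", gridShape = grid, voxelSize = c(0.35, 0.35, 0.35),
        regions = regions, groupEffect = ge,
        subjectSd = c(adc = 0, anisotropy = 0, region = 0),
        noiseSigma = noiseSigma, noiseModel = "rician", s0 = 1,
        couplings = list(),
        birthWeight = list(control = c(mean = 47, sd = 9.3),
                           IUGR = c(mean = 30.4, sd = 12.2)))
}

## Measurement-noise-only zero-effect spec at full default geometry.
nullCalibrationSpec <- function() {
    defaultPhantomSpec(deltaFA = 0, couplingTarget = 0,
                       subjectSd = c(adc = 0, anisotropy = 0, region = 0),
                       effectJitterSd = 0)
}

## Per-subject mask + scalar maps of a cohort (the standard pipeline head).
fitCohort <- function(cohort) {
    out <- list(masks = list(), maps = list(), summaries = list())
    for (id in names(cohort@subjects)) {
        s <- cohort@subjects[[id]]
        bm <- computeBrainMask(computeIDWI(s$dwi))
        mp <- scalarMaps(fitTensors(s$dwi, bm, storeVectors = FALSE))
        out$masks[[id]] <- bm
        out$maps[[id]] <- mp
        out$summaries[[id]] <- summarizeSubject(
            mp, bm, id = id,
            birthWeight = cohort@manifest$birth_weight[
                match(id, cohort@manifest$id)])
    }
    out
}

effectRegionMask <- function(spec) {
    m <- array(FALSE, spec@gridShape)
    for (id in names(spec@groupEffect)) m <- m | spec@regions[[id]]$mask
    m
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## Brute-force 3D morphology oracles (definitional, O(n * kernel)).
bruteDilate6 <- function(a) {
    d <- dim(a); out <- a
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        if (a[x, y, z]) next
        nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                    c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
        nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
                 nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3], ,
                 drop = FALSE]
        if (any(a[nb])) out[x, y, z] <- TRUE
    }
    out
}

bruteErode6 <- function(a) {
    d <- dim(a); out <- a
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        if (!a[x, y, z]) next
        nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                    c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
        inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
               nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (any(!inb) || !all(a[nb])) out[x, y, z] <- FALSE
    }
    out
}

## Random symmetric positive-definite tensors (D = A'A + eps I) as n x 6
## component rows, vectorised for large n.
randomSPD <- function(n) {
    A <- array(rnorm(9 * n), c(n, 3, 3))   # A[i, row, col]
    dot <- function(ci, cj)
        rowSums(A[, , ci, drop = FALSE] * A[, , cj, drop = FALSE])
    cbind(dot(1, 1) + 1e-6, dot(2, 2) + 1e-6, dot(3, 3) + 1e-6,
          dot(1, 2), dot(1, 3), dot(2, 3))
}

randomRotation <- function() {
    qr.Q(qr(matrix(rnorm(9), 3)))
}
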