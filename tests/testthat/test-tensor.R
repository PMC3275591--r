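## helper: ScalarMapSet from an n x 3 eigenvalue matrix
mapsFromEvals <- function(ev) {
    n <- nrow(ev)
    tf <- new("TensorField",
              evals = array(ev, c(n, 1, 1, 3)),
              evecs = array(0, c(0, 0, 0, 0, 0)),
              tensors = array(0, c(0, 0, 0, 0)),
              s0 = array(1, c(n, 1, 1)),
              validMask = array(TRUE, c(n, 1, 1)),
              voxelSize = rep(1, 3), nClamped = 0L)
    scalarMaps(tf)
}

test_that("scalar maps match their closed forms", {
    ev <- rbind(c(1, 1, 1) * 0.7e-3,
                c(1, 0, 0),
                c(1.0, 0.5, 0.5) * 1e-3)
    m <- mapsFromEvals(ev)
    expect_equal(as.vector(m@fa), c(0, 1, sqrt(1 / 6)), tolerance = 1e-12)
    expect_equal(m@linearity[3, 1, 1], 0.25, tolerance = 1e-12)
    expect_equal(m@planarity[3, 1, 1], 0, tolerance = 1e-12)
    expect_equal(m@sphericity[3, 1, 1], 0.75, tolerance = 1e-12)
    expect_equal(m@adc[3, 1, 1], 2e-3 / 3, tolerance = 1e-15)
    expect_equal(m@axial[3, 1, 1], 1e-3)
    expect_equal(m@radial[3, 1, 1], 0.5e-3)
    expect_equal(m@sphericity[1, 1, 1], 1)
    expect_equal(m@linearity[2, 1, 1], 1)
})

test_that("Westin coefficients partition shape and FA is rotation invariant", {
    set.seed(1)
    comps <- randomSPD(2000)
    eig <- dtivba:::.eig3SymBatch(comps, FALSE)
    m <- mapsFromEvals(eig$values)
    s <- m@linearity + m@planarity + m@sphericity
    expect_lt(max(abs(s - 1)), 1e-12)
    expect_true(all(m@fa >= 0 & m@fa <= 1 + 1e-12))

    lam <- c(1.3, 0.7, 0.4) * 1e-3
    fa0 <- dtivba:::faFromEvals(matrix(lam, 1))
    for (i in 1:20) {
        R <- randomRotation()
        D <- R %*% diag(lam) %*% t(R)
        ev <- dtivba:::.eig3SymBatch(
            matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                   1), FALSE)$values
        expect_equal(dtivba:::faFromEvals(ev), fa0, tolerance = 1e-10)
    }
})

test_that("the batched eigensolver agrees with base eigen()", {
    set.seed(2)
    comps <- randomSPD(50)
    eig <- dtivba:::.eig3SymBatch(comps, TRUE)
    for (i in 1:50) {
        D <- matrix(c(comps[i, 1], comps[i, 4], comps[i, 5],
                      comps[i, 4], comps[i, 2], comps[i, 6],
                      comps[i, 5], comps[i, 6], comps[i, 3]), 3)
        ref <- eigen(D, symmetric = TRUE)
        expect_equal(eig$values[i, ], ref$values, tolerance = 1e-12)
        for (j in 1:3)
            expect_equal(abs(sum(eig$vectors[i, 3 * j - 2:0] *
                                 ref$vectors[, j])), 1, tolerance = 1e-9)
    }
})

test_that("log-linear fit agrees with an independent lm()-based fit", {
    spec <- tinySpec(evals = c(1.1, 0.6, 0.3) * 1e-3, direction = c(0, 0, 1))
    gen <- generateTensorField(spec, "control", seed = 1)
    sch <- acquisitionScheme(15)
    dwi <- simulateDWI(gen$field, sch, noiseSigma = 0.02, seed = 3)
    bm <- new("BrainMask", mask = gen$truth$brainMask,
              voxelSize = spec@voxelSize)
    tf <- fitTensors(dwi, bm)
    b <- sch@bvals; g <- sch@bvecs
    vox <- which(gen$truth$brainMask, arr.ind = TRUE)[1:5, , drop = FALSE]
    for (r in seq_len(nrow(vox))) {
        y <- log(dwi@data[vox[r, 1], vox[r, 2], vox[r, 3], ])
        fit <- lm(y ~ I(-b * g[1, ]^2) + I(-b * g[2, ]^2) + I(-b * g[3, ]^2) +
                      I(-2 * b * g[1, ] * g[2, ]) + I(-2 * b * g[1, ] * g[3, ]) +
                      I(-2 * b * g[2, ] * g[3, ]))
        D <- coef(fit)[-1]
        ref <- eigen(matrix(c(D[1], D[4], D[5], D[4], D[2], D[6],
                              D[5], D[6], D[3]), 3), symmetric = TRUE)$values
        got <- tf@evals[vox[r, 1], vox[r, 2], vox[r, 3], ]
        expect_equal(got, pmax(sort(ref, decreasing = TRUE), 0),
                     tolerance = 1e-8)
    }
})

test_that("flat signal profiles fit to isotropic tensors and bad voxels are excluded", {
    d <- c(3, 3, 3)
    sch <- acquisitionScheme(10)
    K <- length(sch@bvals)
    a <- array(rep(c(1, rep(exp(-1), K - 1)), each = prod(d)), c(d, K))
    a[1, 1, 1, 4] <- -0.5   # non-positive signal channel
    dwi <- new("DWIVolume", data = a, voxelSize = rep(1, 3), scheme = sch)
    tf <- fitTensors(dwi, new("BrainMask", mask = array(TRUE, d),
                              voxelSize = rep(1, 3)))
    expect_false(tf@validMask[1, 1, 1])
    ev <- tf@evals[2, 2, 2, ]
    expect_equal(ev, rep(mean(ev), 3), tolerance = 1e-6)
    ## collinear gradients are rejected
    badsch <- gradientScheme(c(0, rep(3000, 6)),
                             cbind(0, matrix(rep(c(1, 0, 0), 6), 3)))
    dwib <- new("DWIVolume", data = a[, , , 1:7], voxelSize = rep(1, 3),
                scheme = badsch)
    expect_error(fitTensors(dwib, new("BrainMask", mask = array(TRUE, d),
                                      voxelSize = rep(1, 3))),
                 "collinear|rank")
})

test_that("negative-eigenvalue voxels can be excluded instead of clamped", {
    spec <- tinySpec(evals = c(0.9, 0.6, 0.2) * 1e-3, direction = c(1, 0, 0))
    gen <- generateTensorField(spec, "control", seed = 2)
    ## heavy noise so some voxels fit a negative smallest eigenvalue
    dwi <- simulateDWI(gen$field, acquisitionScheme(15), noiseSigma = 0.25,
                       seed = 3)
    bm <- new("BrainMask", mask = gen$truth$brainMask,
              voxelSize = spec@voxelSize)
    tfClamp <- fitTensors(dwi, bm, storeVectors = FALSE)
    expect_gt(tfClamp@nClamped, 0)
    expect_true(all(tfClamp@evals >= 0))
    tfExcl <- fitTensors(dwi, bm, storeVectors = FALSE,
                         excludeNegative = TRUE)
    expect_equal(tfExcl@nClamped, tfClamp@nClamped)
    expect_equal(sum(tfClamp@validMask) - sum(tfExcl@validMask),
                 tfClamp@nClamped)
})

test_that("FA-threshold WM masks behave monotonically and match ground truth", {
    spec <- defaultPhantomSpec()
    gen <- generateTensorField(spec, "control", seed = 6)
    dwi <- simulateDWI(gen$field, acquisitionScheme(30),
                       noiseSigma = spec@noiseSigma, seed = 7)
    bm <- computeBrainMask(computeIDWI(dwi))
    maps <- scalarMaps(fitTensors(dwi, bm, storeVectors = FALSE))
    wm <- wmMaskFromFA(maps@fa, bm, 0.20)
    expect_gte(diceCoef(wm@mask, gen$truth$wmMask), 0.8)
    sizes <- vapply(seq(0.05, 0.40, 0.05), function(th)
        sum(suppressWarnings(wmMaskFromFA(maps@fa, bm, th))@mask), 0)
    expect_true(all(diff(sizes) <= 0))
    ## threshold 0 degenerates to all FA > 0 brain voxels
    m0 <- wmMaskFromFA(maps@fa, bm, 0)
    expect_identical(m0@mask, bm@mask & maps@fa > 0)
    expect_warning(wmMaskFromFA(maps@fa, bm, 0.99), "empty")
})

test_that("ADC is preserved under the phantom's trace-preserving FA reduction", {
    spec <- defaultPhantomSpec()
    gc0 <- generateTensorField(spec, "control", seed = 8,
                               storeTensors = FALSE, storeVectors = FALSE)
    gi <- generateTensorField(spec, "IUGR", seed = 8,
                              storeTensors = FALSE, storeVectors = FALSE)
    eff <- effectRegionMask(spec)
    adcC <- rowSums(matrix(gc0$field@evals, ncol = 3)[eff, ]) / 3
    adcI <- rowSums(matrix(gi$field@evals, ncol = 3)[eff, ]) / 3
    expect_equal(adcC, adcI, tolerance = 1e-12)
    expect_gt(mean(gc0$truth$trueFA[eff] - gi$truth$trueFA[eff]), 0.029)
})
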