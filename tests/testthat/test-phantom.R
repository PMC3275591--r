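test_that("default spec encodes the intended two-group generative law", {
    spec <- defaultPhantomSpec()
    expect_s4_class(spec, "PhantomSpec")
    expect_true(validObject(spec))
    cnt <- vapply(spec@regions, function(r) sum(r$mask), 0)
    fa <- vapply(spec@regions, function(r)
        dtivba:::faFromEvals(matrix(r$evals, 1)), 0)
    w <- cnt / sum(cnt)
    ## expected whole-brain FA of the two groups (analytic mixture)
    expect_lt(abs(sum(w * fa) - 0.16), 0.003)
    effW <- sum(cnt[names(spec@groupEffect)]) / sum(cnt)
    expect_lt(abs(sum(w * fa) - 0.03 * effW - 0.15), 0.003)
    ## >= 2 anisotropic tracts with distinct orientations
    dirs <- Filter(function(d) !identical(d, "isotropic"),
                   lapply(spec@regions, `[[`, "direction"))
    expect_gte(length(unique(dirs)), 2)
})

test_that("isotropic baselines give FA 0 and programmed WM directions are exact", {
    iso <- generateTensorField(tinySpec(), "control", seed = 1)
    expect_equal(max(iso$truth$trueFA), 0)
    wm <- generateTensorField(
        tinySpec(evals = c(1.0, 0.5, 0.5) * 1e-3, direction = c(1, 0, 0)),
        "control", seed = 1)
    e1 <- matrix(wm$field@evecs[, , , , 1], ncol = 3)[wm$truth$brainMask, ]
    expect_equal(abs(e1 %*% c(1, 0, 0)), matrix(1, nrow(e1)), tolerance = 1e-12)
    ## tensors are symmetric positive-definite in brain voxels
    ev <- matrix(wm$field@evals, ncol = 3)[wm$truth$brainMask, ]
    expect_true(all(ev > 0))
    expect_true(all(diff(t(ev)) <= 1e-15))
})

test_that("the programmed FA reduction preserves the trace and is recovered on average", {
    spec <- tinySpec(evals = c(1.0, 0.5, 0.5) * 1e-3, direction = c(1, 0, 0),
                     deltaFA = 0.05)
    gc0 <- generateTensorField(spec, "control", seed = 1)
    gi <- generateTensorField(spec, "IUGR", seed = 1)
    bm <- gc0$truth$brainMask
    expect_equal(gc0$truth$trueFA[bm] - gi$truth$trueFA[bm],
                 rep(0.05, sum(bm)), tolerance = 1e-12)
    adc0 <- rowSums(matrix(gc0$field@evals, ncol = 3)[bm, ])
    adc1 <- rowSums(matrix(gi$field@evals, ncol = 3)[bm, ])
    expect_equal(adc0, adc1, tolerance = 1e-12)   # trace-preserving

    ## with jitter, the group difference converges to DeltaFA (500 subjects)
    spec2 <- defaultPhantomSpec(deltaFA = 0.01)
    eff <- effectRegionMask(spec2)
    mfa <- function(group, off) mean(vapply(1:500, function(i) {
        g <- generateTensorField(spec2, group, seed = 10000 + 2 * i + off,
                                 storeTensors = FALSE, storeVectors = FALSE)
        mean(g$truth$trueFA[eff])
    }, 0))
    d <- mfa("control", 0) - mfa("IUGR", 1)
    expect_lt(abs(d - 0.01), 0.0025)   # ~3 Monte-Carlo standard errors
})

test_that("an infeasible FA reduction is rejected", {
    spec <- tinySpec(evals = c(0.50, 0.45, 0.40) * 1e-3,
                     direction = c(1, 0, 0), deltaFA = 0.9)
    expect_error(generateTensorField(spec, "IUGR", seed = 1), "infeasible")
})

test_that("simulated signal follows the closed-form tensor signal law", {
    spec <- tinySpec()   # isotropic D = 0.44e-3
    gen <- generateTensorField(spec, "control", seed = 1)
    sch <- acquisitionScheme(8, b = 3000)
    dwi <- simulateDWI(gen$field, sch, noiseSigma = 0)
    bm <- gen$truth$brainMask
    for (k in seq_along(sch@bvals)) {
        ch <- dwi@data[, , , k][bm]
        want <- if (sch@bvals[k] == 0) 1 else exp(-3000 * 0.44e-3)
        expect_equal(ch, rep(want, sum(bm)), tolerance = 1e-12)
    }
    expect_lt(abs(exp(-3000 * 0.44e-3) - 0.2671), 1e-4)
})

test_that("noiseless simulate -> fit round-trips the programmed tensors", {
    spec <- tinySpec(evals = c(1.0, 0.5, 0.5) * 1e-3, direction = c(1, 0, 0))
    gen <- generateTensorField(spec, "control", seed = 1)
    dwi <- simulateDWI(gen$field, acquisitionScheme(30), noiseSigma = 0)
    bm <- new("BrainMask", mask = gen$truth$brainMask,
              voxelSize = spec@voxelSize)
    tf <- fitTensors(dwi, bm)
    sel <- rep(gen$truth$brainMask, 3)
    relerr <- abs(tf@evals[sel] - gen$field@evals[sel]) /
              abs(gen$field@evals[sel])
    expect_lt(max(relerr), 1e-9)
})

test_that("cohort generation is seed-deterministic and group-balanced", {
    spec <- defaultPhantomSpec(gridShape = c(16L, 16L, 16L))
    a <- suppressWarnings(generateCohort(spec, 3, acquisitionScheme(8), seed = 5))
    b <- suppressWarnings(generateCohort(spec, 3, acquisitionScheme(8), seed = 5))
    expect_identical(a@manifest, b@manifest)
    expect_identical(a@subjects[["iugr02"]]$dwi@data,
                     b@subjects[["iugr02"]]$dwi@data)
    expect_equal(unname(table(a@manifest$group)), c(3, 3), ignore_attr = TRUE)
    expect_error(generateCohort(spec, 1), "nPerGroup")
})

test_that("zero group effect makes the imaging law exchangeable between groups", {
    spec <- defaultPhantomSpec(deltaFA = 0, couplingTarget = 0)
    gc0 <- generateTensorField(spec, "control", seed = 9)
    gi0 <- generateTensorField(spec, "IUGR", seed = 9)
    expect_identical(gc0$field@evals, gi0$field@evals)
    expect_identical(gc0$field@tensors, gi0$field@tensors)
})

test_that("behavioural coupling reaches its target before discretisation", {
    ## large cohort of latent draws: reproduce the copula outside the
    ## generator, seeded identically, to check the pre-discretisation target
    spec <- defaultPhantomSpec(gridShape = c(16L, 16L, 16L))
    coh <- suppressWarnings(
        generateCohort(spec, 150, acquisitionScheme(8), seed = 3))
    ach <- coh@achievedCouplings
    expect_equal(ach$score, "head_turn")
    expect_equal(ach$latent, 0.65, tolerance = 0.08)
    ## discretised score keeps most of the association
    expect_gt(ach$achieved, 0.45)
    ## zero coupling leaves scores independent of FA
    spec0 <- defaultPhantomSpec(gridShape = c(16L, 16L, 16L),
                                couplingTarget = 0)
    coh0 <- generateCohort(spec0, 150, acquisitionScheme(8), seed = 3)
    expect_lt(abs(coh0@achievedCouplings$achieved), 0.15)
})
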