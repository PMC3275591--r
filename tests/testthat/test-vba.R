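mkMask <- function(d, sub) {
    m <- array(FALSE, d); m[sub, sub, sub] <- TRUE; m
}

test_that("identity stacks pass maps through and intersect brain masks", {
    d <- c(10, 10, 10)
    set.seed(1)
    maps <- list(a = array(runif(1000), d), b = array(runif(1000), d))
    masks <- list(a = mkMask(d, 2:9), b = mkMask(d, 3:10))
    st <- buildStack(maps, masks, "a")
    expect_identical(st@maps$a, maps$a)
    expect_identical(st@maps$b, maps$b)
    expect_identical(st@mask, masks$a & masks$b)
    expect_equal(unname(st@provenance), rep("identity", 2))
    ## mismatched grid without a transform is an error
    maps$cc <- array(0, c(8, 8, 8)); masks$cc <- mkMask(c(8, 8, 8), 2:7)
    expect_error(buildStack(maps, masks, "a"), "different grid")
})

test_that("a pure translation affine shifts the resampled map exactly", {
    d <- c(12, 12, 12)
    set.seed(2)
    src <- array(rnorm(prod(d)), d)
    A <- diag(4); A[1:3, 4] <- c(2, 0, 0)   # template (x,y,z) samples source x+2
    res <- applyTransform(src, A, d)
    expect_equal(res[1:9, 2:11, 2:11], src[3:11, 2:11, 2:11],
                 tolerance = 1e-12)
    ## nearest-neighbour round-trips integer labels
    lab <- array(sample(0:3, prod(d), TRUE), d)
    resL <- applyTransform(lab, A, d, "nearest")
    expect_identical(resL[1:9, , ], lab[3:11, , ] * 1)
    ## dense warp equal to the same translation agrees
    warp <- array(0, c(d, 3)); warp[, , , 1] <- 2
    resW <- applyTransform(src, warp, d)
    expect_equal(resW[1:9, 2:11, 2:11], src[3:11, 2:11, 2:11],
                 tolerance = 1e-12)
})

test_that("internal affine registration recovers a known misalignment", {
    spec <- defaultPhantomSpec()
    gen <- generateTensorField(spec, "control", seed = 3,
                               storeTensors = FALSE, storeVectors = FALSE)
    ## a smooth target: piecewise-constant truth loses ~8% correlation to
    ## double trilinear interpolation alone, which would mask the
    ## registration quality being tested
    fa <- smoothMap(smoothMap(gen$truth$trueFA))
    ctr <- (dim(fa) + 1) / 2
    A <- dtivba:::affineFromParams(c(1.5, -1, 0.5, 0.06, -0.04, 0.08,
                                     0, 0, 0, 0, 0, 0), ctr)
    moved <- applyTransform(fa, A, dim(fa))
    reg <- registerAffine(moved, fa, maxit = 300)
    back <- applyTransform(moved, reg$affine, dim(fa))
    inner <- fa > 0
    expect_gt(cor(back[inner], fa[inner]), 0.99)
})

test_that("masked Gaussian smoothing is exact on constants and impulses", {
    d <- c(11, 11, 11)
    mask <- mkMask(d, 2:10)
    const <- array(0, d); const[mask] <- 0.7
    sm <- smoothMap(const, mask)
    expect_equal(sm[mask], rep(0.7, sum(mask)), tolerance = 1e-12)
    expect_equal(sm[!mask], rep(0, sum(!mask)))
    ## unit impulse at the mask centre: weight = g(0) / sum(kernel)
    imp <- array(0, d); imp[6, 6, 6] <- 1
    sm2 <- smoothMap(imp, mask)
    off <- expand.grid(-1:1, -1:1, -1:1)
    w <- exp(-(off[[1]]^2 + off[[2]]^2 + off[[3]]^2) / 2)
    expect_equal(sm2[6, 6, 6], 1 / sum(w), tolerance = 1e-12)
    ## smoothing twice differs from one sqrt(2)-sigma pass only by truncation
    tw <- smoothMap(smoothMap(imp, mask), mask)
    onewide <- smoothMap(imp, mask, sigma = sqrt(2))
    expect_gt(cor(tw[mask], onewide[mask]), 0.9)
    expect_false(isTRUE(all.equal(tw[mask], onewide[mask])))
})

test_that("voxel-wise t maps are correct, nested, and null on duplicated groups", {
    d <- c(8, 8, 8)
    set.seed(4)
    ctrl <- lapply(1:5, function(i) array(rnorm(prod(d), 1), d))
    maps <- c(ctrl, ctrl)   # IUGR duplicates control exactly
    names(maps) <- paste0("s", 1:10)
    masks <- setNames(rep(list(array(TRUE, d)), 10), names(maps))
    man <- data.frame(id = names(maps),
                      group = rep(c("control", "IUGR"), each = 5))
    st <- buildStack(maps, masks, "s1")
    gt <- voxelwiseGroupTest(st, man)
    expect_true(all(gt@p[st@mask] == 1))
    ## nestedness and agreement with t.test on independent data
    maps2 <- lapply(1:10, function(i) array(rnorm(prod(d), i %% 2), d))
    names(maps2) <- names(maps)
    st2 <- buildStack(maps2, masks, "s1")
    gt2 <- voxelwiseGroupTest(st2, man)
    expect_true(all(gt2@sig05[gt2@sig01]))
    v <- c(3, 4, 5)
    ref <- t.test(vapply(maps2[1:5], function(m) m[3, 4, 5], 0),
                  vapply(maps2[6:10], function(m) m[3, 4, 5], 0),
                  var.equal = TRUE)
    expect_equal(gt2@p[3, 4, 5], ref$p.value, tolerance = 1e-12)
    expect_equal(gt2@statistic[3, 4, 5], unname(ref$statistic),
                 tolerance = 1e-12)
})

test_that("voxel-wise Spearman flags perfect monotone association", {
    d <- c(6, 6, 6)
    vals <- seq_len(10)
    maps <- lapply(vals, function(v) array(v + 0.1, d))
    names(maps) <- paste0("s", 1:10)
    masks <- setNames(rep(list(array(TRUE, d)), 10), names(maps))
    man <- data.frame(id = names(maps), group = rep(c("control", "IUGR"), 5),
                      head_turn = vals)
    st <- buildStack(maps, masks, "s1")
    vc <- voxelwiseCorrelation(st, "head_turn", man)
    expect_equal(vc@statistic[2, 2, 2], 1)
    expect_equal(vc@p[2, 2, 2], 0)
    man$head_turn[3] <- NA
    vc2 <- voxelwiseCorrelation(st, "head_turn", man)
    expect_equal(vc2@statistic[2, 2, 2], 1)   # pairwise deletion, still monotone
    disp <- correlationDisplayMask(vc, 0.2)
    expect_true(all(disp[st@mask]))   # rho = 1 everywhere in mask
    man$head_turn <- 2
    expect_error(voxelwiseCorrelation(st, "head_turn", man), "constant")
})

test_that("consensus combines templates by support with monotone strictness", {
    d <- c(5, 5, 5)
    mk <- function(sig) {
        p <- array(0.5, d); p[sig] <- 0.001
        new("StatMap", statistic = array(1, d), p = p,
            sig01 = p < 0.01, sig05 = p < 0.05,
            direction = array(1, d), mask = array(TRUE, d),
            method = "t", voxelSize = rep(1, 3))
    }
    s1 <- mk(1:10); s2 <- mk(1:10)
    cons <- multiTemplateConsensus(list(s1, s2), 0.01, 1.0)
    expect_identical(cons$consensus, s1@sig01)   # unanimity
    s3 <- mk(5:12)
    strict <- multiTemplateConsensus(list(s1, s2, s3), 0.01, 1.0)
    expect_identical(which(strict$consensus), 5:10)
    loose <- multiTemplateConsensus(list(s1, s2, s3), 0.01, 0.5)
    expect_identical(which(loose$consensus), 1:10)
    expect_true(all(loose$consensus[strict$consensus]))  # nested in fraction
    expect_lte(sum(strict$consensus), sum(loose$consensus))
    expect_equal(max(strict$support), 3)
    expect_error(multiTemplateConsensus(list(s1, s2), alpha = 0.2), "alpha")
})
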