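## constant-map fixture: ScalarMapSet with FA = fa0 inside a given mask
constantMaps <- function(mask, fa0 = 0.3, adc0 = 0.5e-3) {
    d <- dim(mask)
    mk <- function(v) { a <- array(0, d); a[mask] <- v; a }
    new("ScalarMapSet", fa = mk(fa0), adc = mk(adc0), axial = mk(adc0 * 1.2),
        radial = mk(adc0 * 0.9), linearity = mk(0.2), planarity = mk(0.1),
        sphericity = mk(0.7), validMask = mask,
        degenerate = array(FALSE, d), voxelSize = rep(0.35, 3))
}

test_that("subject summaries reduce constant fields exactly", {
    mask <- array(FALSE, c(10, 10, 10)); mask[3:8, 3:8, 3:8] <- TRUE
    bm <- new("BrainMask", mask = mask, voxelSize = rep(0.35, 3))
    s <- summarizeSubject(constantMaps(bm@mask), bm, id = "s1",
                          birthWeight = 40)
    expect_equal(unname(s$wholeBrain["fa"]), 0.3)
    ## every threshold below 0.3 sees the same constant field
    expect_true(all(abs(s$wm[seq(0.05, 0.25, 0.05) / 0.05, "fa"] - 0.3) < 1e-12))
    expect_true(all(is.na(s$wm[format(seq(0.3, 0.4, 0.05)), "fa"])))
    expect_equal(s$brainVolume, sum(mask) * 0.35^3)
    expect_equal(s$volumeWeightRatio, s$brainVolume / 40)
})

test_that("ROI means are computed per label and respect affines", {
    mask <- array(TRUE, c(8, 8, 8))
    bm <- new("BrainMask", mask = mask, voxelSize = rep(1, 3))
    maps <- constantMaps(mask, fa0 = 0.25)
    maps@fa[1:4, , ] <- 0.1
    labels <- array(0L, c(8, 8, 8))
    labels[1:4, , ] <- 1L; labels[5:8, , ] <- 2L
    s <- summarizeSubject(maps, bm, rois = labels, id = "s1")
    expect_equal(unname(s$roi["roi1", "fa"]), 0.1)
    expect_equal(unname(s$roi["roi2", "fa"]), 0.25)
    ## labels in another space pulled through a translation affine
    A <- diag(4); A[1, 4] <- -2   # template x maps to source x - 2
    s2 <- summarizeSubject(maps, bm, rois = list(labels = labels, affine = A),
                           id = "s1")
    expect_true(all(c("roi1", "roi2") %in% rownames(s2$roi)))
    expect_error(summarizeSubject(maps, bm,
                                  rois = array(0L, c(4, 4, 4)), id = "s"),
                 "grid")
})

test_that("WM-mask mean FA is non-decreasing in the FA threshold", {
    spec <- defaultPhantomSpec()
    gen <- generateTensorField(spec, "control", seed = 10)
    dwi <- simulateDWI(gen$field, acquisitionScheme(30),
                       noiseSigma = spec@noiseSigma, seed = 11)
    bm <- computeBrainMask(computeIDWI(dwi))
    maps <- scalarMaps(fitTensors(dwi, bm, storeVectors = FALSE))
    s <- summarizeSubject(maps, bm, id = "x")
    faSweep <- s$wm[, "fa"]
    expect_true(all(diff(faSweep[!is.na(faSweep)]) >= -1e-12))
})

test_that("identical duplicated subjects in both groups compare as equal", {
    mask <- array(FALSE, c(8, 8, 8)); mask[2:7, 2:7, 2:7] <- TRUE
    bm <- new("BrainMask", mask = mask, voxelSize = rep(1, 3))
    base <- constantMaps(mask)
    summaries <- lapply(1:8, function(i) {
        m <- base
        m@fa[mask] <- m@fa[mask] + (i %% 4) * 0.01   # same values in each group
        summarizeSubject(m, bm, id = paste0("s", i), birthWeight = 40)
    })
    man <- data.frame(id = paste0("s", 1:8),
                      group = rep(c("control", "IUGR"), each = 4),
                      birth_weight = 40)
    tab <- compareCohort(summaries, man)
    expect_true(all(tab$p[!is.na(tab$p)] == 1))
})

test_that("cohort comparison finds a programmed WM FA deficit at large n", {
    ## full default geometry: the 16^3 grid has too few tract voxels inside
    ## the effect region to carry the white-matter row
    spec <- defaultPhantomSpec()
    coh <- suppressWarnings(
        generateCohort(spec, 25, acquisitionScheme(10), seed = 12))
    f <- fitCohort(coh)
    tab <- compareCohort(f$summaries, coh@manifest)
    row <- tab[tab$measure == "wm_fa", ]
    expect_lt(row$p, 0.05)
    cm <- vapply(f$summaries[coh@manifest$group == "control"],
                 function(s) summaryValue(s, "wm", "fa"), 0)
    im <- vapply(f$summaries[coh@manifest$group == "IUGR"],
                 function(s) summaryValue(s, "wm", "fa"), 0)
    expect_gt(mean(cm), mean(im))   # direction: control > IUGR
    wb <- tab[tab$measure == "wholebrain_fa", ]
    expect_lt(wb$p, 0.05)
})

test_that("behaviour correlations use pairwise deletion and flag constants", {
    mask <- array(TRUE, c(6, 6, 6))
    bm <- new("BrainMask", mask = mask, voxelSize = rep(1, 3))
    set.seed(13)
    summaries <- lapply(1:12, function(i)
        summarizeSubject(constantMaps(mask, fa0 = 0.2 + i * 0.01 + rnorm(1, 0, 0.001)),
                         bm, id = paste0("s", i)))
    man <- data.frame(id = paste0("s", 1:12),
                      group = rep(c("control", "IUGR"), 6),
                      head_turn = c(NA, NA, NA, 1:9),
                      posture = rep(2, 12))
    tab <- behaviorCorrelationTable(summaries, man,
                                    scoreNames = c("head_turn", "posture"))
    ht <- tab[tab$score == "head_turn" & tab$mask == "wholebrain" &
              tab$metric == "fa", ]
    expect_equal(ht$n, 9)   # three missing scores dropped pairwise
    expect_gt(ht$rho, 0.9)  # score tracks FA by construction
    po <- tab[tab$score == "posture" & tab$mask == "wholebrain" &
              tab$metric == "fa", ]
    expect_true(po$degenerate)
    expect_true(is.na(po$rho))
})
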