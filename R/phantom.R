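#' Default two-group phantom specification
#'
#' Builds the reference phantom: an ellipsoidal "brain" of mildly
#' anisotropic, randomly oriented grey matter with two embedded white-matter
#' tracts of distinct orientations (along x and along y), and a spherical
#' effect region straddling grey matter and both tracts in which the IUGR
#' group's FA is reduced (trace preserved, so ADC is unchanged).  One
#' behavioural coupling ties the "head_turn" score to the effect region's
#' true mean FA.
#'
#' Baseline eigenvalues and variability were calibrated once so that, at
#' defaults, the control group's expected whole-brain mean FA is about 0.16
#' (between-subject sd about 0.02) with mean ADC about 0.44e-3 mm^2/s (sd
#' about 0.08e-3), the IUGR group's whole-brain FA is about 0.01 lower, and
#' tract FA is about 0.27 - the regime of ex vivo neonatal rabbit brain at
#' high b-value.
#'
#' @param gridShape voxel counts per axis (default 32^3, a desk-scale grid).
#' @param voxelSize mm per axis (default 0.35 isotropic).
#' @param deltaFA FA reduction programmed in the effect region for the IUGR
#'   group.  Default 0.03, which spread over the effect region's share of
#'   the brain yields a whole-brain difference of about 0.01.  0 gives a
#'   zero-effect (null) phantom.
#' @param noiseSigma Rician noise scale relative to \code{s0}.  The default
#'   0.005 corresponds to the very high SNR of a long ex vivo acquisition;
#'   it keeps the image background well below the 5 percent masking
#'   threshold while still exercising the noise path.
#' @param couplingTarget latent correlation between the "head_turn" score
#'   and effect-region mean FA.  Default 0.65; 0 decouples scores from the
#'   images.
#' @param subjectSd named numeric: \code{adc} (global diffusivity factor
#'   sd), \code{anisotropy} (global anisotropy factor sd), \code{region}
#'   (default per-region anisotropy factor sd).
#' @param effectJitterSd anisotropy-factor sd of the shared latent factor
#'   of the three effect regions.  The effect regions express one common
#'   "maturation" factor - regional microstructure that varies coherently
#'   between animals and carries the behavioural coupling.
#' @param noiseModel "rician" (magnitude MRI) or "gaussian".
#' @return A \linkS4class{PhantomSpec}.
#' @export
defaultPhantomSpec <- function(gridShape = c(32L, 32L, 32L),
                               voxelSize = c(0.35, 0.35, 0.35),
                               deltaFA = 0.03, noiseSigma = 0.005,
                               couplingTarget = 0.65,
                               subjectSd = c(adc = 0.18, anisotropy = 0.03,
                                             region = 0.05),
                               effectJitterSd = 0.07,
                               noiseModel = "rician") {
    gridShape <- as.integer(gridShape)
    ctr <- (gridShape + 1) / 2
    brain <- ellipsoidMask(gridShape, ctr, gridShape * c(13, 11, 10) / 32)
    tx <- cylinderMask(gridShape, 1L, c(NA, ctr[2], ctr[3] - 4),
                       gridShape[1] * 3 / 32, within = brain)
    ty <- cylinderMask(gridShape, 2L, c(ctr[1], NA, ctr[3] + 4),
                       gridShape[2] * 3 / 32, within = brain)
    ty <- ty & !tx
    gm <- brain & !tx & !ty
    eff <- ellipsoidMask(gridShape, ctr, rep(gridShape[1] * 8 / 32, 3)) & brain
    ## calibrated baselines: trace 1.32e-3 mm^2/s in both tissues;
    ## GM FA ~ 0.132, tract FA ~ 0.27
    evGM <- c(0.5051, 0.4075, 0.4075) * 1e-3
    evWM <- c(0.5806, 0.3697, 0.3697) * 1e-3
    reg <- function(id, mask, tissue, direction, evals,
                    jitterGroup = id, jitterSd = NA_real_)
        list(id = id, mask = mask, tissue = tissue, direction = direction,
             evals = evals, jitterGroup = jitterGroup, jitterSd = jitterSd)
    regions <- list(
        reg("gm", gm & !eff, "GM", "isotropic", evGM),
        reg("gm_effect", gm & eff, "GM", "isotropic", evGM,
            "effect", effectJitterSd),
        reg("tract_x", tx & !eff, "WM", c(1, 0, 0), evWM,
            "effect", effectJitterSd),
        reg("tract_x_effect", tx & eff, "WM", c(1, 0, 0), evWM,
            "effect", effectJitterSd),
        reg("tract_y", ty & !eff, "WM", c(0, 1, 0), evWM,
            "effect", effectJitterSd),
        reg("tract_y_effect", ty & eff, "WM", c(0, 1, 0), evWM,
            "effect", effectJitterSd))
    names(regions) <- vapply(regions, `[[`, "", "id")
    groupEffect <- if (deltaFA > 0)
        setNames(rep(deltaFA, 3),
                 c("gm_effect", "tract_x_effect", "tract_y_effect"))
    else setNames(numeric(0), character(0))
    couplings <- list(list(score = "head_turn",
                           region = c("gm_effect", "tract_x_effect",
                                      "tract_y_effect"),
                           target = couplingTarget))
    new("PhantomSpec", gridShape = gridShape,
        voxelSize = as.numeric(voxelSize), regions = regions,
        groupEffect = groupEffect, subjectSd = subjectSd,
        noiseSigma = noiseSigma, noiseModel = noiseModel, s0 = 1,
        couplings = couplings,
        birthWeight = list(control = c(mean = 47.0, sd = 9.3),
                           IUGR = c(mean = 30.4, sd = 12.2)))
}

## Orthonormal frame completing a set of unit vectors (rows of e1).
completeFrame <- function(e1) {
    n <- nrow(e1)
    ref <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    flip <- abs(e1[, 3]) > 0.9
    ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
    e2 <- cbind(e1[, 2] * ref[, 3] - e1[, 3] * ref[, 2],
                e1[, 3] * ref[, 1] - e1[, 1] * ref[, 3],
                e1[, 1] * ref[, 2] - e1[, 2] * ref[, 1])
    e2 <- e2 / sqrt(rowSums(e2^2))
    e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    list(e1 = e1, e2 = e2, e3 = e3)
}

## Six unique tensor components from per-voxel frames and eigenvalues.
tensorComponents <- function(fr, ev) {
    comp <- function(i, j)
        ev[, 1] * fr$e1[, i] * fr$e1[, j] +
        ev[, 2] * fr$e2[, i] * fr$e2[, j] +
        ev[, 3] * fr$e3[, i] * fr$e3[, j]
    cbind(comp(1, 1), comp(2, 2), comp(3, 3),
          comp(1, 2), comp(1, 3), comp(2, 3))
}

#' Generate one subject's true tensor field
#'
#' Draws the subject's between-subject factors (a global diffusivity factor,
#' a global anisotropy factor, and independent per-region anisotropy
#' factors), builds a symmetric positive-definite tensor in every brain
#' voxel (constant eigenvalues per region; white-matter principal
#' eigenvectors equal the region's programmed direction, "isotropic"
#' regions get a random per-voxel orientation), and - for the IUGR group -
#' rescales eigenvalue deviations in effect regions so the region's FA drops
#' by the programmed amount with the trace (hence ADC) preserved.
#' Background voxels hold zero diffusivity and zero unweighted signal.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param group "control" or "IUGR".
#' @param seed integer seed (all randomness is drawn under it).
#' @param storeTensors,storeVectors set FALSE to skip materialising the
#'   (x,y,z,6) tensor array / eigenvector array when only eigenvalue-based
#'   ground truth is needed.
#' @return list with \code{field} (a \linkS4class{TensorField}) and
#'   \code{truth} (true FA map, per-region eigenvalues and mean FA, brain /
#'   white-matter / effect-region masks).
#' @export
generateTensorField <- function(spec, group = c("control", "IUGR"), seed,
                                storeTensors = TRUE, storeVectors = TRUE) {
    group <- match.arg(group)
    validObject(spec)
    set.seed(seed)
    d <- spec@gridShape
    nv <- prod(d)
    evalsArr <- array(0, c(d, 3))
    tens <- if (storeTensors) matrix(0, nv, 6) else NULL
    vecs <- if (storeVectors) matrix(0, nv, 9) else NULL
    s0 <- array(0, d)
    trueFA <- array(0, d)
    brain <- array(FALSE, d)
    wm <- array(FALSE, d)
    effMask <- array(FALSE, d)

    sdv <- spec@subjectSd
    mAdc <- max(0.2, rnorm(1, 1, sdv[["adc"]]))
    aGlob <- max(0.05, rnorm(1, 1, sdv[["anisotropy"]]))

    ## per-region anisotropy factors; regions sharing a jitterGroup share
    ## one factor (a coherent latent "maturation" factor across them)
    jg <- vapply(spec@regions, function(r)
        if (is.null(r$jitterGroup)) r$id else r$jitterGroup, "")
    jsd <- vapply(spec@regions, function(r)
        if (is.null(r$jitterSd) || is.na(r$jitterSd)) sdv[["region"]]
        else r$jitterSd, 0)
    groupFac <- setNames(rep(NA_real_, length(unique(jg))), unique(jg))
    for (g in names(groupFac))
        groupFac[[g]] <- max(0.05, rnorm(1, 1, jsd[match(g, jg)]))

    regionFA <- regionEvals <- list()
    ev1 <- matrix(0, nv, 3)  # flattened eigenvalue store
    for (rg in spec@regions) {
        idx <- which(rg$mask)
        if (rg$tissue == "background" || length(idx) == 0) next
        ev0 <- rg$evals
        m0 <- mean(ev0)
        a <- aGlob * groupFac[[if (is.null(rg$jitterGroup)) rg$id
                               else rg$jitterGroup]]
        if (ev0[3] < m0)             # keep the smallest eigenvalue positive
            a <- min(a, 0.999 * m0 / (m0 - ev0[3]))
        ev <- mAdc * (m0 + a * (ev0 - m0))
        if (group == "IUGR" && rg$id %in% names(spec@groupEffect)) {
            dfa <- spec@groupEffect[[rg$id]]
            f0 <- faFromEvals(matrix(ev, 1))
            ft <- f0 - dfa
            if (ft < 0)
                stop("programmed FA reduction ", dfa,
                     " infeasible for region '", rg$id, "' (baseline FA ",
                     signif(f0, 3), ")")
            s <- faScaleFactor(matrix(ev, 1), ft)
            ev <- mean(ev) + s * (ev - mean(ev))
            if (any(ev <= 0))
                stop("FA adjustment drove an eigenvalue non-positive in region '",
                     rg$id, "'")
            effMask[idx] <- TRUE
        }
        ev <- sort(ev, decreasing = TRUE)
        n <- length(idx)
        if (!storeTensors && !storeVectors) {
            ## eigenvalue-only path (ground-truth Monte-Carlo): orientations
            ## do not affect eigenvalue-derived quantities
            evm <- matrix(ev, n, 3, byrow = TRUE)
        } else if (identical(rg$direction, "isotropic")) {
            z <- matrix(rnorm(3 * n), ncol = 3)
            e1 <- z / sqrt(rowSums(z^2))
            fr <- completeFrame(e1)
            evm <- matrix(ev, n, 3, byrow = TRUE)
        } else {
            u <- rg$direction / sqrt(sum(rg$direction^2))
            fr <- completeFrame(matrix(u, 1))
            fr <- lapply(fr, function(e) matrix(e, n, 3, byrow = TRUE))
            evm <- matrix(ev, n, 3, byrow = TRUE)
        }
        if (storeTensors) tens[idx, ] <- tensorComponents(fr, evm)
        if (storeVectors) vecs[idx, ] <- cbind(fr$e1, fr$e2, fr$e3)
        ev1[idx, ] <- evm
        fa <- faFromEvals(matrix(ev, 1))
        trueFA[idx] <- fa
        brain[idx] <- TRUE
        if (rg$tissue == "WM") wm[idx] <- TRUE
        s0[idx] <- spec@s0
        regionFA[[rg$id]] <- fa
        regionEvals[[rg$id]] <- ev
    }
    evalsArr <- array(ev1, c(d, 3))
    field <- new("TensorField",
        evals = evalsArr,
        evecs = if (storeVectors) array(vecs, c(d, 3, 3)) else array(0, c(0, 0, 0, 0, 0)),
        tensors = if (storeTensors) array(tens, c(d, 6)) else array(0, c(0, 0, 0, 0)),
        s0 = s0, validMask = brain, voxelSize = spec@voxelSize,
        nClamped = 0L)
    truth <- list(trueFA = trueFA, regionMeanFA = unlist(regionFA),
                  regionEvals = regionEvals, brainMask = brain,
                  wmMask = wm, effectMask = effMask,
                  factors = c(adc = mAdc, anisotropy = aGlob))
    list(field = field, truth = truth)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' The noiseless channel obeys the mono-exponential single-tensor signal law
#' S_k = S0 exp(-b_k g_k' D g_k) exactly.  Noise is Rician by default (the
#' magnitude of the complex signal with i.i.d. Gaussian noise of scale
#' \code{noiseSigma} on both channels), or plain additive Gaussian.
#'
#' @param field a \linkS4class{TensorField} with tensors materialised.
#' @param scheme a \linkS4class{GradientScheme} with >= 1 b = 0 measurement.
#' @param s0 unweighted signal; defaults to the field's s0 map.
#' @param noiseSigma noise scale in signal units (same units as s0).
#' @param seed integer seed; required when noiseSigma > 0.
#' @param model "rician" or "gaussian".
#' @return A \linkS4class{DWIVolume}.
#' @export
simulateDWI <- function(field, scheme, s0 = NULL, noiseSigma = 0,
                        seed = NULL, model = c("rician", "gaussian")) {
    model <- match.arg(model)
    validObject(scheme)
    if (!length(field@tensors))
        stop("tensor components not materialised (storeTensors = FALSE?)")
    d <- dim(field@validMask)
    nv <- prod(d)
    K <- length(scheme@bvals)
    g <- scheme@bvecs
    G <- cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
               2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
               2 * g[2, ] * g[3, ]) * scheme@bvals
    tens <- matrix(field@tensors, nv, 6)
    s0v <- if (is.null(s0)) as.vector(field@s0) else rep(s0, length.out = nv)
    S <- s0v * exp(-tens %*% t(G))
    if (noiseSigma > 0) {
        if (is.null(seed)) stop("seed required when noiseSigma > 0")
        set.seed(seed)
        if (model == "rician") {
            S <- sqrt((S + rnorm(nv * K, 0, noiseSigma))^2 +
                      rnorm(nv * K, 0, noiseSigma)^2)
        } else {
            S <- S + rnorm(nv * K, 0, noiseSigma)
        }
    }
    new("DWIVolume", data = array(S, c(d, K)), voxelSize = field@voxelSize,
        scheme = scheme)
}

#' Generate a two-group phantom cohort
#'
#' Generates \code{nPerGroup} control and \code{nPerGroup} IUGR subjects on
#' one shared grid (identity registration is exact by construction).  Each
#' subject gets a simulated DWI volume, ground truth (true FA map, masks,
#' per-region mean FA), a birth weight drawn from the group's law, and the
#' 13 behavioural scores.  Coupled scores are drawn through a Gaussian
#' copula: the latent score is \code{target * z(FA) + sqrt(1 - target^2) *
#' eps} with z(FA) the cohort-standardised true mean FA of the coupled
#' region, then discretised to the score's registry scale.  The achieved
#' (post-discretisation) correlation is reported in the returned object and
#' a warning is raised when discretisation moves it more than 0.2 from the
#' target.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nPerGroup subjects per group (>= 2).
#' @param scheme acquisition scheme; default 30 directions at b = 3000.
#' @param seed integer master seed; every subject and score stream derives
#'   its own child seed from it.
#' @return A \linkS4class{CohortDataset}.
#' @export
generateCohort <- function(spec, nPerGroup = 10,
                           scheme = acquisitionScheme(30), seed = 1) {
    if (nPerGroup < 2) stop("nPerGroup must be >= 2")
    validObject(spec)
    groups <- rep(c("control", "IUGR"), each = nPerGroup)
    ids <- c(sprintf("ctrl%02d", seq_len(nPerGroup)),
             sprintf("iugr%02d", seq_len(nPerGroup)))
    subjects <- vector("list", length(ids))
    names(subjects) <- ids
    for (i in seq_along(ids)) {
        gen <- generateTensorField(spec, groups[i],
                                   seed = childSeed(seed, ids[i]),
                                   storeVectors = FALSE)
        dwi <- simulateDWI(gen$field, scheme,
                           noiseSigma = spec@noiseSigma,
                           seed = childSeed(seed, paste0(ids[i], ".dwi")),
                           model = spec@noiseModel)
        subjects[[i]] <- list(id = ids[i], group = groups[i], dwi = dwi,
                              truth = gen$truth)
    }
    ## behavioural scores and birth weights
    set.seed(childSeed(seed, "manifest"))
    n <- length(ids)
    bw <- numeric(n)
    for (g in c("control", "IUGR")) {
        law <- spec@birthWeight[[g]]
        sel <- groups == g
        bw[sel] <- pmax(5, rnorm(sum(sel), law[["mean"]], law[["sd"]]))
    }
    reg <- scoreRegistry()
    coupledBy <- setNames(rep(NA_integer_, nrow(reg)), reg$name)
    for (j in seq_along(spec@couplings))
        coupledBy[[spec@couplings[[j]]$score]] <- j
    scores <- matrix(NA_real_, n, nrow(reg),
                     dimnames = list(ids, reg$name))
    achieved <- NULL
    for (k in seq_len(nrow(reg))) {
        entry <- reg[k, ]
        eps <- rnorm(n)
        j <- coupledBy[[entry$name]]
        if (!is.na(j)) {
            cp <- spec@couplings[[j]]
            faVec <- vapply(subjects, function(s) {
                rf <- s$truth$regionMeanFA[cp$region]
                nvx <- vapply(cp$region, function(r)
                    sum(spec@regions[[r]]$mask), 0)
                sum(rf * nvx) / sum(nvx)
            }, 0)
            z <- if (sd(faVec) > 0) as.vector(scale(faVec)) else rep(0, n)
            latent <- cp$target * z + sqrt(1 - cp$target^2) * eps
            sc <- discretiseScore(latent, entry)
            ach <- if (sd(sc) > 0 && sd(faVec) > 0) cor(sc, faVec)
                   else NA_real_
            achieved <- rbind(achieved, data.frame(
                score = entry$name,
                region = paste(cp$region, collapse = "+"),
                target = cp$target,
                latent = cor(latent, faVec), achieved = ach))
            if (cp$target != 0 && (is.na(ach) || abs(ach - cp$target) > 0.2))
                warning("coupling for '", entry$name,
                        "': achieved correlation ",
                        if (is.na(ach)) "undefined" else signif(ach, 3),
                        " differs from target ", cp$target,
                        " after discretisation")
            scores[, k] <- sc
        } else {
            scores[, k] <- discretiseScore(eps, entry)
        }
    }
    manifest <- data.frame(id = ids, group = groups, birth_weight = bw,
                           scores, stringsAsFactors = FALSE)
    rownames(manifest) <- NULL
    if (is.null(achieved))
        achieved <- data.frame(score = character(), region = character(),
                               target = numeric(), latent = numeric(),
                               achieved = numeric())
    new("CohortDataset", subjects = subjects, manifest = manifest,
        spec = spec, scheme = scheme, achievedCouplings = achieved)
}

#' Write a phantom cohort to disk
#'
#' Writes per-subject 4D DWI NIfTIs with FSL .bval/.bvec tables, the
#' subject manifest CSV, and ground-truth masks (brain, white matter,
#' effect region) plus the true FA map per subject.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vs <- cohort@spec@voxelSize
    for (s in cohort@subjects) {
        base <- file.path(dir, s$id)
        writeDWI(s$dwi, paste0(base, "_dwi.nii.gz"))
        writeNiftiArray(array(as.integer(s$truth$brainMask),
                              dim(s$truth$brainMask)), vs,
                        paste0(base, "_truth_brain.nii.gz"),
                        datatype = "uint8")
        writeNiftiArray(array(as.integer(s$truth$effectMask),
                              dim(s$truth$effectMask)), vs,
                        paste0(base, "_truth_effect.nii.gz"),
                        datatype = "uint8")
        writeNiftiArray(s$truth$trueFA, vs,
                        paste0(base, "_truth_fa.nii.gz"))
    }
    writeManifest(cohort@manifest, file.path(dir, "manifest.csv"))
    invisible(dir)
}
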