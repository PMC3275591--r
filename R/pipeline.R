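#' Default run configuration
#'
#' All stage parameters of a reproducible run, serialisable alongside the
#' outputs.  A run is a pure function of its configuration and seed.
#'
#' @param seed master seed.
#' @param outDir output directory.
#' @return named list of parameters.
#' @export
defaultRunConfig <- function(seed = 1, outDir = "dtivba_run") {
    list(seed = seed, outDir = outDir,
         nPerGroup = 10, nDirections = 30, bValue = 3000,
         deltaFA = 0.03, noiseSigma = 0.02, couplingTarget = 0.65,
         thresholdFraction = 0.05, closingRadius = 1, openingRadius = 1,
         wmThreshold = 0.20, wmThresholds = seq(0.05, 0.40, 0.05),
         smoothKernel = 3, smoothSigma = 1,
         vbaMetrics = "fa", vbaScores = "head_turn",
         register = "none", templates = NULL,
         alpha = 0.01, consensusFraction = 1.0)
}

writeConfig <- function(config, path) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                             null = "null")
    } else {
        dput(config, file = path)
    }
    invisible(path)
}

#' Generate and write a phantom cohort run
#'
#' Builds the phantom specification from the configuration, generates the
#' two-group cohort, and writes per-subject DWIs (NIfTI + .bval/.bvec),
#' ground-truth masks and FA maps, the manifest CSV and the resolved
#' configuration to \code{config$outDir}.
#'
#' @param config list as from [defaultRunConfig()].
#' @return Invisibly, the generated \linkS4class{CohortDataset}.
#' @export
runPhantom <- function(config = defaultRunConfig()) {
    if (config$nPerGroup < 2)
        stop("nPerGroup must be >= 2 (a one-subject group cannot be tested)")
    spec <- defaultPhantomSpec(deltaFA = config$deltaFA,
                               noiseSigma = config$noiseSigma,
                               couplingTarget = config$couplingTarget)
    scheme <- acquisitionScheme(config$nDirections, config$bValue)
    cohort <- generateCohort(spec, config$nPerGroup, scheme, config$seed)
    writeCohort(cohort, config$outDir)
    writeConfig(config, file.path(config$outDir, "config.json"))
    message("phantom cohort written to ", config$outDir, " (",
            nrow(cohort@manifest), " subjects, seed ", config$seed, ")")
    invisible(cohort)
}

#' Load a cohort written by [runPhantom()]
#'
#' @param dir cohort directory containing \code{manifest.csv} and
#'   per-subject \code{<id>_dwi.nii.gz} files.
#' @return list with \code{dwis} (named list of
#'   \linkS4class{DWIVolume}s) and \code{manifest}.
#' @export
loadCohortDir <- function(dir) {
    manifest <- readManifest(file.path(dir, "manifest.csv"))
    dwis <- lapply(manifest$id, function(id) {
        base <- file.path(dir, paste0(id, "_dwi"))
        readDWI(paste0(base, ".nii.gz"), paste0(base, ".bval"),
                paste0(base, ".bvec"))
    })
    names(dwis) <- manifest$id
    list(dwis = dwis, manifest = manifest)
}

#' Run the full analysis on a set of subjects
#'
#' Executes, per subject: iDWI, brain extraction, tensor fit, scalar maps,
#' global/WM/ROI summaries; then the cohort-level comparison and
#' behaviour-correlation tables; then the voxel-based analysis per metric
#' (registration to each template, masked Gaussian smoothing, voxel-wise
#' t-maps) with the multi-template consensus, and voxel-wise
#' behaviour-correlation maps on the reporting template (the first
#' template, which hosts all consensus output).  A subject failing the
#' tensor fit aborts the run (cohort integrity) unless
#' \code{skipFailures = TRUE}.
#'
#' @param dwis named list of \linkS4class{DWIVolume}s.
#' @param manifest data.frame with \code{id}, \code{group}, optional
#'   \code{birth_weight} and score columns.
#' @param config list as from [defaultRunConfig()].
#' @param rois optional label map (see [summarizeSubject()]).
#' @param transforms optional named list of per-subject transforms into
#'   template space (identity when absent and grids match).
#' @param skipFailures drop subjects whose fit fails instead of aborting.
#' @param verbose emit per-stage progress messages.
#' @return list with \code{summaries}, \code{comparison},
#'   \code{behavior}, \code{vba} (per metric: per-template
#'   \linkS4class{StatMap}s, \code{consensus}, \code{correlations}),
#'   \code{masks}, \code{maps}, \code{log}.
#' @export
runAnalysis <- function(dwis, manifest, config = defaultRunConfig(),
                        rois = NULL, transforms = NULL,
                        skipFailures = FALSE, verbose = TRUE) {
    say <- function(...) if (verbose) message(...)
    ids <- names(dwis)
    stopifnot(all(ids %in% manifest$id))
    masks <- list(); mapsets <- list(); summaries <- list(); log <- list()
    for (id in ids) {
        res <- try({
            idwi <- computeIDWI(dwis[[id]])
            brain <- computeBrainMask(idwi, config$thresholdFraction,
                                      config$closingRadius,
                                      config$openingRadius)
            tf <- fitTensors(dwis[[id]], brain, storeVectors = FALSE)
            maps <- scalarMaps(tf)
            bw <- manifest$birth_weight[match(id, manifest$id)]
            s <- summarizeSubject(maps, brain, config$wmThresholds, rois,
                                  id = id, birthWeight = bw)
            list(brain = brain, maps = maps, summary = s,
                 counts = c(masked = sum(brain@mask),
                            valid = sum(tf@validMask),
                            clamped = tf@nClamped))
        }, silent = TRUE)
        if (inherits(res, "try-error")) {
            if (!skipFailures)
                stop("subject '", id, "' failed: ",
                     attr(res, "condition")$message)
            say("subject ", id, " skipped: ", attr(res, "condition")$message)
            next
        }
        masks[[id]] <- res$brain
        mapsets[[id]] <- res$maps
        summaries[[id]] <- res$summary
        log[[id]] <- res$counts
        say(sprintf("subject %s: %d brain voxels, %d valid fits, %d clamped",
                    id, res$counts[1], res$counts[2], res$counts[3]))
    }
    ids <- names(mapsets)
    comparison <- compareCohort(summaries, manifest, config$wmThreshold)
    behavior <- behaviorCorrelationTable(summaries, manifest,
                                         wmThreshold = config$wmThreshold)
    templates <- config$templates
    if (is.null(templates)) templates <- ids
    vba <- list()
    vs <- mapsets[[1]]@voxelSize
    faMaps <- lapply(mapsets, slot, "fa")
    for (metric in config$vbaMetrics) {
        raw <- lapply(mapsets, slot, metric)
        perTemplate <- list()
        stacks <- list()
        for (tpl in templates) {
            stack <- buildStack(raw, masks, tpl, transforms,
                                register = config$register,
                                registerOn = faMaps, voxelSize = vs)
            stack@maps <- lapply(stack@maps, smoothMap, mask = stack@mask,
                                 kernel = config$smoothKernel,
                                 sigma = config$smoothSigma)
            stacks[[tpl]] <- stack
            perTemplate[[tpl]] <- voxelwiseGroupTest(stack, manifest)
            say("VBA ", metric, ": template ", tpl, " done")
        }
        consensus <- if (length(perTemplate) >= 2)
            multiTemplateConsensus(perTemplate, config$alpha,
                                   config$consensusFraction)
        else NULL
        correlations <- list()
        for (sc in intersect(config$vbaScores, names(manifest))) {
            cm <- tryCatch(voxelwiseCorrelation(stacks[[1]], sc, manifest),
                           error = function(e) {
                               say("correlation map for '", sc,
                                   "' skipped: ", conditionMessage(e))
                               NULL
                           })
            if (!is.null(cm)) correlations[[sc]] <- cm
        }
        vba[[metric]] <- list(perTemplate = perTemplate,
                              consensus = consensus,
                              correlations = correlations)
    }
    list(summaries = summaries, comparison = comparison,
         behavior = behavior, vba = vba, masks = masks, maps = mapsets,
         log = log)
}

#' Write an analysis report bundle to disk
#'
#' Emits the comparison and behaviour tables as CSV, the consensus and
#' per-template significance volumes plus correlation maps as NIfTI, and a
#' JSON run summary with significant-voxel counts.
#'
#' @param report output of [runAnalysis()].
#' @param dir output directory.
#' @param config the configuration used (stored alongside).
#' @return Invisibly, the directory.
#' @export
writeReport <- function(report, dir, config = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$comparison, file.path(dir, "table_global.csv"),
              row.names = FALSE)
    write.csv(report$behavior, file.path(dir, "table_correlations.csv"),
              row.names = FALSE)
    counts <- list()
    for (metric in names(report$vba)) {
        v <- report$vba[[metric]]
        vs <- v$perTemplate[[1]]@voxelSize
        for (tpl in names(v$perTemplate)) {
            sm <- v$perTemplate[[tpl]]
            base <- file.path(dir, paste0("vba_", metric, "_", tpl))
            writeNiftiArray(sm@statistic, vs, paste0(base, "_t.nii.gz"))
            writeNiftiArray(sm@p, vs, paste0(base, "_p.nii.gz"))
            writeNiftiArray(array(as.integer(sm@sig01), dim(sm@sig01)), vs,
                            paste0(base, "_sig01.nii.gz"), "uint8")
        }
        if (!is.null(v$consensus)) {
            writeNiftiArray(array(as.integer(v$consensus$consensus),
                                  dim(v$consensus$consensus)), vs,
                            file.path(dir, paste0("vba_", metric,
                                                  "_consensus.nii.gz")),
                            "uint8")
            writeNiftiArray(v$consensus$support, vs,
                            file.path(dir, paste0("vba_", metric,
                                                  "_support.nii.gz")))
            counts[[paste0(metric, "_consensus_voxels")]] <-
                sum(v$consensus$consensus)
        }
        for (sc in names(v$correlations)) {
            cm <- v$correlations[[sc]]
            base <- file.path(dir, paste0("vba_", metric, "_rho_", sc))
            writeNiftiArray(cm@statistic, vs, paste0(base, ".nii.gz"))
            counts[[paste0(metric, "_", sc, "_sig01_voxels")]] <-
                sum(cm@sig01)
        }
        counts[[paste0(metric, "_sig01_voxels_template1")]] <-
            sum(v$perTemplate[[1]]@sig01)
    }
    if (!is.null(config)) writeConfig(config, file.path(dir, "config.json"))
    writeConfig(counts, file.path(dir, "summary.json"))
    invisible(dir)
}
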