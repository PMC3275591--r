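#' Per-subject global, white-matter and ROI summaries
#'
#' Computes, for one subject: the whole-brain mean of each scalar metric
#' (over brain-and-valid voxels), the mean inside FA-thresholded
#' white-matter masks for a sweep of thresholds, per-ROI means when a label
#' map is given, the brain volume (mask voxel count times voxel volume) and
#' the brain-volume / birth-weight ratio (mm^3/g).
#'
#' @param maps a \linkS4class{ScalarMapSet}.
#' @param brain a \linkS4class{BrainMask}.
#' @param wmThresholds FA thresholds for the white-matter sweep
#'   (default 0.05 to 0.40 in steps of 0.05).
#' @param rois optional integer 3D label map on the same grid (0 =
#'   unlabeled), or a list \code{list(labels=, affine=)} with an affine to
#'   pull the labels onto the DWI grid by nearest-neighbour.
#' @param id subject identifier.
#' @param birthWeight grams; NA gives an NA ratio.
#' @return A \code{SubjectSummary} list: \code{id},
#'   \code{brainVolume}, \code{volumeWeightRatio}, \code{wholeBrain}
#'   (named numeric over metrics), \code{wm} (thresholds x metrics matrix),
#'   \code{roi} (labels x metrics matrix or NULL).
#' @export
summarizeSubject <- function(maps, brain, wmThresholds = seq(0.05, 0.40, 0.05),
                             rois = NULL, id = "subject", birthWeight = NA) {
    checkSameGrid(maps@fa, brain@mask)
    metrics <- c("fa", "adc", "axial", "radial", "linearity", "planarity",
                 "sphericity")
    base <- brain@mask & maps@validMask
    vals <- vapply(metrics, function(m) slot(maps, m)[base],
                   numeric(sum(base)))
    fa <- maps@fa[base]
    wholeBrain <- colMeans(vals)
    wm <- t(vapply(wmThresholds, function(th) {
        sel <- fa > th
        if (!any(sel)) return(setNames(rep(NA_real_, length(metrics)), metrics))
        colMeans(vals[sel, , drop = FALSE])
    }, setNames(numeric(length(metrics)), metrics)))
    rownames(wm) <- format(wmThresholds)
    roi <- NULL
    if (!is.null(rois)) {
        labels <- rois
        if (is.list(rois) && !is.null(rois$affine)) {
            labels <- applyTransform(rois$labels, rois$affine, dim(maps@fa),
                                     "nearest", fill = 0)
        } else if (is.list(rois)) labels <- rois$labels
        checkSameGrid(labels, maps@fa)
        labs <- sort(setdiff(unique(as.integer(labels[labels > 0])), 0L))
        roi <- t(vapply(labs, function(l) {
            sel <- base & (labels == l)
            if (!any(sel)) return(setNames(rep(NA_real_, length(metrics)), metrics))
            vapply(metrics, function(m) mean(slot(maps, m)[sel]), 0)
        }, setNames(numeric(length(metrics)), metrics)))
        rownames(roi) <- paste0("roi", labs)
    }
    vol <- brainVolume(brain)
    structure(list(id = id, brainVolume = vol,
                   volumeWeightRatio = vol / birthWeight,
                   wholeBrain = wholeBrain, wm = wm, roi = roi,
                   wmThresholds = wmThresholds),
              class = "SubjectSummary")
}

## Pull one scalar out of a summary: mask is "wholebrain", "wm" (at
## threshold th) or "roiX".
summaryValue <- function(s, mask, metric, th = 0.20) {
    if (mask == "wholebrain") return(s$wholeBrain[[metric]])
    if (mask == "wm") {
        i <- which(abs(s$wmThresholds - th) < 1e-9)
        if (!length(i)) stop("threshold ", th, " not in the sweep")
        return(s$wm[i, metric])
    }
    if (!is.null(s$roi) && mask %in% rownames(s$roi))
        return(s$roi[mask, metric])
    NA_real_
}

#' Group comparison table of global measures
#'
#' The global-analysis table: one row per measure (brain volume,
#' volume/birth-weight ratio, then each scalar metric in the whole brain
#' and inside the FA > \code{wmThreshold} white-matter mask, and per-ROI
#' metrics when present), comparing control vs IUGR with the
#' normality-gated two-sample test.  Group summaries follow the usual
#' convention: mean (sd) when the t branch was taken, median (IQR)
#' otherwise.
#'
#' @param summaries list of \code{SubjectSummary} objects.
#' @param manifest data.frame with \code{id}, \code{group}.
#' @param wmThreshold FA threshold of the reported WM rows (default 0.20).
#' @param alphaNormality normality-gate level passed to
#'   [twoSampleCompare()].
#' @return data.frame with columns \code{measure}, \code{control},
#'   \code{iugr}, \code{statistic}, \code{p}, \code{method}, \code{n1},
#'   \code{n2}.
#' @export
compareCohort <- function(summaries, manifest, wmThreshold = 0.20,
                          alphaNormality = 0.05) {
    ids <- vapply(summaries, `[[`, "", "id")
    grp <- manifest$group[match(ids, manifest$id)]
    if (!all(c("control", "IUGR") %in% grp))
        stop("both groups must be present")
    metrics <- c("fa", "adc", "axial", "radial", "linearity", "planarity",
                 "sphericity")
    measures <- list(
        brain_volume = function(s) s$brainVolume,
        volume_weight_ratio = function(s) s$volumeWeightRatio)
    for (m in metrics) {
        local({
            mm <- m
            measures[[paste0("wholebrain_", mm)]] <<-
                function(s) summaryValue(s, "wholebrain", mm)
            measures[[paste0("wm_", mm)]] <<-
                function(s) summaryValue(s, "wm", mm, wmThreshold)
        })
    }
    roiNames <- unique(unlist(lapply(summaries, function(s) rownames(s$roi))))
    for (rn in roiNames) for (m in metrics) {
        local({
            rr <- rn; mm <- m
            measures[[paste0(rr, "_", mm)]] <<-
                function(s) summaryValue(s, rr, mm)
        })
    }
    rows <- lapply(names(measures), function(nm) {
        v <- vapply(summaries, measures[[nm]], 0)
        x <- v[grp == "control"]; y <- v[grp == "IUGR"]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 3 || length(y) < 3)
            return(data.frame(measure = nm, control = NA, iugr = NA,
                              statistic = NA, p = NA, method = "insufficient",
                              n1 = length(x), n2 = length(y)))
        ts <- twoSampleCompare(x, y, alphaNormality)
        normal <- ts$branch == "t"
        data.frame(measure = nm,
                   control = groupDescriptive(x, normal),
                   iugr = groupDescriptive(y, normal),
                   statistic = unname(ts$statistic), p = ts$p.value,
                   method = ts$branch, n1 = length(x), n2 = length(y))
    })
    do.call(rbind, rows)
}

#' Diffusion-behaviour correlation table
#'
#' Spearman correlations between each behavioural score and each diffusion
#' summary (FA, ADC, axial and radial diffusivity by default; whole brain
#' and FA > \code{wmThreshold} masks), with pairwise deletion of missing
#' scores.  Scores constant across the available subjects yield a flagged
#' undefined row (NA rho/p) rather than an error.
#'
#' @param summaries list of \code{SubjectSummary} objects.
#' @param manifest data.frame with \code{id} and score columns.
#' @param metrics which metrics to correlate.
#' @param scoreNames which scores; defaults to every registry score found
#'   in the manifest.
#' @param wmThreshold FA threshold for the WM-mask columns.
#' @return data.frame with columns \code{score}, \code{metric},
#'   \code{mask}, \code{rho}, \code{p}, \code{n}, \code{degenerate}.
#' @export
behaviorCorrelationTable <- function(summaries, manifest,
                                     metrics = c("fa", "adc", "axial", "radial"),
                                     scoreNames = NULL,
                                     wmThreshold = 0.20) {
    ids <- vapply(summaries, `[[`, "", "id")
    if (is.null(scoreNames))
        scoreNames <- intersect(scoreRegistry()$name, names(manifest))
    rows <- list()
    for (sc in scoreNames) {
        v <- manifest[[sc]][match(ids, manifest$id)]
        for (msk in c("wholebrain", "wm")) for (m in metrics) {
            x <- vapply(summaries, summaryValue, 0, msk, m, wmThreshold)
            ok <- !is.na(x) & !is.na(v)
            if (sum(ok) < 4) {
                rows[[length(rows) + 1]] <- data.frame(
                    score = sc, metric = m, mask = msk, rho = NA, p = NA,
                    n = sum(ok), degenerate = NA)
                next
            }
            res <- spearmanCorr(x[ok], v[ok])
            rows[[length(rows) + 1]] <- data.frame(
                score = sc, metric = m, mask = msk,
                rho = unname(res$estimate), p = res$p.value, n = res$n,
                degenerate = res$degenerate)
        }
    }
    do.call(rbind, rows)
}
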