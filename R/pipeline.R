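#' @include simulate.R
NULL

#' Pipeline configuration
#'
#' Flat configuration of the whole two-stage run; every key corresponds
#' to a module parameter. The default pipeline is fully deterministic;
#' `seed` only matters for the `random` reference policy.
#'
#' @param merge a [mergeConfig()] list.
#' @param referencePolicy `"most_peaks"` or `"random"`.
#' @param wCandidates candidate mixture weights.
#' @param grubbsAlpha Grubbs significance level.
#' @param enforceMs0 gate partial matches on `mS >= mS0` too.
#' @param rtCorrection landmark-anchored RT correction before partial
#'   alignment (default FALSE).
#' @param seed integer RNG seed.
#' @return list with class `"RunConfig"`.
#' @export
runConfig <- function(merge = mergeConfig(),
                      referencePolicy = c("most_peaks", "random"),
                      wCandidates = gcxgcAlign::wCandidates(),
                      grubbsAlpha = 0.05, enforceMs0 = FALSE,
                      rtCorrection = FALSE, seed = 1L) {
    referencePolicy <- match.arg(referencePolicy)
    stopifnot(inherits(merge, "MergeConfig"),
              all(wCandidates >= 0 & wCandidates <= 1),
              grubbsAlpha > 0, grubbsAlpha < 1,
              is.logical(enforceMs0), is.logical(rtCorrection))
    structure(list(merge = merge, referencePolicy = referencePolicy,
                   wCandidates = wCandidates, grubbsAlpha = grubbsAlpha,
                   enforceMs0 = enforceMs0, rtCorrection = rtCorrection,
                   seed = as.integer(seed)),
              class = c("RunConfig", "list"))
}

#' Run the full two-stage alignment pipeline
#'
#' Executes, in order: within-sample split-entry merging, z-score
#' transformation of both retention-time dimensions, global `dmax`,
#' reference selection, landmark discovery, mixture-weight optimisation,
#' Grubbs-based threshold derivation, optional landmark-anchored RT
#' correction, and partial alignment of the remaining peaks. The report
#' records the selected reference, landmark count, optimised weight,
#' `dmax`, derived thresholds and per-stage peak counts.
#'
#' @param samples list of [PeakList-class] objects, or a directory of
#'   peak-list files in the input dialect (all `*.csv`/`*.tsv` except
#'   `truth.csv`).
#' @param config a [runConfig()] list.
#' @param outputDir optional directory; when given,
#'   `alignment_table.csv` and `report.json` are written there.
#' @return list with `table` ([AlignmentTable-class]), `thresholds`
#'   ([Thresholds-class]), `landmarks`, `wsearch` and `report` (a plain
#'   list).
#' @export
runPipeline <- function(samples, config = runConfig(), outputDir = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.character(samples)) {
        paths <- list.files(samples, pattern = "\\.(csv|tsv)$",
                            full.names = TRUE)
        paths <- paths[basename(paths) != "truth.csv"]
        if (length(paths) < 2L)
            stop("[io] need at least 2 peak-list files in '", samples, "'")
        samples <- lapply(paths, readPeakList)
    }
    if (length(samples) < 2L)
        stop("[io] need at least 2 samples")
    ids <- vapply(samples, sampleId, "")
    rawCounts <- stats::setNames(vapply(samples, nPeaks, 1L), ids)

    merged <- lapply(samples, mergeEntries, cfg = config$merge)
    mergedCounts <- stats::setNames(vapply(merged, nPeaks, 1L), ids)
    zs <- lapply(merged, zscoreTransform)
    dmax <- computeDmax(zs)

    set.seed(config$seed)
    refId <- selectReference(zs, policy = config$referencePolicy)
    landmarks <- findLandmarks(zs, refId)
    if (!length(landmarks@groupNames))
        stop("[full_alignment] no landmark peaks shared by all samples; ",
             "cannot derive thresholds")
    ws <- optimizeW(landmarks, zs, dmax, candidates = config$wCandidates)
    th <- deriveThresholds(landmarks, zs, w = ws@wOpt, dmax = dmax,
                           cfg = grubbsConfig(alpha = config$grubbsAlpha))
    tab <- alignAll(zs, landmarks, th, enforceMs0 = config$enforceMs0,
                    rtCorrection = config$rtCorrection)
    report <- list(
        n_samples = length(ids),
        reference = refId,
        peak_counts_raw = as.list(rawCounts),
        peak_counts_merged = as.list(mergedCounts),
        n_landmarks = length(landmarks@groupNames),
        w_opt = ws@wOpt,
        d_max = dmax,
        d0 = th@d0, sim0 = th@sim0, ms0 = th@ms0,
        n_groups = nrow(tab@groups),
        n_full_rows = length(fullRows(tab)),
        rt_correction = config$rtCorrection,
        enforce_ms0 = config$enforceMs0)
    if (!is.null(outputDir)) {
        if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
        writeAlignmentTable(tab, file.path(outputDir, "alignment_table.csv"))
        jsonlite::write_json(report,
                             file.path(outputDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(table = tab, thresholds = th, landmarks = landmarks,
         wsearch = ws, report = report)
}
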