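#' @import methods
NULL

#' Fragment-ion mass spectrum
#'
#' Sparse unit-resolution fragment spectrum of one chromatographic peak:
#' parallel vectors of m/z channels (strictly increasing) and non-negative
#' intensities. TOF fragment spectra are stored at unit m/z resolution so
#' that Pearson correlation between two spectra is defined on a shared
#' integer grid.
#'
#' @slot mz numeric, strictly increasing m/z values.
#' @slot intensity numeric, non-negative intensities; at least one positive.
#'
#' @seealso [parseSpectrum()], [spectrumSimilarity()]
#' @export
setClass("MassSpectrum",
    representation(mz = "numeric", intensity = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@mz) == 0L)
            msg <- c(msg, "spectrum must contain at least one ion")
        if (length(object@mz) != length(object@intensity))
            msg <- c(msg, "mz and intensity lengths differ")
        if (any(!is.finite(object@mz)) || any(!is.finite(object@intensity)))
            msg <- c(msg, "non-finite m/z or intensity")
        else {
            if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
                msg <- c(msg, "m/z values must be strictly increasing")
            if (any(object@intensity < 0))
                msg <- c(msg, "negative intensity")
            if (length(object@intensity) && all(object@intensity <= 0))
                msg <- c(msg, "all intensities are zero")
        }
        if (length(msg)) msg else TRUE
    })

#' One sample's peak list
#'
#' All peaks detected in a single GCxGC/TOF-MS run, as exported by
#' deconvolution software: per peak a compound name (possibly empty =
#' unassigned), first- and second-dimension retention times in seconds,
#' area, and a fragment spectrum. Peaks are kept sorted by (rt1, rt2).
#'
#' The `peaks` slot is a data.frame with columns `name`, `rt1`, `rt2`,
#' `area` and, once [zscoreTransform()] has run, z-scored coordinates
#' `z1`, `z2` (NA beforehand). `spectra` and `sourceIds` are parallel
#' lists: `sourceIds[[i]]` records the original input-row indices behind
#' peak i and grows when split entries are merged.
#'
#' @slot sampleId character(1) sample identifier.
#' @slot peaks data.frame, one row per peak (see Details).
#' @slot spectra list of [MassSpectrum-class] objects, one per peak.
#' @slot sourceIds list of integer vectors, one per peak.
#' @slot zstats named numeric of length 0 (untransformed) or 4:
#'   `rt1_mean`, `rt1_sd`, `rt2_mean`, `rt2_sd`.
#'
#' @export
setClass("PeakList",
    representation(sampleId = "character", peaks = "data.frame",
                   spectra = "list", sourceIds = "list",
                   zstats = "numeric"),
    validity = function(object) {
        msg <- character()
        p <- object@peaks
        if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
            !nzchar(object@sampleId))
            msg <- c(msg, "sampleId must be one non-empty string")
        need <- c("name", "rt1", "rt2", "area", "z1", "z2")
        if (!all(need %in% names(p)))
            return(paste("peaks lacks columns:",
                         paste(setdiff(need, names(p)), collapse = ", ")))
        if (nrow(p) != length(object@spectra) ||
            nrow(p) != length(object@sourceIds))
            msg <- c(msg, "spectra/sourceIds not parallel to peaks")
        if (nrow(p)) {
            if (any(p$rt1 <= 0) || any(p$rt2 <= 0))
                msg <- c(msg, "retention times must be positive")
            if (any(p$area <= 0))
                msg <- c(msg, "areas must be positive")
            if (nrow(p) > 1L) {
                d1 <- diff(p$rt1); d2 <- diff(p$rt2)
                if (any(d1 < 0 | (d1 == 0 & d2 < 0)))
                    msg <- c(msg, "peaks must be sorted by (rt1, rt2)")
            }
            if (any(vapply(object@sourceIds, length, 1L) == 0L))
                msg <- c(msg, "every peak needs at least one source id")
        }
        if (length(object@zstats) &&
            !identical(names(object@zstats),
                       c("rt1_mean", "rt1_sd", "rt2_mean", "rt2_sd")))
            msg <- c(msg, "zstats must be named rt1_mean/rt1_sd/rt2_mean/rt2_sd")
        if (length(object@zstats) == 4L &&
            (object@zstats[["rt1_sd"]] <= 0 || object@zstats[["rt2_sd"]] <= 0))
            msg <- c(msg, "zstats standard deviations must be positive")
        if (length(msg)) msg else TRUE
    })

#' Landmark peaks shared by every sample
#'
#' The full-alignment result: compound peaks found, under the same assigned
#' name, in every sample. Row g of `members` gives the peak index of
#' landmark group g within each sample's [PeakList-class] (columns are
#' named by sample id, the reference included).
#'
#' @slot referenceId character(1), id of the reference sample.
#' @slot members integer matrix, groups x samples, colnames = sample ids.
#' @slot groupNames character, the shared compound name of each group.
#'
#' @export
setClass("LandmarkSet",
    representation(referenceId = "character", members = "matrix",
                   groupNames = "character"),
    validity = function(object) {
        msg <- character()
        m <- object@members
        if (is.null(colnames(m)))
            msg <- c(msg, "members must have sample ids as colnames")
        else if (!object@referenceId %in% colnames(m))
            msg <- c(msg, "referenceId absent from members colnames")
        if (nrow(m) != length(object@groupNames))
            msg <- c(msg, "groupNames not parallel to members rows")
        if (nrow(m) && any(is.na(m)))
            msg <- c(msg, "landmark groups must cover every sample")
        for (j in seq_len(ncol(m)))
            if (anyDuplicated(m[, j]))
                msg <- c(msg, "a peak appears in two landmark groups")
        if (length(msg)) msg else TRUE
    })

#' Data-derived alignment thresholds
#'
#' Matching thresholds derived from the landmark pairs after Grubbs outlier
#' rejection, together with the mixture-similarity parameters: `d0` is the
#' maximum allowed peak distance in z-score retention-time space, `sim0`
#' the minimum spectrum Pearson correlation, `ms0` the minimum mixture
#' similarity (reported; only enforced on request), `w` the optimised
#' mixture weight and `dmax` the global maximum pairwise peak distance.
#'
#' @export
setClass("Thresholds",
    representation(d0 = "numeric", sim0 = "numeric", ms0 = "numeric",
                   w = "numeric", dmax = "numeric"),
    validity = function(object) {
        msg <- character()
        one <- function(x) length(x) == 1L && is.finite(x)
        if (!all(vapply(list(object@d0, object@sim0, object@ms0,
                             object@w, object@dmax), one, TRUE)))
            return("all slots must be finite scalars")
        if (object@dmax <= 0) msg <- c(msg, "dmax must be positive")
        if (object@d0 <= 0) msg <- c(msg, "d0 must be positive")
        if (object@d0 > object@dmax + 1e-9)
            msg <- c(msg, "d0 cannot exceed dmax")
        if (object@sim0 < -1 || object@sim0 > 1)
            msg <- c(msg, "sim0 must lie in [-1, 1]")
        if (object@w < 0 || object@w > 1)
            msg <- c(msg, "w must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' Mixture-weight grid-search result
#'
#' @slot wOpt numeric(1), the selected mixture weight.
#' @slot scores named numeric, summed mixture similarity per candidate.
#' @slot perPair data.frame of per-(reference, target) summed scores per
#'   candidate, for diagnostics.
#' @export
setClass("WSearchResult",
    representation(wOpt = "numeric", scores = "numeric",
                   perPair = "data.frame"),
    validity = function(object) {
        if (!length(object@scores) || is.null(names(object@scores)))
            return("scores must be a named vector")
        sc <- object@scores[as.character(object@wOpt)]
        if (is.na(sc) || sc < max(object@scores) - 1e-9)
            return("wOpt must be a maximiser of scores")
        TRUE
    })

#' Cross-sample alignment table
#'
#' Rows are aligned compound groups, columns samples. `groups` holds one
#' row per aligned group (`group_id`, `kind` = landmark/partial,
#' `consensus_name`); `members` is a long data.frame with one row per
#' (group, sample) cell: `group_id`, `sample_id`, `peak_idx` (index into
#' that sample's PeakList), `name`, `rt1`, `rt2`, `area`.
#' `memberSources` is a list parallel to `members` rows carrying the
#' original input-row indices of each member peak.
#'
#' @export
setClass("AlignmentTable",
    representation(samples = "character", groups = "data.frame",
                   members = "data.frame", memberSources = "list"),
    validity = function(object) {
        msg <- character()
        g <- object@groups; m <- object@members
        if (anyDuplicated(object@samples))
            msg <- c(msg, "duplicate sample ids")
        if (!all(c("group_id", "kind", "consensus_name") %in% names(g)))
            msg <- c(msg, "groups needs group_id/kind/consensus_name")
        if (!all(c("group_id", "sample_id", "peak_idx", "name",
                   "rt1", "rt2", "area") %in% names(m)))
            return(c(msg, "members lacks required columns"))
        if (nrow(m) != length(object@memberSources))
            msg <- c(msg, "memberSources not parallel to members")
        if (nrow(m)) {
            if (!all(m$sample_id %in% object@samples))
                msg <- c(msg, "member sample id not in samples")
            if (anyDuplicated(m[, c("group_id", "sample_id")]))
                msg <- c(msg, "a group holds two peaks of one sample")
            if (anyDuplicated(m[, c("sample_id", "peak_idx")]))
                msg <- c(msg, "a peak appears in two groups")
            if (length(g$kind) && any(g$kind == "landmark")) {
                full <- table(factor(m$group_id, levels = g$group_id))
                bad <- g$kind == "landmark" &
                    as.integer(full) != length(object@samples)
                if (any(bad))
                    msg <- c(msg, "landmark rows must cover every sample")
            }
        }
        if (nrow(g) && !all(g$kind %in% c("landmark", "partial")))
            msg <- c(msg, "kind must be landmark or partial")
        if (length(msg)) msg else TRUE
    })

#' Alignment evaluation against ground truth
#'
#' Counts and metrics of a scored alignment: `np` positive peak pairs
#' (compounds present in all samples), `nm` matched peak pairs (full rows
#' reported by the aligner), TP/FP/FN and TPR (recall), PPV (precision)
#' and F1 (their harmonic mean). Rows not covering all samples are counted
#' separately in `partialRows`.
#'
#' @export
setClass("EvaluationResult",
    representation(np = "integer", nm = "integer", tp = "integer",
                   fp = "integer", fn = "integer", tpr = "numeric",
                   ppv = "numeric", f1 = "numeric", partialRows = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@tp + object@fn != object@np)
            msg <- c(msg, "tp + fn must equal np")
        if (object@tp + object@fp != object@nm)
            msg <- c(msg, "tp + fp must equal nm")
        rng <- c(object@tpr, object@ppv, object@f1)
        if (any(rng < 0 | rng > 1))
            msg <- c(msg, "metrics must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

## ---- parameter constructors (plain validated lists) ----

#' Peak-merging parameters
#'
#' The only user-facing matching thresholds of the whole method: the
#' retention-time windows and minimum spectrum correlation that decide when
#' two entries of one sample are split reports of the same compound.
#'
#' @param rt1Window first-dimension window in seconds (default 5).
#' @param rt2Window second-dimension window in seconds (default 0.1).
#' @param r0 minimum spectrum Pearson correlation in (0, 1] (default 0.95).
#' @return list with class `"MergeConfig"`.
#' @export
mergeConfig <- function(rt1Window = 5, rt2Window = 0.1, r0 = 0.95) {
    stopifnot(rt1Window > 0, rt2Window > 0, r0 > 0, r0 <= 1)
    structure(list(rt1Window = rt1Window, rt2Window = rt2Window, r0 = r0),
              class = c("MergeConfig", "list"))
}

#' Grubbs outlier-test parameters
#'
#' @param alpha significance level in (0, 1), default 0.05.
#' @param maxIterations cap on iterative removals (default unlimited in
#'   practice: 1000).
#' @return list with class `"GrubbsConfig"`.
#' @export
grubbsConfig <- function(alpha = 0.05, maxIterations = 1000L) {
    stopifnot(alpha > 0, alpha < 1, maxIterations >= 1)
    structure(list(alpha = alpha, maxIterations = as.integer(maxIterations)),
              class = c("GrubbsConfig", "list"))
}
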