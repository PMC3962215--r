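#' @include AllGenerics.R
NULL

## ---- MassSpectrum ----

#' Construct a mass spectrum
#'
#' @param mz numeric m/z values (need not be sorted; duplicates summed).
#' @param intensity numeric non-negative intensities, parallel to `mz`.
#' @param roundMz round m/z to the nearest integer channel (default TRUE,
#'   unit-resolution TOF data).
#' @return a [MassSpectrum-class]
#' @export
MassSpectrum <- function(mz, intensity, roundMz = TRUE) {
    if (roundMz) mz <- round(mz)
    if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, mz, sum))
        mz <- sort(unique(mz))
    } else {
        o <- order(mz)
        mz <- mz[o]; intensity <- intensity[o]
    }
    new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' @describeIn MassSpectrum m/z channels
#' @param object,x a MassSpectrum
#' @export
mz <- function(x) x@mz

#' @describeIn MassSpectrum intensities
#' @export
intensity <- function(x) x@intensity

setMethod("show", "MassSpectrum", function(object) {
    cat("MassSpectrum with", length(object@mz), "ions, m/z",
        min(object@mz), "-", max(object@mz),
        sprintf("(base peak %g @ m/z %g)\n",
                max(object@intensity), object@mz[which.max(object@intensity)]))
})

## ---- PeakList ----

#' Construct a peak list
#'
#' @param sampleId sample identifier.
#' @param peaks data.frame with columns `name`, `rt1`, `rt2`, `area`
#'   (seconds, seconds, positive area); `z1`/`z2` added if absent.
#' @param spectra list of [MassSpectrum-class], parallel to `peaks` rows.
#' @param sourceIds optional list of integer vectors (default: row numbers).
#' @param zstats optional named numeric(4) z-score statistics.
#' @return a [PeakList-class], peaks sorted by (rt1, rt2).
#' @export
PeakList <- function(sampleId, peaks, spectra, sourceIds = NULL,
                     zstats = numeric()) {
    peaks$name <- as.character(peaks$name)
    if (is.null(peaks$z1)) peaks$z1 <- NA_real_
    if (is.null(peaks$z2)) peaks$z2 <- NA_real_
    if (is.null(sourceIds)) sourceIds <- as.list(seq_len(nrow(peaks)))
    o <- order(peaks$rt1, peaks$rt2)
    pk <- peaks[o, c("name", "rt1", "rt2", "area", "z1", "z2"), drop = FALSE]
    rownames(pk) <- NULL
    new("PeakList", sampleId = as.character(sampleId), peaks = pk,
        spectra = spectra[o], sourceIds = lapply(sourceIds[o], as.integer),
        zstats = zstats)
}

#' @export
setMethod("sampleId", "PeakList", function(x) x@sampleId)
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)
#' @export
setMethod("spectra", "PeakList", function(x) x@spectra)
#' @export
setMethod("sourceIds", "PeakList", function(x) x@sourceIds)
#' @export
setMethod("nPeaks", "PeakList", function(x) nrow(x@peaks))
#' @export
setMethod("zStats", "PeakList", function(x) x@zstats)

setMethod("show", "PeakList", function(object) {
    cat("PeakList '", object@sampleId, "': ", nrow(object@peaks),
        " peaks", sep = "")
    if (nrow(object@peaks))
        cat(sprintf(", rt1 %.1f-%.1f s, rt2 %.2f-%.2f s",
                    min(object@peaks$rt1), max(object@peaks$rt1),
                    min(object@peaks$rt2), max(object@peaks$rt2)))
    cat(if (length(object@zstats)) " [z-transformed]\n" else "\n")
})

## ---- LandmarkSet ----

#' @export
setMethod("referenceId", "LandmarkSet", function(x) x@referenceId)
#' @export
setMethod("members", "LandmarkSet", function(x) x@members)
#' @export
setMethod("groupNames", "LandmarkSet", function(x) x@groupNames)
#' @export
setMethod("sampleIds", "LandmarkSet", function(x) colnames(x@members))
setMethod("length", "LandmarkSet", function(x) nrow(x@members))

setMethod("show", "LandmarkSet", function(object) {
    cat("LandmarkSet:", nrow(object@members), "landmark groups across",
        ncol(object@members), "samples (reference:",
        paste0("'", object@referenceId, "')\n"))
})

## ---- Thresholds ----

#' Construct a Thresholds object
#' @param d0,sim0,ms0,w,dmax see [Thresholds-class].
#' @export
Thresholds <- function(d0, sim0, ms0, w, dmax) {
    new("Thresholds", d0 = d0, sim0 = sim0, ms0 = ms0, w = w, dmax = dmax)
}

setMethod("show", "Thresholds", function(object) {
    cat(sprintf(paste0("Thresholds: d0 = %.4g, sim0 = %.4g, mS0 = %.4g ",
                       "(w = %.2f, dmax = %.4g)\n"),
                object@d0, object@sim0, object@ms0, object@w, object@dmax))
})

setMethod("show", "WSearchResult", function(object) {
    cat("WSearchResult: w_opt =", object@wOpt, "over",
        length(object@scores), "candidates\n")
})

## ---- AlignmentTable ----

#' @export
setMethod("sampleIds", "AlignmentTable", function(x) x@samples)
#' @export
setMethod("groups", "AlignmentTable", function(x) x@groups)
#' @export
setMethod("members", "AlignmentTable", function(x) x@members)
setMethod("length", "AlignmentTable", function(x) nrow(x@groups))

#' Full rows of an alignment table
#'
#' Group ids of rows holding one peak from every sample ("matched peak
#' pairs" in the evaluation sense).
#' @param x an [AlignmentTable-class]
#' @export
fullRows <- function(x) {
    stopifnot(is(x, "AlignmentTable"))
    if (!nrow(x@members)) return(integer())
    cnt <- table(factor(x@members$group_id, levels = x@groups$group_id))
    x@groups$group_id[as.integer(cnt) == length(x@samples)]
}

setMethod("show", "AlignmentTable", function(object) {
    nk <- table(factor(object@groups$kind, levels = c("landmark", "partial")))
    cat("AlignmentTable:", nrow(object@groups), "groups (",
        nk[["landmark"]], "landmark,", nk[["partial"]], "partial ) x",
        length(object@samples), "samples;",
        length(fullRows(object)), "rows cover all samples\n")
})

setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf(paste0("EvaluationResult: Np = %d, Nm = %d | TP = %d, ",
                       "FP = %d, FN = %d\n  TPR = %.4f, PPV = %.4f, ",
                       "F1 = %.4f (%d partial rows not scored)\n"),
                object@np, object@nm, object@tp, object@fp, object@fn,
                object@tpr, object@ppv, object@f1, object@partialRows))
})
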