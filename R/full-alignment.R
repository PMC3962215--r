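#' @include preprocess.R
NULL

#' Choose the reference sample
#'
#' @param samples list of [PeakList-class] (>= 2).
#' @param policy `"most_peaks"` (default): the sample with the most peaks,
#'   ties broken by lexicographic sample id; `"random"`: uniform draw from
#'   the session RNG (seed it for reproducibility).
#' @return character(1) sample id.
#' @export
selectReference <- function(samples, policy = c("most_peaks", "random")) {
    policy <- match.arg(policy)
    if (length(samples) < 2L)
        stop("need at least 2 samples to align")
    ids <- vapply(samples, sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample ids")
    if (policy == "random") return(sample(ids, 1L))
    cnt <- vapply(samples, nPeaks, 1L)
    best <- which(cnt == max(cnt))
    ids[best][order(ids[best])][1L]
}

## deterministic target order: descending peak count, then sample id
.targetOrder <- function(samples, referenceId) {
    ids <- vapply(samples, sampleId, "")
    cnt <- vapply(samples, nPeaks, 1L)
    keep <- ids != referenceId
    ids[keep][order(-cnt[keep], ids[keep])]
}

#' Find landmark peaks present in every sample
#'
#' Progressive name-guided matching: for each reference peak carrying a
#' compound name, the target peaks assigned the same name are the
#' candidates and the one at minimum retention-time distance in z-score
#' space is paired (each target peak at most once; reference peaks are
#' visited in (rt1, rt2) order). After each target the reference shrinks
#' to the peaks that found a partner, so the surviving groups are present
#' in all samples. Targets are visited in descending peak count, then
#' sample id. Unnamed peaks never become landmarks.
#'
#' @param samples list of merged, z-transformed [PeakList-class] objects.
#' @param referenceId the reference sample id (see [selectReference()]).
#' @return a [LandmarkSet-class]; empty (with a warning) if no compound
#'   name is shared by all samples.
#' @export
findLandmarks <- function(samples, referenceId) {
    ids <- vapply(samples, sampleId, "")
    names(samples) <- ids
    if (!referenceId %in% ids) stop("unknown reference '", referenceId, "'")
    for (s in samples)
        if (!length(s@zstats))
            stop("sample '", s@sampleId, "' is not z-transformed")
    ref <- samples[[referenceId]]
    refP <- ref@peaks
    active <- which(nzchar(refP$name))
    targets <- .targetOrder(samples, referenceId)
    matches <- list()
    for (tid in targets) {
        tgt <- samples[[tid]]@peaks
        used <- logical(nrow(tgt))
        got <- integer(0); kept <- integer(0)
        for (r in active) {
            cand <- which(!used & nzchar(tgt$name) &
                          tgt$name == refP$name[r])
            if (!length(cand)) next
            dd <- rtDistance(refP$z1[r], refP$z2[r],
                             tgt$z1[cand], tgt$z2[cand])
            j <- cand[order(dd, cand)][1L]
            used[j] <- TRUE
            kept <- c(kept, r); got <- c(got, j)
        }
        matches[[tid]] <- stats::setNames(got, kept)
        active <- kept
        if (!length(active)) break
    }
    if (!length(active)) {
        warning("no landmark peaks: no compound name is shared by all ",
                "samples; thresholds cannot be derived")
        m <- matrix(integer(), 0L, length(ids),
                    dimnames = list(NULL, c(referenceId, targets)))
        return(new("LandmarkSet", referenceId = referenceId, members = m,
                   groupNames = character()))
    }
    m <- matrix(NA_integer_, length(active), length(ids),
                dimnames = list(NULL, c(referenceId, targets)))
    m[, referenceId] <- active
    for (tid in targets)
        m[, tid] <- unname(matches[[tid]][as.character(active)])
    new("LandmarkSet", referenceId = referenceId, members = m,
        groupNames = refP$name[active])
}

## per (target sample, landmark group): z-distance and spectrum similarity
.landmarkPairStats <- function(landmarks, samples) {
    ids <- vapply(samples, sampleId, "")
    names(samples) <- ids
    ref <- samples[[landmarks@referenceId]]
    m <- landmarks@members
    targets <- setdiff(colnames(m), landmarks@referenceId)
    out <- vector("list", length(targets))
    for (k in seq_along(targets)) {
        tid <- targets[k]
        tgt <- samples[[tid]]
        ri <- m[, landmarks@referenceId]; ti <- m[, tid]
        d <- rtDistance(ref@peaks$z1[ri], ref@peaks$z2[ri],
                        tgt@peaks$z1[ti], tgt@peaks$z2[ti])
        sim <- vapply(seq_len(nrow(m)), function(g)
            spectrumSimilarity(ref@spectra[[ri[g]]], tgt@spectra[[ti[g]]]),
            numeric(1))
        out[[k]] <- data.frame(target = tid, group = seq_len(nrow(m)),
                               d = d, sim = sim, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Candidate mixture weights
#'
#' The fixed grid over which the contribution factor is optimised.
#' @export
wCandidates <- function() {
    c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
}

#' Optimise the mixture weight over the candidate grid
#'
#' For each candidate weight, sums the mixture similarity of every
#' landmark pair over all (reference, target) sample pairs and returns the
#' arg-max candidate (ties favour the smaller weight, i.e. the spectrum
#' term). Per-sample-pair sums are retained for diagnostics.
#'
#' @param landmarks a non-empty [LandmarkSet-class].
#' @param samples list of z-transformed [PeakList-class] objects.
#' @param dmax global maximum pairwise distance (see [computeDmax()]).
#' @param candidates numeric candidate weights (default [wCandidates()]).
#' @return a [WSearchResult-class].
#' @export
optimizeW <- function(landmarks, samples, dmax, candidates = wCandidates()) {
    stopifnot(is(landmarks, "LandmarkSet"), length(candidates) >= 1L)
    if (!nrow(landmarks@members)) stop("empty landmark set")
    st <- .landmarkPairStats(landmarks, samples)
    perPair <- do.call(rbind, lapply(candidates, function(w) {
        ms <- mixtureSimilarity(st$d, st$sim, w = w, dmax = dmax)
        agg <- tapply(ms, st$target, sum)
        data.frame(w = w, target = names(agg), score = as.numeric(agg),
                   stringsAsFactors = FALSE)
    }))
    rownames(perPair) <- NULL
    scores <- vapply(candidates, function(w)
        sum(mixtureSimilarity(st$d, st$sim, w = w, dmax = dmax)), numeric(1))
    names(scores) <- as.character(candidates)
    best <- candidates[scores >= max(scores) - 1e-12]
    new("WSearchResult", wOpt = min(best), scores = scores, perPair = perPair)
}
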