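#' @include full-alignment.R
NULL

#' One-sided Grubbs critical value
#'
#' Critical value of the one-sided Grubbs statistic
#' `G = (extreme - mean) / sd` at significance `alpha` for sample size
#' `n`, from the t-distribution:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = t_{alpha/n, n-2}`.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return numeric critical value (vectorised over `n`).
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
    stopifnot(all(n >= 3L))
    t2 <- stats::qt(alpha / n, n - 2, lower.tail = FALSE)^2
    (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative one-sided Grubbs outlier removal
#'
#' Repeatedly tests the single most extreme value in the configured tail
#' and removes it while its Grubbs statistic exceeds the critical value at
#' `cfg$alpha`, up to `cfg$maxIterations` removals. The order of the
#' survivors is preserved. With fewer than 3 values, or zero spread, the
#' input is returned unchanged (with a warning in the former case).
#'
#' @param values numeric vector.
#' @param cfg a [grubbsConfig()] list.
#' @param tail `"high"` tests the maximum (used for distances), `"low"`
#'   the minimum (similarities).
#' @return the retained values, input order preserved.
#' @export
grubbsRemove <- function(values, cfg = grubbsConfig(),
                         tail = c("high", "low")) {
    tail <- match.arg(tail)
    stopifnot(inherits(cfg, "GrubbsConfig"), is.numeric(values))
    if (length(values) < 3L) {
        warning("Grubbs test undefined for n < 3; values kept unchanged")
        return(values)
    }
    keep <- values
    for (it in seq_len(cfg$maxIterations)) {
        n <- length(keep)
        if (n < 3L) break
        s <- stats::sd(keep)
        if (s == 0) break
        i <- if (tail == "high") which.max(keep) else which.min(keep)
        G <- abs(keep[i] - mean(keep)) / s
        if (G <= grubbsCritical(n, cfg$alpha)) break
        keep <- keep[-i]
    }
    keep
}

#' Derive matching thresholds from the landmark pairs
#'
#' Treats the landmark pairs as true alignments: collects, over every
#' (reference, target) sample pair, the z-space distance `d`, spectrum
#' correlation `sim` and mixture similarity `mS` of each landmark pair,
#' removes outliers from each collection by iterative one-sided Grubbs
#' (high tail for d, low tail for sim and mS), and sets `d0` to the
#' maximum retained distance, `sim0` to the minimum retained similarity
#' and `mS0` to the minimum retained mixture similarity.
#'
#' @param landmarks a non-empty [LandmarkSet-class].
#' @param samples list of z-transformed [PeakList-class] objects.
#' @param w optimised mixture weight (see [optimizeW()]).
#' @param dmax global maximum pairwise distance.
#' @param cfg a [grubbsConfig()] list.
#' @return a [Thresholds-class].
#' @export
deriveThresholds <- function(landmarks, samples, w, dmax,
                             cfg = grubbsConfig()) {
    if (!nrow(landmarks@members))
        stop("cannot derive thresholds from an empty landmark set")
    st <- .landmarkPairStats(landmarks, samples)
    ms <- mixtureSimilarity(st$d, st$sim, w = w, dmax = dmax)
    dKeep <- grubbsRemove(st$d, cfg, tail = "high")
    simKeep <- grubbsRemove(st$sim, cfg, tail = "low")
    msKeep <- grubbsRemove(ms, cfg, tail = "low")
    if (!length(dKeep) || !length(simKeep) || !length(msKeep))
        stop("threshold derivation emptied a parameter collection")
    d0 <- max(dKeep)
    if (d0 <= 0) d0 <- .Machine$double.eps  # all landmark pairs coincide
    Thresholds(d0 = d0, sim0 = min(simKeep), ms0 = min(msKeep),
               w = w, dmax = dmax)
}

## piecewise-linear map through (xs, ys) anchors, linear extrapolation
## beyond the anchor range; duplicate xs are averaged
.pwlMap <- function(x, xs, ys) {
    if (anyDuplicated(xs)) {
        ys <- as.numeric(tapply(ys, xs, mean))
        xs <- sort(unique(xs))
    } else {
        o <- order(xs); xs <- xs[o]; ys <- ys[o]
    }
    n <- length(xs)
    if (n < 2L) return(x + (ys - xs))  # single anchor: constant offset
    out <- stats::approx(xs, ys, xout = x, rule = 1)$y
    lo <- x < xs[1L]; hi <- x > xs[n]
    if (any(lo)) {
        sl <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
        out[lo] <- ys[1L] + sl * (x[lo] - xs[1L])
    }
    if (any(hi)) {
        sl <- (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
        out[hi] <- ys[n] + sl * (x[hi] - xs[n])
    }
    out
}

#' Landmark-anchored retention-time correction
#'
#' Optional correction of a target sample's retention-time axes onto the
#' reference: per dimension independently, a piecewise-linear map
#' interpolating target-landmark coordinates onto the corresponding
#' reference-landmark coordinates (linear extrapolation beyond the
#' landmark range) is applied to the target's original and z-scored
#' coordinates. Landmark peaks map exactly onto their reference partners.
#' The matching procedure never requires this step and it is disabled by
#' default; with fewer than 2 landmark anchors the identity is returned
#' with a warning.
#'
#' @param target a z-transformed [PeakList-class].
#' @param anchors data.frame with target coordinates (`rt1`, `rt2`, `z1`,
#'   `z2`) and reference coordinates (`ref_rt1`, `ref_rt2`, `ref_z1`,
#'   `ref_z2`) of this sample pair's landmark pairs.
#' @param enabled apply the correction (FALSE = identity).
#' @return the corrected [PeakList-class].
#' @export
correctRt <- function(target, anchors, enabled = TRUE) {
    stopifnot(is(target, "PeakList"))
    if (!enabled) return(target)
    if (is.null(anchors) || nrow(anchors) < 2L) {
        warning("RT correction needs >= 2 landmark anchors; identity used")
        return(target)
    }
    p <- target@peaks
    p$rt1 <- .pwlMap(p$rt1, anchors$rt1, anchors$ref_rt1)
    p$rt2 <- .pwlMap(p$rt2, anchors$rt2, anchors$ref_rt2)
    p$z1 <- .pwlMap(p$z1, anchors$z1, anchors$ref_z1)
    p$z2 <- .pwlMap(p$z2, anchors$z2, anchors$ref_z2)
    PeakList(target@sampleId, p, target@spectra,
             sourceIds = target@sourceIds, zstats = target@zstats)
}

## canonical candidate-pair table for one (reference, target) pair
.candidatePairs <- function(reference, target, refIdx, tgtIdx, th,
                            enforceMs0 = FALSE) {
    rp <- reference@peaks; tp <- target@peaks
    out <- vector("list", length(refIdx))
    for (k in seq_along(refIdx)) {
        r <- refIdx[k]
        near <- tgtIdx[abs(tp$z1[tgtIdx] - rp$z1[r]) < th@d0]
        if (!length(near)) next
        d <- rtDistance(rp$z1[r], rp$z2[r], tp$z1[near], tp$z2[near])
        near <- near[d < th@d0]; d <- d[d < th@d0]
        if (!length(near)) next
        sim <- vapply(near, function(j)
            spectrumSimilarity(reference@spectra[[r]], target@spectra[[j]]),
            numeric(1))
        ok <- sim > th@sim0
        if (!any(ok)) next
        out[[k]] <- data.frame(ref_idx = r, tgt_idx = near[ok],
                               d = d[ok], sim = sim[ok])
    }
    cand <- do.call(rbind, out)
    if (is.null(cand))
        return(data.frame(ref_idx = integer(), tgt_idx = integer(),
                          d = numeric(), sim = numeric(), ms = numeric()))
    cand$ms <- mixtureSimilarity(cand$d, cand$sim, w = th@w, dmax = th@dmax)
    if (enforceMs0) cand <- cand[cand$ms >= th@ms0, , drop = FALSE]
    ## canonical order makes the procedure invariant to input ordering
    cand <- cand[order(-cand$ms, cand$d, cand$ref_idx, cand$tgt_idx), ,
                 drop = FALSE]
    rownames(cand) <- NULL
    cand
}

.purgeConflicts <- function(pairs, accepted) {
    pairs[!(pairs$ref_idx %in% accepted$ref_idx |
            pairs$tgt_idx %in% accepted$tgt_idx), , drop = FALSE]
}

#' Align the non-landmark peaks of one sample pair
#'
#' Implements the pairwise matching of the remaining (non-landmark) peaks:
#' (1) candidate pairs are all (reference, target) combinations passing
#' the gate `d < d0` and `sim > sim0`; (2) candidates split into same-name
#' and different-name subgroups; (3) same-name pairs resolve per compound
#' name -- a name occurring in a single pair is accepted outright, a name
#' occurring in several keeps the largest-mS pair and purges pairs sharing
#' either of its peaks, repeating until the subgroup is empty; (4)
#' different-name pairs conflicting with an accepted pair are purged; (5)
#' the remaining different-name pairs are accepted greedily by largest mS
#' (purging conflicts) until none remain. Ties break by smaller d, then
#' smaller reference and target index. Each peak ends up in at most one
#' accepted pair.
#'
#' @param reference,target z-transformed [PeakList-class] objects.
#' @param thresholds a [Thresholds-class].
#' @param refIdx,tgtIdx integer indices of the peaks to align (default:
#'   all); landmark peaks should be excluded by the caller.
#' @param enforceMs0 additionally require `mS >= mS0` at the gate
#'   (default FALSE: mS only ranks).
#' @return data.frame of accepted pairs with columns `ref_idx`,
#'   `tgt_idx`, `d`, `sim`, `ms`.
#' @export
alignPair <- function(reference, target, thresholds,
                      refIdx = seq_len(nPeaks(reference)),
                      tgtIdx = seq_len(nPeaks(target)),
                      enforceMs0 = FALSE) {
    stopifnot(is(reference, "PeakList"), is(target, "PeakList"),
              is(thresholds, "Thresholds"))
    cand <- .candidatePairs(reference, target, refIdx, tgtIdx, thresholds,
                            enforceMs0)
    if (!nrow(cand)) return(cand)
    rn <- reference@peaks$name[cand$ref_idx]
    tn <- target@peaks$name[cand$tgt_idx]
    sameName <- nzchar(rn) & rn == tn
    sn <- cand[sameName, , drop = FALSE]
    dn <- cand[!sameName, , drop = FALSE]
    accepted <- cand[0L, , drop = FALSE]
    ## step 3: resolve same-name pairs per compound name
    while (nrow(sn)) {
        nm <- reference@peaks$name[sn$ref_idx]
        cnt <- table(nm)
        uniq <- nm %in% names(cnt)[cnt == 1L]
        if (any(uniq)) {
            accepted <- rbind(accepted, sn[uniq, , drop = FALSE])
            sn <- sn[!uniq, , drop = FALSE]
            sn <- .purgeConflicts(sn, accepted)
            next
        }
        best <- sn[1L, , drop = FALSE]  # canonical order: largest mS first
        accepted <- rbind(accepted, best)
        sn <- .purgeConflicts(sn, best)
    }
    ## step 4: drop different-name pairs touching an accepted peak
    dn <- .purgeConflicts(dn, accepted)
    ## step 5: greedy max-mS over the rest
    while (nrow(dn)) {
        best <- dn[1L, , drop = FALSE]
        accepted <- rbind(accepted, best)
        dn <- .purgeConflicts(dn, best)
    }
    accepted <- accepted[order(accepted$ref_idx), , drop = FALSE]
    rownames(accepted) <- NULL
    accepted
}

.consensusName <- function(nms, refName) {
    nms <- nms[nzchar(nms)]
    if (!length(nms)) return("")
    cnt <- sort(table(nms), decreasing = TRUE)
    top <- names(cnt)[cnt == max(cnt)]
    if (nzchar(refName) && refName %in% top) refName else sort(top)[1L]
}

#' Align all samples into one table
#'
#' Combines the landmark groups (one full row each) with the partial
#' alignment of the remaining peaks: every target sample is aligned
#' pairwise against the reference with [alignPair()], and pairwise matches
#' are merged into groups keyed by reference peak, so every partial row is
#' anchored to a reference peak (reference peaks with no partner become
#' singleton rows; a compound absent from the reference cannot be
#' reported). With a single input sample the table is that sample's peaks
#' as singleton rows.
#'
#' @param samples list of merged, z-transformed [PeakList-class] objects
#'   (original coordinates are reported in the table).
#' @param landmarks a [LandmarkSet-class] for these samples.
#' @param thresholds a [Thresholds-class].
#' @param enforceMs0 see [alignPair()].
#' @param rtCorrection apply [correctRt()] to each target before matching
#'   (default FALSE).
#' @return an [AlignmentTable-class].
#' @export
alignAll <- function(samples, landmarks, thresholds, enforceMs0 = FALSE,
                     rtCorrection = FALSE) {
    ids <- vapply(samples, sampleId, "")
    names(samples) <- ids
    if (length(samples) == 1L) {
        s <- samples[[1L]]
        n <- nPeaks(s)
        g <- data.frame(group_id = seq_len(n), kind = "partial",
                        consensus_name = s@peaks$name,
                        stringsAsFactors = FALSE)
        m <- data.frame(group_id = seq_len(n), sample_id = ids,
                        peak_idx = seq_len(n), name = s@peaks$name,
                        rt1 = s@peaks$rt1, rt2 = s@peaks$rt2,
                        area = s@peaks$area, stringsAsFactors = FALSE)
        return(new("AlignmentTable", samples = ids, groups = g,
                   members = m, memberSources = s@sourceIds))
    }
    refId <- landmarks@referenceId
    reference <- samples[[refId]]
    lm <- landmarks@members
    targets <- setdiff(colnames(lm), refId)
    refRest <- setdiff(seq_len(nPeaks(reference)), lm[, refId])
    ## matches[[tid]]: named vector target peak idx by reference peak idx
    matches <- list()
    for (tid in targets) {
        tgt <- samples[[tid]]
        tgtRest <- setdiff(seq_len(nPeaks(tgt)), lm[, tid])
        if (rtCorrection && nrow(lm) >= 2L) {
            rp <- reference@peaks; tp <- tgt@peaks
            anchors <- data.frame(
                rt1 = tp$rt1[lm[, tid]], rt2 = tp$rt2[lm[, tid]],
                z1 = tp$z1[lm[, tid]], z2 = tp$z2[lm[, tid]],
                ref_rt1 = rp$rt1[lm[, refId]], ref_rt2 = rp$rt2[lm[, refId]],
                ref_z1 = rp$z1[lm[, refId]], ref_z2 = rp$z2[lm[, refId]])
            tgt <- correctRt(tgt, anchors, enabled = TRUE)
        }
        acc <- alignPair(reference, tgt, thresholds,
                         refIdx = refRest, tgtIdx = tgtRest,
                         enforceMs0 = enforceMs0)
        matches[[tid]] <- stats::setNames(acc$tgt_idx, acc$ref_idx)
    }
    ## assemble: landmark rows first, then one partial row per rest peak
    gRows <- list(); mRows <- list(); mSrc <- list()
    gid <- 0L
    for (g in seq_len(nrow(lm))) {
        gid <- gid + 1L
        gRows[[gid]] <- data.frame(group_id = gid, kind = "landmark",
                                   consensus_name = landmarks@groupNames[g],
                                   stringsAsFactors = FALSE)
        rows <- lapply(colnames(lm), function(sid) {
            s <- samples[[sid]]; i <- lm[g, sid]
            data.frame(group_id = gid, sample_id = sid, peak_idx = i,
                       name = s@peaks$name[i], rt1 = s@peaks$rt1[i],
                       rt2 = s@peaks$rt2[i], area = s@peaks$area[i],
                       stringsAsFactors = FALSE)
        })
        mRows[[gid]] <- do.call(rbind, rows)
        mSrc[[gid]] <- lapply(colnames(lm),
                              function(sid) samples[[sid]]@sourceIds[[lm[g, sid]]])
    }
    for (r in refRest) {
        gid <- gid + 1L
        memIds <- refId; memIdx <- r
        for (tid in targets) {
            j <- matches[[tid]][as.character(r)]
            if (!is.na(j)) { memIds <- c(memIds, tid); memIdx <- c(memIdx, j) }
        }
        rows <- mapply(function(sid, i) {
            s <- samples[[sid]]
            data.frame(group_id = gid, sample_id = sid, peak_idx = i,
                       name = s@peaks$name[i], rt1 = s@peaks$rt1[i],
                       rt2 = s@peaks$rt2[i], area = s@peaks$area[i],
                       stringsAsFactors = FALSE)
        }, memIds, memIdx, SIMPLIFY = FALSE)
        gRows[[gid]] <- data.frame(
            group_id = gid, kind = "partial",
            consensus_name = .consensusName(
                vapply(rows, function(x) x$name, ""),
                reference@peaks$name[r]),
            stringsAsFactors = FALSE)
        mRows[[gid]] <- do.call(rbind, rows)
        mSrc[[gid]] <- mapply(function(sid, i) samples[[sid]]@sourceIds[[i]],
                              memIds, memIdx, SIMPLIFY = FALSE)
    }
    members <- do.call(rbind, mRows)
    rownames(members) <- NULL
    out <- new("AlignmentTable", samples = colnames(lm),
               groups = do.call(rbind, gRows), members = members,
               memberSources = unlist(mSrc, recursive = FALSE,
                                      use.names = FALSE))
    validObject(out)
    out
}
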