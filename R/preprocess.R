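#' @include similarity.R
NULL

## area-weighted average of member spectra on the union m/z grid
.mergeSpectra <- function(specs, areas) {
    grid <- sort(unique(unlist(lapply(specs, mz))))
    acc <- numeric(length(grid))
    wts <- areas / sum(areas)
    for (k in seq_along(specs))
        acc[match(specs[[k]]@mz, grid)] <-
            acc[match(specs[[k]]@mz, grid)] + wts[k] * specs[[k]]@intensity
    new("MassSpectrum", mz = grid, intensity = acc)
}

#' Merge split peak entries within one sample
#'
#' Deconvolution software can report one compound as several adjacent
#' entries. Entries are grouped by transitive chaining: starting from each
#' peak in (rt1, rt2) order, any still-unassigned peak lying within the
#' forward rt1 window and the rt2 window of an already-accepted member,
#' with spectrum correlation above `r0` against that member, joins the
#' group, and the windows slide on to it. Each group is replaced by one
#' representative whose area is the member sum and whose retention times
#' are the area-weighted member means in both dimensions; its spectrum is
#' the area-weighted average spectrum on the union m/z grid and its name
#' that of the largest-area member. Total area is conserved and source ids
#' accumulate.
#'
#' @param sample a [PeakList-class] (peaks sorted by rt1, rt2).
#' @param cfg a [mergeConfig()] list.
#' @return a [PeakList-class] with merged entries, re-sorted.
#' @export
mergeEntries <- function(sample, cfg = mergeConfig()) {
    stopifnot(is(sample, "PeakList"), inherits(cfg, "MergeConfig"))
    p <- sample@peaks
    n <- nrow(p)
    if (n <= 1L) return(sample)
    groupOf <- integer(n)   # 0 = unassigned
    ng <- 0L
    for (i in seq_len(n)) {
        if (groupOf[i]) next
        ng <- ng + 1L
        groupOf[i] <- ng
        queue <- i
        while (length(queue)) {
            m <- queue[1L]; queue <- queue[-1L]
            cand <- which(groupOf == 0L &
                          p$rt1 >= p$rt1[m] &
                          p$rt1 - p$rt1[m] <= cfg$rt1Window &
                          abs(p$rt2 - p$rt2[m]) <= cfg$rt2Window)
            for (j in cand) {
                if (groupOf[j]) next
                if (spectrumSimilarity(sample@spectra[[m]],
                                       sample@spectra[[j]]) > cfg$r0) {
                    groupOf[j] <- ng
                    queue <- c(queue, j)
                }
            }
        }
    }
    if (ng == n) return(sample)
    rows <- vector("list", ng); specs <- vector("list", ng)
    srcs <- vector("list", ng)
    for (g in seq_len(ng)) {
        idx <- which(groupOf == g)
        if (length(idx) == 1L) {
            rows[[g]] <- p[idx, c("name", "rt1", "rt2", "area"), drop = FALSE]
            specs[[g]] <- sample@spectra[[idx]]
            srcs[[g]] <- sample@sourceIds[[idx]]
            next
        }
        a <- p$area[idx]; atot <- sum(a)
        rows[[g]] <- data.frame(
            name = p$name[idx][which.max(a)],
            rt1 = sum(a * p$rt1[idx]) / atot,
            rt2 = sum(a * p$rt2[idx]) / atot,
            area = atot, stringsAsFactors = FALSE)
        specs[[g]] <- .mergeSpectra(sample@spectra[idx], a)
        srcs[[g]] <- sort(unique(unlist(sample@sourceIds[idx])))
    }
    PeakList(sample@sampleId, do.call(rbind, rows), specs, sourceIds = srcs)
}

#' Z-score both retention-time dimensions of one sample
#'
#' Standardises rt1 and rt2 over the sample's own peaks (sample standard
#' deviation, n - 1) so the short second dimension contributes on equal
#' footing with the first in distance calculations. Original retention
#' times are kept; z-coordinates are stored in the `z1`/`z2` columns and
#' the per-sample statistics in `zStats()`.
#'
#' @param sample a [PeakList-class] with at least 2 peaks.
#' @return the transformed [PeakList-class].
#' @export
zscoreTransform <- function(sample) {
    stopifnot(is(sample, "PeakList"))
    p <- sample@peaks
    if (nrow(p) < 2L)
        stop("degenerate sample '", sample@sampleId,
             "': need >= 2 peaks to z-transform")
    s <- c(rt1_mean = mean(p$rt1), rt1_sd = stats::sd(p$rt1),
           rt2_mean = mean(p$rt2), rt2_sd = stats::sd(p$rt2))
    if (s[["rt1_sd"]] == 0 || s[["rt2_sd"]] == 0)
        stop("degenerate sample '", sample@sampleId,
             "': zero retention-time variance")
    out <- sample
    out@peaks$z1 <- (p$rt1 - s[["rt1_mean"]]) / s[["rt1_sd"]]
    out@peaks$z2 <- (p$rt2 - s[["rt2_mean"]]) / s[["rt2_sd"]]
    out@zstats <- s
    validObject(out)
    out
}

#' Maximum pairwise peak distance over all samples
#'
#' The largest Euclidean distance between any two peaks (within or across
#' samples) in z-score retention-time space; it normalises the distance
#' term of the mixture similarity. Computed exactly via the convex hull of
#' the pooled z-coordinates (the diameter is attained on the hull).
#'
#' @param samples list of z-transformed [PeakList-class] objects.
#' @return positive numeric.
#' @export
computeDmax <- function(samples) {
    z <- do.call(rbind, lapply(samples, function(s) {
        if (!length(s@zstats)) stop("sample '", s@sampleId,
                                    "' is not z-transformed")
        cbind(s@peaks$z1, s@peaks$z2)
    }))
    if (is.null(z) || nrow(z) < 2L)
        stop("need at least 2 peaks to compute dmax")
    pts <- unique(z)
    if (nrow(pts) < 2L) stop("all peaks coincide in z-space; dmax undefined")
    if (nrow(pts) > 3L)
        pts <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
    max(stats::dist(pts))
}
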