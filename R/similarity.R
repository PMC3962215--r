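#' @include accessors.R
NULL

#' Retention-time distance in z-score space
#'
#' Euclidean distance between two peaks in the two-dimensional z-scored
#' retention-time plane. Both arguments must carry z-transformed
#' coordinates (see [zscoreTransform()]).
#'
#' @param z1a,z2a z-scored coordinates of the first peak.
#' @param z1b,z2b z-scored coordinates of the second peak.
#' @return non-negative numeric (vectorised over peaks).
#' @export
rtDistance <- function(z1a, z2a, z1b, z2b) {
    if (any(is.na(c(z1a, z2a, z1b, z2b))))
        stop("rtDistance requires z-transformed coordinates (found NA)")
    sqrt((z1a - z1b)^2 + (z2a - z2b)^2)
}

## intensities of two sparse spectra laid out on the union m/z grid,
## absent channels zero-filled
.unionVectors <- function(x, y) {
    grid <- sort(unique(c(x@mz, y@mz)))
    xi <- numeric(length(grid)); yi <- numeric(length(grid))
    xi[match(x@mz, grid)] <- x@intensity
    yi[match(y@mz, grid)] <- y@intensity
    list(x = xi, y = yi)
}

#' Spectrum similarity (Pearson correlation)
#'
#' Pearson correlation of two fragment spectra on the union of their m/z
#' grids, with channels absent from one spectrum set to zero so that
#' absent-ion evidence counts against a match. If either zero-filled
#' vector is constant the correlation is undefined; this is reported as
#' -1 (a flat spectrum should never win a match).
#'
#' @param x,y [MassSpectrum-class] objects.
#' @return numeric in [-1, 1].
#' @export
spectrumSimilarity <- function(x, y) {
    stopifnot(is(x, "MassSpectrum"), is(y, "MassSpectrum"))
    v <- .unionVectors(x, y)
    if (length(v$x) < 2L || stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
        return(-1)
    stats::cor(v$x, v$y)
}

#' Mixture similarity of two peaks
#'
#' The convex blend of a normalised retention-time proximity term and the
#' spectrum correlation:
#' `mS = w * (1 - (d / dmax)^2) + (1 - w) * sim`,
#' where `w` is the contribution factor, `d` the two-dimensional
#' retention-time distance in z-score space and `dmax` the maximum
#' pairwise peak distance over all samples. Distances exceeding `dmax`
#' (possible for peaks outside the landmark envelope) are clamped with a
#' warning.
#'
#' @param d non-negative distance(s) in z-score space.
#' @param sim spectrum correlation(s) in [-1, 1].
#' @param w contribution factor in [0, 1].
#' @param dmax maximum pairwise distance, positive.
#' @return numeric mixture similarity, at most 1 (vectorised).
#' @examples
#' mixtureSimilarity(1, 0.8, w = 0.3, dmax = 2)  # 0.785
#' @export
mixtureSimilarity <- function(d, sim, w, dmax) {
    stopifnot(length(w) == 1L, w >= 0, w <= 1,
              length(dmax) == 1L, dmax > 0)
    if (any(d < 0)) stop("negative distance")
    if (any(d > dmax)) {
        warning("distance(s) exceed dmax; clamped")
        d <- pmin(d, dmax)
    }
    w * (1 - (d / dmax)^2) + (1 - w) * sim
}
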