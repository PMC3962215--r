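## Small in-code fixtures shared across the suite.

## spectrum with given channels/intensities (no rounding surprises)
spec <- function(mz, int) MassSpectrum(mz, int, roundMz = FALSE)

## random sparse spectrum over unit channels
randomSpec <- function(nChan = 12L, mzRange = 50:200) {
    spec(sort(sample(mzRange, nChan)), stats::rexp(nChan) * 100)
}

## build a PeakList from vectors; distinct default spectra per peak
toyPeakList <- function(id, rt1, rt2, area = rep(100, length(rt1)),
                        name = sprintf("Cmp_%02d", seq_along(rt1)),
                        spectra = NULL, z = FALSE) {
    if (is.null(spectra))
        spectra <- lapply(seq_along(rt1), function(i)
            spec(c(50 + 3 * i, 60 + 3 * i, 90 + 2 * i),
                 c(100, 400 + 10 * i, 250)))
    pl <- PeakList(id, data.frame(name = name, rt1 = rt1, rt2 = rt2,
                                  area = area, stringsAsFactors = FALSE),
                   spectra)
    if (z) pl <- zscoreTransform(pl)
    pl
}

## textbook two-pass Pearson on zero-filled union vectors (oracle)
naivePearson <- function(x, y) {
    grid <- sort(unique(c(mz(x), mz(y))))
    xi <- numeric(length(grid)); yi <- numeric(length(grid))
    xi[match(mz(x), grid)] <- intensity(x)
    yi[match(mz(y), grid)] <- intensity(y)
    mx <- mean(xi); my <- mean(yi)
    num <- sum((xi - mx) * (yi - my))
    den <- sqrt(sum((xi - mx)^2) * sum((yi - my)^2))
    if (den == 0) return(NA_real_)
    num / den
}

## independent greedy max-mS matcher: full matrices, repeated global argmax
greedyMatchOracle <- function(reference, target, w, dmax,
                              d0 = Inf, sim0 = -Inf) {
    rp <- peaks(reference); tp <- peaks(target)
    nr <- nrow(rp); nt <- nrow(tp)
    d <- matrix(Inf, nr, nt); s <- matrix(-Inf, nr, nt)
    for (i in seq_len(nr)) for (j in seq_len(nt)) {
        d[i, j] <- sqrt((rp$z1[i] - tp$z1[j])^2 + (rp$z2[i] - tp$z2[j])^2)
        s[i, j] <- naivePearson(spectra(reference)[[i]], spectra(target)[[j]])
    }
    ok <- d < d0 & s > sim0
    ms <- w * (1 - (pmin(d, dmax) / dmax)^2) + (1 - w) * s
    out <- NULL
    while (any(ok)) {
        best <- which(ok)
        best <- best[order(-ms[best], d[best], (best - 1) %% nr + 1,
                           (best - 1) %/% nr + 1)][1L]
        i <- (best - 1) %% nr + 1; j <- (best - 1) %/% nr + 1
        out <- rbind(out, data.frame(ref_idx = i, tgt_idx = j))
        ok[i, ] <- FALSE; ok[, j] <- FALSE
    }
    if (is.null(out)) data.frame(ref_idx = integer(), tgt_idx = integer())
    else out[order(out$ref_idx), , drop = FALSE]
}

## noiseless multi-sample instance: same compounds everywhere, constant
## per-sample RT offsets (z-scoring removes them exactly)
noiselessSamples <- function(nSamples = 3L, nCompounds = 5L, seed = 42L) {
    set.seed(seed)
    rt1 <- sort(runif(nCompounds, 400, 2000))
    rt2 <- runif(nCompounds, 1, 4)
    specs <- lapply(seq_len(nCompounds), function(i) randomSpec())
    lapply(seq_len(nSamples), function(s) {
        PeakList(sprintf("T%02d", s),
                 data.frame(name = sprintf("Cmp_%02d", seq_len(nCompounds)),
                            rt1 = rt1 + 5 * s, rt2 = rt2 + 0.05 * s,
                            area = runif(nCompounds, 1e4, 1e6),
                            stringsAsFactors = FALSE),
                 specs)
    })
}
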