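test_that("selectReference picks most peaks with documented tie-break", {
    a <- toyPeakList("A", rt1 = seq(100, 500, length.out = 50),
                     rt2 = rep(1:5, 10))
    b <- toyPeakList("B", rt1 = seq(100, 600, length.out = 60),
                     rt2 = rep(1:6, 10))
    c_ <- toyPeakList("C", rt1 = seq(100, 550, length.out = 55),
                      rt2 = rep(1:5, 11))
    expect_equal(selectReference(list(a, b, c_)), "B")
    a50 <- toyPeakList("A", rt1 = seq(100, 500, length.out = 50),
                       rt2 = rep(1:5, 10))
    b50 <- toyPeakList("B", rt1 = seq(100, 500, length.out = 50),
                       rt2 = rep(1:5, 10))
    expect_equal(selectReference(list(b50, a50)), "A")   # lexicographic tie
    expect_error(selectReference(list(a)), "2 samples")
    ## random policy is reproducible under a fixed seed
    set.seed(99); r1 <- selectReference(list(a, b, c_), policy = "random")
    set.seed(99); r2 <- selectReference(list(a, b, c_), policy = "random")
    expect_identical(r1, r2)
})

test_that("findLandmarks recovers all shared compounds on toy samples", {
    sams <- lapply(noiselessSamples(nSamples = 3, nCompounds = 5),
                   zscoreTransform)
    ref <- selectReference(sams)
    lmk <- findLandmarks(sams, ref)
    expect_equal(nrow(members(lmk)), 5L)
    expect_setequal(groupNames(lmk), sprintf("Cmp_%02d", 1:5))
    ## brute-force check: every group's members carry one shared name
    for (g in seq_len(nrow(members(lmk))))
        for (sid in sampleIds(lmk)) {
            s <- sams[[match(sid, vapply(sams, sampleId, ""))]]
            expect_equal(peaks(s)$name[members(lmk)[g, sid]],
                         groupNames(lmk)[g])
        }
    ## partition: no peak in two groups
    for (sid in sampleIds(lmk))
        expect_false(anyDuplicated(members(lmk)[, sid]) > 0)
})

test_that("findLandmarks is empty with a warning when no name is shared", {
    sams <- noiselessSamples(nSamples = 2, nCompounds = 3)
    p2 <- peaks(sams[[2]]); p2$name <- c("X", "Y", "Z")
    sams[[2]] <- PeakList("T02", p2, spectra(sams[[2]]))
    sams <- lapply(sams, zscoreTransform)
    expect_warning(lmk <- findLandmarks(sams, "T01"), "no landmark")
    expect_equal(nrow(members(lmk)), 0L)
})

test_that("duplicate names resolve to the nearer candidate in z-space", {
    ref <- zscoreTransform(toyPeakList("R", rt1 = c(100, 500, 900),
                                       rt2 = c(1, 2, 3),
                                       name = c("X", "Y", "Z")))
    ## target holds two peaks named X; the one at rt1 110 is nearer
    tgt <- zscoreTransform(toyPeakList("T", rt1 = c(110, 480, 520, 910),
                                       rt2 = c(1.02, 2.1, 1.9, 3.05),
                                       name = c("X", "X", "Y", "Z"),
                                       spectra = lapply(1:4, function(i)
                                           spec(c(60, 70), c(10 * i, 5)))))
    lmk <- findLandmarks(list(ref, tgt), "R")
    gX <- which(groupNames(lmk) == "X")
    iT <- unname(members(lmk)[gX, "T"])
    dts <- rtDistance(peaks(ref)$z1[1], peaks(ref)$z2[1],
                      peaks(tgt)$z1, peaks(tgt)$z2)
    named_X <- which(peaks(tgt)$name == "X")
    expect_equal(iT, named_X[which.min(dts[named_X])])
})

test_that("findLandmarks is invariant to within-sample peak order", {
    sams <- noiselessSamples(nSamples = 3, nCompounds = 8, seed = 77)
    shuffled <- lapply(sams, function(s) {
        o <- sample(nPeaks(s))
        PeakList(sampleId(s), peaks(s)[o, ], spectra(s)[o])
    })
    l1 <- findLandmarks(lapply(sams, zscoreTransform), "T01")
    l2 <- findLandmarks(lapply(shuffled, zscoreTransform), "T01")
    ## same groups by name and identical matched retention times
    o1 <- order(groupNames(l1)); o2 <- order(groupNames(l2))
    expect_equal(groupNames(l1)[o1], groupNames(l2)[o2])
    expect_equal(members(l1)[o1, sampleIds(l1)],
                 members(l2)[o2, sampleIds(l1)])
})

test_that("optimizeW hits the monotone limits of the blend", {
    sams <- lapply(noiselessSamples(nSamples = 3, nCompounds = 6, seed = 3),
                   zscoreTransform)
    lmk <- findLandmarks(sams, "T01")
    ## constant offsets vanish under z-scoring: all d ~ 0 while spectra
    ## are identical -> every candidate ties -> smallest w wins
    tie <- optimizeW(lmk, sams, dmax = 5)
    expect_equal(tie@wOpt, 0.05)
    ## degrade the spectra of one sample (sim < 1, d ~ 0): distance term
    ## dominates, largest candidate wins
    noisy <- sams
    sp <- lapply(spectra(noisy[[2]]), function(s)
        spec(mz(s), intensity(s) + rev(intensity(s)) * 0.8))
    noisy[[2]] <- zscoreTransform(PeakList("T02", peaks(noisy[[2]]), sp))
    up <- optimizeW(findLandmarks(noisy, "T01"), noisy, dmax = 5)
    expect_equal(up@wOpt, 0.95)
})

test_that("optimizeW equals an exhaustive loop over the candidate grid", {
    set.seed(17)
    sams <- noiselessSamples(nSamples = 4, nCompounds = 10, seed = 55)
    ## jitter RTs so distances are informative
    sams <- lapply(sams, function(s) {
        p <- peaks(s)
        p$rt1 <- p$rt1 + rnorm(nrow(p), 0, 2)
        p$rt2 <- p$rt2 + rnorm(nrow(p), 0, 0.05)
        zscoreTransform(PeakList(sampleId(s), p, spectra(s)))
    })
    lmk <- findLandmarks(sams, "T01")
    dmax <- computeDmax(sams)
    res <- optimizeW(lmk, sams, dmax)
    ## independent exhaustive evaluation
    names(sams) <- vapply(sams, sampleId, "")
    refP <- peaks(sams[["T01"]])
    scores <- sapply(wCandidates(), function(w) {
        tot <- 0
        for (tid in setdiff(sampleIds(lmk), "T01")) {
            tp <- peaks(sams[[tid]])
            for (g in seq_len(nrow(members(lmk)))) {
                ri <- members(lmk)[g, "T01"]; ti <- members(lmk)[g, tid]
                d <- sqrt((refP$z1[ri] - tp$z1[ti])^2 +
                          (refP$z2[ri] - tp$z2[ti])^2)
                sim <- naivePearson(spectra(sams[["T01"]])[[ri]],
                                    spectra(sams[[tid]])[[ti]])
                tot <- tot + w * (1 - (d / dmax)^2) + (1 - w) * sim
            }
        }
        tot
    })
    expect_equal(unname(res@scores), scores, tolerance = 1e-9)
    expect_equal(res@wOpt, wCandidates()[which.max(scores)])
})
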