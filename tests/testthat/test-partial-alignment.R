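test_that("grubbsRemove rejects a gross high-tail outlier and stops", {
    kept <- grubbsRemove(c(8, 9, 10, 10, 10, 50), grubbsConfig(),
                         tail = "high")
    expect_equal(kept, c(8, 9, 10, 10, 10))
    ## low tail mirror
    keptL <- grubbsRemove(c(-40, 8, 9, 10, 10, 10), grubbsConfig(),
                          tail = "low")
    expect_equal(keptL, c(8, 9, 10, 10, 10))
})

test_that("grubbsRemove leaves degenerate inputs unchanged", {
    expect_equal(grubbsRemove(rep(5, 10), grubbsConfig(), "high"),
                 rep(5, 10))
    expect_warning(kept <- grubbsRemove(c(1, 100), grubbsConfig(), "high"),
                   "n < 3")
    expect_equal(kept, c(1, 100))
})

test_that("grubbsCritical matches the published one-sided 5% table", {
    published <- c(`3` = 1.1531, `4` = 1.4625, `5` = 1.6714, `6` = 1.8221,
                   `7` = 1.9381, `10` = 2.1761, `15` = 2.4090,
                   `20` = 2.5566, `30` = 2.7451)
    got <- grubbsCritical(as.integer(names(published)), alpha = 0.05)
    expect_equal(unname(got), unname(published), tolerance = 1e-3)
})

test_that("grubbsRemove decisions follow the critical value for n=3..30", {
    set.seed(61)
    for (rep in 1:30) {
        n <- sample(3:30, 1)
        x <- c(rnorm(n - 1), rnorm(1, sd = sample(c(1, 8), 1)))
        kept <- grubbsRemove(x, grubbsConfig(maxIterations = 1), "high")
        G <- (max(x) - mean(x)) / sd(x)
        if (G > grubbsCritical(n, 0.05)) {
            expect_equal(kept, x[-which.max(x)])
        } else {
            expect_equal(kept, x)
        }
    }
})

test_that("deriveThresholds takes extremes of the retained collections", {
    sams <- lapply(noiselessSamples(nSamples = 2, nCompounds = 4, seed = 9),
                   zscoreTransform)
    lmk <- findLandmarks(sams, "T01")
    th <- deriveThresholds(lmk, sams, w = 0.5, dmax = 4)
    expect_s4_class(th, "Thresholds")
    st <- gcxgcAlign:::.landmarkPairStats(lmk, sams)
    ## no outliers here: d0 / sim0 are the plain extremes
    expect_equal(th@d0, max(max(st$d), .Machine$double.eps))
    expect_equal(th@sim0, min(st$sim))
    expect_lte(th@d0, th@dmax)
    expect_error(deriveThresholds(
        new("LandmarkSet", referenceId = "T01",
            members = matrix(integer(), 0, 2,
                             dimnames = list(NULL, c("T01", "T02"))),
            groupNames = character()), sams, 0.5, 4), "empty")
})

test_that("deriveThresholds drops a distance outlier before taking the max", {
    ## hand case: distances [0.10, 0.15, 0.20, 5.0] -> 5.0 rejected, d0 = 0.20
    kept <- grubbsRemove(c(0.10, 0.15, 0.20, 5.0), grubbsConfig(), "high")
    expect_equal(kept, c(0.10, 0.15, 0.20))
    expect_equal(max(kept), 0.20)
})

test_that("correctRt maps landmarks exactly and defaults to identity", {
    tgt <- zscoreTransform(toyPeakList("T",
        rt1 = c(100, 200, 300, 400), rt2 = c(1, 2, 3, 4)))
    anchors <- data.frame(rt1 = c(100, 300), rt2 = c(1, 3),
                          z1 = peaks(tgt)$z1[c(1, 3)],
                          z2 = peaks(tgt)$z2[c(1, 3)],
                          ref_rt1 = c(98, 298), ref_rt2 = c(1.1, 3.1),
                          ref_z1 = peaks(tgt)$z1[c(1, 3)] + 0.1,
                          ref_z2 = peaks(tgt)$z2[c(1, 3)] - 0.2)
    out <- correctRt(tgt, anchors, enabled = TRUE)
    expect_equal(peaks(out)$rt1[c(1, 3)], c(98, 298))
    expect_equal(peaks(out)$rt2[c(1, 3)], c(1.1, 3.1))
    expect_equal(peaks(out)$z1[c(1, 3)], anchors$ref_z1)
    ## disabled -> identity
    expect_equal(peaks(correctRt(tgt, anchors, enabled = FALSE)),
                 peaks(tgt))
    ## too few anchors -> identity with warning
    expect_warning(idn <- correctRt(tgt, anchors[1, ], enabled = TRUE),
                   "anchors")
    expect_equal(peaks(idn), peaks(tgt))
})

test_that("correctRt recovers a two-segment distortion via interpolation", {
    ## reference scale distorted in two linear pieces; anchors at 6 points
    warp <- function(x) ifelse(x <= 1000, 1.02 * x + 5,
                               1.02 * 1000 + 5 + 0.97 * (x - 1000))
    lmRt <- c(200, 500, 900, 1100, 1500, 1900)
    tgt <- zscoreTransform(toyPeakList("T",
        rt1 = sort(c(lmRt, 650, 1300)), rt2 = seq(1, 2.4, by = 0.2)))
    p <- peaks(tgt)
    anchors <- data.frame(rt1 = lmRt, rt2 = p$rt2[match(lmRt, p$rt1)],
                          z1 = p$z1[match(lmRt, p$rt1)],
                          z2 = p$z2[match(lmRt, p$rt1)],
                          ref_rt1 = warp(lmRt),
                          ref_rt2 = p$rt2[match(lmRt, p$rt1)],
                          ref_z1 = p$z1[match(lmRt, p$rt1)],
                          ref_z2 = p$z2[match(lmRt, p$rt1)])
    out <- correctRt(tgt, anchors, enabled = TRUE)
    ## non-landmark peaks land within the oracle interpolation of the warp:
    ## both 650 and 1300 sit inside a single linear segment of the warp, so
    ## interpolation is exact there
    expect_equal(peaks(out)$rt1[match(650, p$rt1)], warp(650),
                 tolerance = 1e-9)
    expect_equal(peaks(out)$rt1[match(1300, p$rt1)], warp(1300),
                 tolerance = 1e-9)
})

## ---- alignPair ----

mkTh <- function(d0, sim0, w = 0.5, dmax = 10, ms0 = -1)
    Thresholds(d0 = d0, sim0 = sim0, ms0 = ms0, w = w, dmax = dmax)

test_that("alignPair accepts unambiguous in-gate pairs and honours gates", {
    specs <- lapply(1:3, function(i) randomSpec(10))
    ref <- zscoreTransform(toyPeakList("R", rt1 = c(100, 500, 900),
                                       rt2 = c(1, 2, 3),
                                       name = c("A", "B", "C"),
                                       spectra = specs))
    tgt <- zscoreTransform(toyPeakList("T", rt1 = c(102, 505, 910),
                                       rt2 = c(1.01, 2.02, 3.03),
                                       name = c("A", "B", "C"),
                                       spectra = specs))
    acc <- alignPair(ref, tgt, mkTh(d0 = 0.5, sim0 = 0.9))
    expect_equal(acc$ref_idx, 1:3)
    expect_equal(acc$tgt_idx, 1:3)
    ## post-hoc: every accepted pair satisfies the gate
    expect_true(all(acc$d < 0.5) && all(acc$sim > 0.9))
    ## distance gate excludes everything when d0 is tiny
    expect_equal(nrow(alignPair(ref, tgt, mkTh(d0 = 1e-9, sim0 = -1))), 0L)
    ## similarity gate excludes everything when sim0 = 1
    expect_equal(nrow(alignPair(ref, tgt, mkTh(d0 = 5, sim0 = 1))), 0L)
})

test_that("same-name conflicts resolve to the largest mixture similarity", {
    sp <- randomSpec(10)
    ref <- zscoreTransform(toyPeakList("R", rt1 = c(100, 500, 900),
                                       rt2 = c(1, 2, 3),
                                       name = c("X", "", ""),
                                       spectra = rep(list(sp), 3)))
    ## two target peaks named X, both in gate of ref peak 1
    tgt <- zscoreTransform(toyPeakList("T", rt1 = c(104, 101, 500, 900),
                                       rt2 = c(1.0, 1.0, 2, 3),
                                       name = c("X", "X", "", ""),
                                       spectra = rep(list(sp), 4)))
    acc <- alignPair(ref, tgt, mkTh(d0 = 3, sim0 = 0.5))
    xrow <- acc[acc$ref_idx == 1, ]
    expect_equal(nrow(xrow), 1L)
    ## identical spectra: larger mS = smaller d = the peak at rt1 101
    expect_equal(xrow$tgt_idx, which(peaks(tgt)$rt1 == 101))
    ## exhaustive check over the toy candidate set
    d1 <- rtDistance(peaks(ref)$z1[1], peaks(ref)$z2[1],
                     peaks(tgt)$z1[1:2], peaks(tgt)$z2[1:2])
    expect_equal(xrow$d, min(d1))
})

test_that("alignPair is invariant to peak input order", {
    set.seed(23)
    specs <- lapply(1:6, function(i) randomSpec(8))
    ref <- zscoreTransform(toyPeakList("R",
        rt1 = c(100, 300, 500, 700, 900, 1100), rt2 = 1:6 / 2,
        name = c("A", "B", "", "", "C", ""), spectra = specs))
    mkTgt <- function(perm) {
        p <- data.frame(name = c("A", "B", "", "", "C", "")[perm],
                        rt1 = (c(100, 300, 500, 700, 900, 1100) + 3)[perm],
                        rt2 = (1:6 / 2 + 0.02)[perm],
                        area = rep(10, 6), stringsAsFactors = FALSE)
        zscoreTransform(PeakList("T", p, specs[perm]))
    }
    t1 <- mkTgt(1:6); t2 <- mkTgt(sample(6))
    a1 <- alignPair(ref, t1, mkTh(d0 = 1, sim0 = 0))
    a2 <- alignPair(ref, t2, mkTh(d0 = 1, sim0 = 0))
    ## compare by matched retention times (indices differ after sorting)
    key <- function(a, t) paste(a$ref_idx, peaks(t)$rt1[a$tgt_idx])
    expect_setequal(key(a1, t1), key(a2, t2))
})

test_that("loosened thresholds reduce alignPair to greedy max-mS matching", {
    set.seed(29)
    for (rep in 1:200) {
        nr <- sample(2:8, 1); nt <- sample(2:8, 1)
        ref <- zscoreTransform(toyPeakList("R",
            rt1 = sort(runif(nr, 100, 1000)), rt2 = runif(nr, 1, 4),
            name = rep("", nr),
            spectra = lapply(seq_len(nr), function(i) randomSpec(6))))
        tgt <- zscoreTransform(toyPeakList("T",
            rt1 = sort(runif(nt, 100, 1000)), rt2 = runif(nt, 1, 4),
            name = rep("", nt),
            spectra = lapply(seq_len(nt), function(i) randomSpec(6))))
        th <- mkTh(d0 = 100, sim0 = -1, w = 0.4, dmax = 100)
        acc <- alignPair(ref, tgt, th)
        orc <- greedyMatchOracle(ref, tgt, w = 0.4, dmax = 100)
        expect_equal(acc$ref_idx, orc$ref_idx)
        expect_equal(acc$tgt_idx, orc$tgt_idx)
    }
})

test_that("each peak joins at most one accepted pair", {
    set.seed(37)
    for (rep in 1:20) {
        nr <- sample(4:10, 1); nt <- sample(4:10, 1)
        nm <- function(n) sample(c("A", "B", ""), n, replace = TRUE)
        ref <- zscoreTransform(toyPeakList("R",
            rt1 = sort(runif(nr, 100, 400)), rt2 = runif(nr, 1, 2),
            name = nm(nr),
            spectra = lapply(seq_len(nr), function(i) randomSpec(6))))
        tgt <- zscoreTransform(toyPeakList("T",
            rt1 = sort(runif(nt, 100, 400)), rt2 = runif(nt, 1, 2),
            name = nm(nt),
            spectra = lapply(seq_len(nt), function(i) randomSpec(6))))
        acc <- alignPair(ref, tgt, mkTh(d0 = 2, sim0 = -0.99))
        expect_false(anyDuplicated(acc$ref_idx) > 0)
        expect_false(anyDuplicated(acc$tgt_idx) > 0)
    }
})

## ---- alignAll ----

test_that("alignAll yields one full row per compound on clean samples", {
    sams <- lapply(noiselessSamples(nSamples = 3, nCompounds = 6, seed = 19),
                   zscoreTransform)
    lmk <- findLandmarks(sams, "T01")
    th <- deriveThresholds(lmk, sams, w = 0.5, dmax = computeDmax(sams))
    tab <- alignAll(sams, lmk, th)
    expect_equal(length(fullRows(tab)), 6L)
    expect_true(all(groups(tab)$kind == "landmark"))
})

test_that("compounds absent from the reference are not reported", {
    sams <- noiselessSamples(nSamples = 3, nCompounds = 5, seed = 23)
    ## drop compound 5 from the reference only (reference = most peaks)
    p1 <- peaks(sams[[1]])[-5, ]; s1 <- spectra(sams[[1]])[-5]
    sams[[1]] <- PeakList("T01", p1, s1)
    sams <- lapply(sams, zscoreTransform)
    ref <- selectReference(sams)
    expect_true(ref %in% c("T02", "T03"))
    lmk <- findLandmarks(sams, "T01")  # force T01 as reference
    th <- deriveThresholds(lmk, sams, w = 0.5, dmax = computeDmax(sams))
    tab <- alignAll(sams, lmk, th)
    expect_false("Cmp_05" %in% groups(tab)$consensus_name)
})

test_that("a single sample degenerates to singleton rows", {
    s <- toyPeakList("solo", rt1 = c(100, 200, 300), rt2 = c(1, 2, 3))
    tab <- alignAll(list(s), NULL, NULL)
    expect_equal(nrow(groups(tab)), 3L)
    expect_true(all(groups(tab)$kind == "partial"))
    expect_equal(length(fullRows(tab)), 3L)  # one sample: every row full
})

test_that("no peak appears in two rows of the final table", {
    sim <- simulatePeakLists(simConfig(nCompounds = 40, nSamples = 3,
                                       seed = 12))
    res <- suppressWarnings(runPipeline(sim$samples))
    m <- members(res$table)
    expect_false(anyDuplicated(m[, c("sample_id", "peak_idx")]) > 0)
    ## accepted partial pairs satisfy the gates post-hoc
    th <- res$thresholds
    expect_lte(th@d0, th@dmax)
})
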