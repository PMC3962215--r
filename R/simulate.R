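#' @include evaluation.R
NULL

#' Simulation parameters
#'
#' The generator's defaults are the package's documented moderate-noise
#' study conditions: 4 replicate runs of a 100-compound mixture on a
#' GCxGC configuration with a 50-min first dimension (rt1 in 300-3300 s)
#' and a ~5 s modulation (rt2 in 0.5-5.5 s); per-run linear retention-time
#' drift plus Gaussian jitter; 10% split-peak, 5% dropout and 10%
#' name-corruption rates; sparse unit-resolution spectra over m/z 50-500
#' with multiplicative log-normal intensity noise.
#'
#' @param nCompounds number of compounds in the mixture.
#' @param nSamples number of replicate runs.
#' @param rt1Range,rt2Range base retention-time ranges in seconds.
#' @param shiftModel per-sample drift model: `"constant"` (offset only),
#'   `"linear"` (offset + slope) or `"piecewise"` (two linear segments,
#'   continuous at the mid-range breakpoint).
#' @param rtJitterSd numeric(2), Gaussian jitter sd in seconds (rt1, rt2).
#' @param splitProb probability a peak is reported as 2-3 split entries.
#' @param dropoutProb probability a compound is missing from a run.
#' @param nameErrorProb probability a peak's assigned name is corrupted
#'   (blank / swapped with the nearest-rt1 compound / random string, in
#'   equal shares).
#' @param spectrumChannels fragment channels drawn per compound.
#' @param spectrumNoiseSd sdlog of the per-run multiplicative intensity
#'   noise.
#' @param mergeWindows [mergeConfig()] windows that split entries must
#'   stay within (so merging can invert the split).
#' @param seed integer RNG seed; a fixed seed makes output byte-identical.
#' @return list with class `"SimConfig"`.
#' @export
simConfig <- function(nCompounds = 100L, nSamples = 4L,
                      rt1Range = c(300, 3300), rt2Range = c(0.5, 5.5),
                      shiftModel = c("linear", "constant", "piecewise"),
                      rtJitterSd = c(0.5, 0.02),
                      splitProb = 0.1, dropoutProb = 0.05,
                      nameErrorProb = 0.1,
                      spectrumChannels = 40L, spectrumNoiseSd = 0.1,
                      mergeWindows = mergeConfig(), seed = 1L) {
    shiftModel <- match.arg(shiftModel)
    stopifnot(nCompounds >= 1, nSamples >= 1,
              diff(rt1Range) > 0, diff(rt2Range) > 0, all(rt1Range > 0),
              all(rt2Range > 0), all(rtJitterSd >= 0),
              splitProb >= 0, splitProb <= 1,
              dropoutProb >= 0, dropoutProb <= 1,
              nameErrorProb >= 0, nameErrorProb <= 1,
              spectrumChannels >= 2, spectrumNoiseSd >= 0)
    structure(list(nCompounds = as.integer(nCompounds),
                   nSamples = as.integer(nSamples),
                   rt1Range = rt1Range, rt2Range = rt2Range,
                   shiftModel = shiftModel, rtJitterSd = rtJitterSd,
                   splitProb = splitProb, dropoutProb = dropoutProb,
                   nameErrorProb = nameErrorProb,
                   spectrumChannels = as.integer(spectrumChannels),
                   spectrumNoiseSd = spectrumNoiseSd,
                   mergeWindows = mergeWindows, seed = as.integer(seed)),
              class = c("SimConfig", "list"))
}

#' Split one peak into 2-3 sub-entries
#'
#' Emulates a deconvolution artifact: the peak's area is partitioned into
#' `k` positive shares (the last share absorbing rounding so the areas sum
#' exactly) and the sub-entries' retention times are offset so that their
#' area-weighted mean equals the original retention time in both
#' dimensions, with a spread strictly inside the merge windows -- so
#' [mergeEntries()] inverts the split. Sub-entries keep the original name
#' and spectrum.
#'
#' @param row one-row data.frame with `name`, `rt1`, `rt2`, `area`.
#' @param k number of sub-entries (2 or 3).
#' @param windows a [mergeConfig()] list bounding the sub-entry spread.
#' @return data.frame of `k` rows.
#' @export
splitPeak <- function(row, k = 2L, windows = mergeConfig()) {
    stopifnot(k >= 2L, k <= 3L, nrow(row) == 1L)
    p <- stats::runif(k, 0.15, 1)
    p <- p / sum(p)
    a <- row$area * p
    a[k] <- row$area - sum(a[-k])
    off1 <- stats::runif(k, -windows$rt1Window / 3, windows$rt1Window / 3)
    off2 <- stats::runif(k, -windows$rt2Window / 3, windows$rt2Window / 3)
    off1 <- off1 - sum(p * off1)
    off2 <- off2 - sum(p * off2)
    data.frame(name = row$name, rt1 = row$rt1 + off1, rt2 = row$rt2 + off2,
               area = a, stringsAsFactors = FALSE)
}

.randomName <- function(n = 1L) {
    vapply(seq_len(n), function(i)
        paste0("Unknown_", paste(sample(c(LETTERS, 0:9), 6, TRUE),
                                 collapse = "")), "")
}

.sampleShift <- function(cfg, range1, range2) {
    mk <- function(off, slopes, rng) {
        switch(cfg$shiftModel,
            constant = { a <- stats::runif(1, -off, off)
                         function(x) x + a },
            linear = { b <- stats::runif(1, slopes[1], slopes[2])
                       a <- stats::runif(1, -off, off)
                       function(x) a + b * x },
            piecewise = {
                brk <- mean(rng)
                b1 <- stats::runif(1, slopes[1], slopes[2])
                b2 <- stats::runif(1, slopes[1], slopes[2])
                a <- stats::runif(1, -off, off)
                function(x) ifelse(x <= brk, a + b1 * x,
                                   a + b1 * brk + b2 * (x - brk))
            })
    }
    list(f1 = mk(10, c(0.98, 1.02), range1),
         f2 = mk(0.1, c(0.97, 1.03), range2))
}

#' Generate multi-sample peak lists with known ground truth
#'
#' Draws a compound library (base retention times uniform over the
#' configured ranges, names `Compound_###`, sparse spectra over m/z
#' 50-500), then renders each sample by applying its drift model and
#' jitter, dropping compounds, splitting peaks into sub-entries and
#' corrupting names at the configured rates. Every generated row is
#' recorded in the truth map.
#'
#' @param cfg a [simConfig()] list.
#' @return list with `samples` (list of [PeakList-class]), `truth`
#'   (data.frame `sample_id`, `peak_id`, `compound_id`) and `cfg`.
#' @export
simulatePeakLists <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nC <- cfg$nCompounds
    lib <- data.frame(
        compound_id = sprintf("C%03d", seq_len(nC)),
        name = sprintf("Compound_%03d", seq_len(nC)),
        rt1 = stats::runif(nC, cfg$rt1Range[1], cfg$rt1Range[2]),
        rt2 = stats::runif(nC, cfg$rt2Range[1], cfg$rt2Range[2]),
        area = exp(stats::runif(nC, log(1e4), log(1e7))),
        stringsAsFactors = FALSE)
    libSpec <- lapply(seq_len(nC), function(i) {
        ch <- sort(sample(50:500, cfg$spectrumChannels))
        MassSpectrum(ch, stats::rexp(cfg$spectrumChannels) * 999,
                     roundMz = TRUE)
    })
    samples <- vector("list", cfg$nSamples)
    truth <- list()
    for (s in seq_len(cfg$nSamples)) {
        sid <- sprintf("S%02d", s)
        shift <- .sampleShift(cfg, cfg$rt1Range, cfg$rt2Range)
        keep <- which(stats::runif(nC) >= cfg$dropoutProb)
        rows <- list(); specs <- list(); comp <- character()
        for (i in keep) {
            rt1 <- shift$f1(lib$rt1[i]) + stats::rnorm(1, 0, cfg$rtJitterSd[1])
            rt2 <- shift$f2(lib$rt2[i]) + stats::rnorm(1, 0, cfg$rtJitterSd[2])
            rt2 <- max(rt2, 0.05)
            nm <- lib$name[i]
            if (stats::runif(1) < cfg$nameErrorProb) {
                mode <- sample(3L, 1L)
                nm <- if (mode == 1L) "" else if (mode == 2L) {
                    near <- order(abs(lib$rt1 - lib$rt1[i]))
                    lib$name[setdiff(near, i)[1L]]
                } else .randomName()
            }
            area <- lib$area[i] * exp(stats::rnorm(1, 0, 0.2))
            sp <- MassSpectrum(libSpec[[i]]@mz,
                               libSpec[[i]]@intensity *
                                   exp(stats::rnorm(length(libSpec[[i]]@mz),
                                                    0, cfg$spectrumNoiseSd)),
                               roundMz = FALSE)
            base <- data.frame(name = nm, rt1 = rt1, rt2 = rt2, area = area,
                               stringsAsFactors = FALSE)
            if (stats::runif(1) < cfg$splitProb) {
                k <- sample(2:3, 1L)
                base <- splitPeak(base, k, cfg$mergeWindows)
            }
            for (r in seq_len(nrow(base))) {
                rows[[length(rows) + 1L]] <- base[r, , drop = FALSE]
                specs[[length(specs) + 1L]] <- sp
                comp <- c(comp, lib$compound_id[i])
            }
        }
        df <- do.call(rbind, rows)
        o <- order(df$rt1, df$rt2)
        df <- df[o, , drop = FALSE]
        rownames(df) <- NULL
        samples[[s]] <- PeakList(sid, df, specs[o],
                                 sourceIds = as.list(seq_len(nrow(df))))
        truth[[s]] <- data.frame(sample_id = sid,
                                 peak_id = seq_len(nrow(df)),
                                 compound_id = comp[o],
                                 stringsAsFactors = FALSE)
    }
    list(samples = samples,
         truth = do.call(rbind, truth),
         cfg = cfg)
}

#' Write a simulation to disk
#'
#' Writes each sample in the peak-list dialect (`<sample_id>.csv`) plus
#' `truth.csv`.
#' @param sim result of [simulatePeakLists()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in sim$samples)
        writePeakList(s, file.path(dir, paste0(sampleId(s), ".csv")))
    utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(dir)
}
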