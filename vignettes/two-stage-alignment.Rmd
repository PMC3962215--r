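---
title: "Two-stage landmark-based alignment of GC×GC/TOF-MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage landmark-based alignment of GC×GC/TOF-MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxgcAlign)
```

## Model and assumptions

`gcxgcAlign` aligns deconvoluted peak lists from replicate GC×GC/TOF-MS
runs. Its working assumptions are:

* each peak carries two retention times (seconds), an area, a fragment-ion
  spectrum at unit m/z resolution, and a possibly-empty compound name
  assigned by the deconvolution software's library search;
* retention-time drift between runs is smooth (approximately affine per
  run, with small random jitter on top), so that after per-sample
  z-scoring of both dimensions the same compound sits close to itself
  across runs;
* true matches have highly correlated fragment spectra, and the name
  assignments, while imperfect, are right more often than wrong.

Evidence about a candidate pair is blended by the mixture similarity
`mS = w (1 − (d/dmax)^2) + (1 − w) sim`: `d` is the Euclidean distance of
the two peaks in z-scored retention-time space, `dmax` the maximum pairwise
peak distance over all samples (so the first term is in [0, 1]), `sim` the
Pearson correlation of the spectra on their zero-filled union m/z grid, and
`w` a data-chosen weight. `mS` ranks competing candidates; the *gates* that
decide admissibility (`d0`, `sim0`) are derived from landmark peaks, which
is what removes the need for user-tuned cutoffs.

The pipeline (`runPipeline()`) is: merge split entries per sample →
z-score both RT dimensions → global `dmax` → pick a reference sample → find
landmark peaks present in every sample → optimise `w` over the fixed grid
(0.05, 0.1, 0.2, …, 0.9, 0.95) → derive `d0`, `sim0`, `mS0` by Grubbs
outlier rejection on the landmark pair statistics → align the remaining
peaks pairwise against the reference.

## Tunable parameters

Only the split-entry **merge step** takes user thresholds, because what
counts as a split entry is a property of the instrument method, not of the
data-driven matching:

* `merge.rt1Window` (default 5 s): first-dimension window; split entries
  of one compound land within roughly one modulation period of each other.
* `merge.rt2Window` (default 0.1 s): second-dimension window; the second
  column is only a few seconds long and split entries barely move in it.
* `merge.r0` (default 0.95): minimum spectrum correlation; split entries
  share one underlying spectrum, so this is deliberately strict.

The remaining knobs have safe defaults and exist mainly for analysis of
the method itself: the Grubbs significance level (`grubbsAlpha`, 0.05, the
conventional level for the test), the reference policy (`most_peaks`,
deterministic; `random` available behind the run seed), `enforceMs0`
(off: the six matching steps gate on `d0` and `sim0` only, `mS` ranks;
`mS0` is reported so users can audit it), and `rtCorrection` (off, see
below).

## Design choices where the design was open

* **Reference update during landmark search.** After each target sample is
  processed, the reference is *shrunk* to the peaks that found a partner;
  their coordinates are not touched. Updating coordinates (e.g. averaging)
  would entangle the reference with target noise and make the result
  depend on target order in a harder-to-audit way.
* **One global `w`.** The weight search could return one `w` per sample
  pair, but stage 2 needs a single parameterisation of `mS`; we maximise
  the summed score over all sample pairs and log the per-pair sums. Ties
  favour the smaller `w`, i.e. the spectrum term, which is the more
  specific evidence.
* **Grubbs variant.** The outlier test is iterative and one-sided — high
  tail for distances, low tail for similarities — because only one tail of
  each collection can harbour faulty landmark pairs. The critical value
  comes from the standard t-distribution formula; iteration stops at the
  first non-rejection.
* **Same-name candidates first.** In the pairwise matching, same-named
  candidate pairs are resolved before unnamed/different-named ones. A name
  agreement is independent evidence (it encodes the library search), so it
  outranks a marginally better `mS` from an anonymous competitor.
* **Merged-entry representative.** A merged peak's spectrum is the
  area-weighted mean of its members' spectra on the union grid and its
  name is the largest-area member's, consistent with the area-weighted
  retention-time mean; deconvolution assigns names more reliably to larger
  peaks.
* **rt2 merge window is symmetric.** Split entries can deviate in either
  direction along the short second dimension, so the window is
  `|Δrt2| ≤ rt2Window` while rt1 slides forward through the (sorted) list.
* **Retention-time correction is opt-in.** A landmark-anchored
  piecewise-linear correction of the target axes (exact at landmarks,
  linear extrapolation beyond them) is available via `rtCorrection`, but
  the matching procedure is defined entirely in z-space with data-derived
  gates and does not require it; it is off by default and clearly labelled
  as an extra.

## Numerical choices and degenerate inputs

* Standard deviations use the sample (n − 1) convention throughout.
* Spectra are compared as raw intensities; Pearson correlation is
  scale-invariant, so no normalisation is applied. A spectrum that is
  constant on the union grid has no defined correlation and is scored −1,
  so a flat spectrum can never win a match.
* m/z values are rounded to integer channels on input (unit-resolution TOF
  spectra); duplicate channels are summed.
* `dmax` is computed exactly via the convex hull of the pooled
  z-coordinates (the diameter of a point set is attained on its hull).
* Matching tie-breaks are total and documented: larger `mS`, then smaller
  `d`, then smaller reference and target index — so results are invariant
  to input row order.
* Degenerate inputs fail loudly: a sample with zero retention-time
  variance cannot be z-scored; an empty landmark set aborts the run with a
  diagnostic (no thresholds can be derived); Grubbs with n < 3 or zero
  spread returns its input unchanged with a warning; a single-sample
  "alignment" degenerates to singleton rows.
* If all landmark distances are exactly zero (an idealised noise-free
  input), `d0` would be 0 and the strict gate `d < d0` would reject
  everything; `d0` is floored at machine epsilon, which keeps exact
  coincidences admissible and nothing else.

## What the generator emulates — and what it does not

`simulatePeakLists()` draws a compound library (uniform base retention
times, sparse exponential-intensity spectra over m/z 50–500) and renders
each run with: per-sample drift (default: linear, slope within ±2% in rt1
and ±3% in rt2 plus offsets up to ±10 s / ±0.1 s), Gaussian jitter
(0.5 s / 0.02 s), 10% split entries (2–3 sub-entries whose areas sum
exactly and whose area-weighted RT mean equals the original, spread inside
the merge windows), 5% compound dropout per run, 10% name corruption
(blank, swap with the nearest-rt1 compound's name, or a novel string, in
equal shares) and multiplicative log-normal spectrum noise (sdlog 0.1).
These defaults are the package's documented moderate-noise study
conditions: 100 compounds and 4 replicate runs, sized like a typical
standard-mixture experiment, with drift, jitter and assignment-error rates
a practitioner would consider realistic for replicate runs on one
instrument. The acceptance tests run them at the default seed (1), so the
end-to-end checks are deterministic; the formula-level and oracle tests
cover many seeds.

The generator does **not** emulate chromatographic peak shapes, detector
saturation, co-elution that defeats deconvolution, electron-ionisation
fragmentation physics, or structured (non-smooth) retention-time
distortion. Passing tests on this test bed therefore demonstrate the
correctness of the algorithm and its parameter derivation under the stated
noise model, not instrument-level performance on raw data.

## Known limitations

* **Reference anchoring.** All groups are anchored to reference peaks, so
  a compound absent from the reference sample is never reported, even if
  it is present in every other sample. Choosing the largest peak list as
  reference (the default) minimises, but cannot eliminate, this loss.
* **Finite-sample thresholds.** `d0` and `sim0` are the extremes of a
  finite landmark sample; true pairs slightly outside the landmark
  envelope are rejected by the gate. With fewer landmarks the clipping
  worsens — recall varies by a few percent from seed to seed at the
  moderate-noise conditions, which mirrors the behaviour of
  threshold-from-landmark designs generally.
* **Name dependence of stage 1.** Landmarks require a shared name in every
  sample. Consistent mislabelling — a near-neighbour's name swapped in
  while the true holder's name is simultaneously corrupted — can create a
  wrong landmark group; the Grubbs step removes its (outlying) statistics
  from the threshold collections, but the group itself remains in the
  table as a false positive.
* **Pairwise, not transitive.** Peaks of two non-reference samples are
  never compared directly; a match is claimed only through the reference.
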