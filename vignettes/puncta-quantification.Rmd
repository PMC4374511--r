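---
title: "Quantifying synaptic puncta along neuronal cords"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic puncta along neuronal cords}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaquant)
```

## The measurement

Fluorescently tagged synaptic-vesicle proteins (GFP::RAB-3, SNB-1::GFP and
similar reporters) concentrate at presynaptic specializations, appearing as
discrete bright *puncta* along the dorsal and ventral nerve cords of
*C. elegans*. Mutations that disrupt vesicle trafficking redistribute the
reporter: it can become diffuse along the axon, accumulate in cell bodies,
or form abnormally large and bright puncta. The standard way to quantify
these phenotypes is a *line scan*: a 1D intensity profile sampled along the
traced cord, split into punctal fluorescence (PF, the signal inside punctum
regions) and inter-punctal fluorescence (IPF, the axonal signal between
puncta).

Two statistics per animal summarise the scan:

* **PN (puncta number)** — the count of called puncta in a 100 µm analysis
  window centred on the middle of the traced cord.
* **SE (synaptic enrichment)** — total PF / total IPF over the same window.
  SE is high when the reporter is concentrated at synapses and falls toward
  zero when it is diffuse.

A candidate peak is called a punctum when

$$\frac{\text{peak PF}}{\text{average IPF}} \ge 2,$$

with the threshold inclusive. Groups of animals (one genotype each) are
summarised as mean ± SD and compared pairwise with two-sided Student's
t-tests, labelled `**` (p < 0.01), `*` (p < 0.05) or `NS`.

## The circular definition and its fixed point

PF and IPF are mutually defining: which samples count as "between puncta"
depends on which peaks are puncta, and whether a peak is a punctum depends
on the average IPF. `call_puncta()` resolves this with a shrinking fixed
point:

1. Start from every candidate peak (`detect_candidates()`).
2. For the current punctal set, converge the punctum extents and the
   average IPF jointly: extents are computed from the current IPF estimate,
   the IPF is recomputed as the mean of unmasked samples outside all
   extents, and the two are iterated until the IPF is stable (relative
   tolerance 1e-12).
3. Drop every candidate whose peak / converged-IPF ratio falls below the
   threshold; if anything was dropped, return to step 2.

Dropping a dim punctum moves its (relatively bright) samples into the IPF,
which can only raise the baseline, so the punctal set shrinks monotonically
and the outer loop terminates in at most one pass per candidate. The inner
convergence in step 2 matters: testing retention against an IPF whose
extents have not settled can drop borderline candidates that the
self-consistent solution keeps. The test suite checks the converged set
against an exhaustive oracle that enumerates all $2^k$ candidate subsets
(for profiles with $k \le 12$ candidates) and verifies that the result is a
maximal self-consistent subset.

Degenerate inputs are handled explicitly: a fully masked profile is an
error; a profile whose extents swallow every unmasked sample sets a
`zero_ipf` flag; a window with no called puncta reports SE = 0 with a
`no_puncta` flag (a diffuse mutant still yields a finite, low SE rather
than a missing value, which keeps group statistics well defined); a profile
shorter than the window uses the whole profile and flags
`window_truncated`.

## Candidate detection choices

The peak-ratio rule is the primary filter, so detection is deliberately
permissive: all interior local maxima of unmasked runs qualify, with a
minimum topographic prominence of 0 by default. Two details are fixed by
explicit tie-break rules:

* **Plateaus** (runs of equal values with lower flanks) report their centre
  sample.
* **Minimum separation** (default 1 µm, below the 2 µm punctum spacing the
  simulator guarantees): a local maximum is suppressed when a strictly
  higher maximum — or an equally high one to its left — lies within the
  separation distance. This formulation is order-free (no dependence on
  processing sequence), which makes it directly checkable by an exhaustive
  $O(n^2)$ search, and it suppresses only sampling-noise duplicates on a
  punctum's summit.

Punctum boundaries use a half-max rule: the extent is the maximal
contiguous interval around the peak where intensity stays at or above
`avg_ipf + (peak − avg_ipf) / 2`. For a Gaussian punctum on a flat baseline
this recovers the FWHM ($2\sqrt{2\ln 2}\,\sigma \approx 2.355\sigma$).
Extents of adjacent puncta that would overlap are split at the lowest
sample between the two peaks, so punctal regions are always disjoint. The
minimum extent is one sample.

Intensities are used raw: no smoothing (a moving-average option exists but
defaults to off) and no camera-offset subtraction (exposed as
`subtract_offset`, default 0). Both the ratio rule and SE are ratios of
intensities, so they are invariant under multiplicative gain — rescaling an
image cannot change PN or SE — but *not* under additive offsets; the test
suite asserts both facts, and analyses comparing instruments with different
offsets should enable the subtraction option.

## Profile extraction from images

`extract_profile()` converts a micrograph plus a traced cord polyline into
a calibrated profile. The trace is sampled at uniform arc-length steps of
nominally one pixel (the step is adjusted to divide the trace length
evenly, so the profile span equals the trace length exactly), each point
evaluated by bilinear interpolation with 0-based pixel centres and
x = column. At every sample the reported intensity is the **maximum** over
a short scan perpendicular to the local tangent (half-width 2 px by
default): the maximum is robust to sub-pixel tracing error on a thin cord,
whereas a mean would dilute the ridge with background. Perpendicular points
that leave the image are ignored rather than zero-filled (zero-filling
would bias edge samples downward); samples with no in-bounds point at all
are flagged in the exclusion mask rather than dropped, so positions remain
uniformly spaced.

Cell bodies and other structures that must not count toward synaptic signal
are removed with `mask_regions()`; masked samples are invisible to peak
detection and excluded from every PF/IPF sum.

## The synthetic-scene generator

No public micrographs accompany this class of measurement, so the package
ships a generator that emulates the four phenotype classes the analysis
must discriminate, with ground-truth punctum tables for validation:

| preset | density (/µm) | amplitude (AU) | σ (µm) | diffuse (AU) | soma fraction |
|---|---|---|---|---|---|
| `wild_type` | 0.3 | 150 ± 15 | 0.5 | 20 | 0 |
| `diffuse_mutant` | 0 | — | — | 60 | 0 |
| `enlarged_puncta` | 0.2 | 250 ± 30 | 0.7 | 20 | 0 |
| `soma_retention` | 0.3 | 150 ± 15 | 0.5 | 20 | 0.95 |

All scenes add a camera offset of 10 AU and Poisson–Gaussian camera noise
(gain 1 AU/photon, read noise SD 2 AU; `noise_gain = 0` gives a noiseless
photon path). Punctum counts are Poisson with mean density × length;
positions are uniform with a 2 µm minimum separation by rejection sampling,
so the detector operates in its well-separated design regime; amplitudes
are normal, truncated at zero. Placement and noise draw from independent
sub-streams of the scene seed, so a punctum configuration can be reused
across noise realisations, and identical arguments give bit-identical
scenes.

The magnitudes are package choices — the underlying studies publish no
intensity scale or punctum size calibration — but they are not arbitrary:

* The *directions* of the contrasts encode the phenotypes: diffuse mutants
  have zero punctum density with the reporter redistributed into an
  elevated axonal baseline; enlarged-puncta mutants have fewer but larger
  and brighter puncta; soma-retention mutants move ~95% of the above-offset
  signal into two wide (σ = 2 µm) blobs at the cord ends, leaving the cord
  near the camera offset.
* The wild-type amplitude is set so that *every* punctum clears the ratio-2
  rule with margin. With half-max extents, roughly a quarter of each
  punctum's Gaussian mass remains in the IPF, so at crowded Poisson
  realisations the IPF baseline reaches ≈ 55 AU; requiring the −3 SD peak
  (amplitude mean − 3·15 plus the 30 AU baseline) to exceed twice that with
  ~20% headroom gives an amplitude mean of 150 AU. At 100 AU the −2 SD tail
  of puncta falls below the rule on crowded scenes and recovery degrades.
* The enlarged-puncta preset uses a *lower* density (0.2/µm) than wild
  type: packing σ = 0.7 µm puncta at 0.3/µm with the 2 µm separation floor
  lets their shoulders contaminate the IPF enough that the ratio-2 fixed
  point can collapse entirely — the preset would no longer model a
  punctate phenotype at all. Fewer-but-larger matches the biology of the
  calcium-channel and priming-factor mutants this class emulates.

2D scenes (`make_image()`) render the cord as a Gaussian ridge
(cross-section σ = 0.3 µm) along the trace, puncta as isotropic 2D
Gaussians on the trace, and soma blobs at the trace endpoints, with the
same noise model.

What the generator does **not** emulate: realistic optics (no Airy PSF, no
axial dimension), photobleaching, animal-to-animal expression variability
beyond Poisson punctum counts, autofluorescence gradients, tracing error
(traces are exact), or multi-channel colocalization. Passing tests
therefore show that the *measurement pipeline* is correct and discriminates
the designed phenotypes; they do not certify performance on real
micrographs with uncalibrated noise or imperfect traces.

## Group statistics

`compare_groups()` is the classical pooled-variance two-sided Student's
t-test by default (Welch's variant is an option), matching the field's
reporting convention; labels are a pure function of p (`**` < 0.01,
`*` < 0.05, else `NS`). No multiple-testing correction is applied —
comparisons are reported per panel against a single reference genotype, as
is conventional for this assay — so users running many contrasts should
adjust externally. Zero-variance degenerate groups are handled explicitly
(identical constants: t = 0, p = 1).

Calibration is verified two ways: the type-I error rate at α = 0.05 is
estimated by split-half resampling from a single pool of same-preset SE
values (both groups always drawn from the same sampling distribution, 1000
replicates, expected rate 0.05 ± 0.02), and p-values are compared against
a label-permutation oracle on small samples.

## Problem sizes and numerical tolerances

The validation suite runs at sizes chosen to exercise every code path while
remaining quick to execute: profiles of 30–120 µm at 0.1 µm/pixel
(300–1200 samples), 20 animals per genotype for discrimination tests
(mirroring the ">20 animals per genotype" convention), 200 profiles for
the subset-enumeration oracle (candidate count capped at 12 so $2^k$
enumeration is exact), 100 scenes for the SE direct-summation oracle
(agreement to 1e-9 relative), and 1000 resampling replicates for t-test
calibration. The IPF fixed point uses a relative convergence tolerance of
1e-12 with an iteration cap of 100 (`max_iterations`), which in practice
converges in fewer than five outer passes.

## Known limitations

* The punctum-boundary (half-max) rule is a package definition; published
  analyses do not define punctum extents, and SE magnitudes shift with the
  boundary rule even though genotype *orderings* are robust to it.
* "Average peak IPF" is read as the mean intensity of inter-punctal
  samples; alternative readings (e.g. the mean of local IPF maxima) would
  lower the effective threshold.
* PN and SE share one analysis window; whether published PN values use the
  same 100 µm window as SE is unstated in the sources this design follows.
* The pipeline is strictly 1D after extraction; puncta are not segmented as
  2D blobs, so two puncta stacked perpendicular to the cord merge.
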