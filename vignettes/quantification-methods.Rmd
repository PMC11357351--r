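---
title: "Quantification methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

This vignette explains the models behind each quantification, the
parameters that matter, the design choices made where the underlying
procedures were genuinely open, and what the synthetic generators do and
do not emulate.

## Imaging primitives

All imaging stages share a `field`: named 2D intensity rasters of
identical size (roles such as `HRAS_EGFP`, `GOLGI_RFP`, `PM_WGA`, `DONOR`,
`ACCEPTOR`, `FRET`, `DAPI`, `MHC`), an optional pixel size in micrometres,
and provenance metadata. Coordinates are row-major with the origin at the
top left; rasters read from TIFF keep their integer type, and everything
downstream of background subtraction is floating point because ratio and
FRET arithmetic needs fractional values.

**Thresholding.** The default threshold is Otsu's criterion: the level
that maximizes the between-class variance of the intensity histogram,
computed by an exhaustive scan over every observed intensity (exact at any
bit depth, no binning). When the maximizing level is followed by an empty
intensity gap — the typical case for well-separated foreground — the
reported threshold is the midpoint between that level and the next
observed one; the resulting mask is identical, but the threshold value
sits conventionally in the middle of the gap rather than at its lower
edge. A constant raster has no threshold and raises a degenerate-input
error; segmentation wrappers that can legitimately meet empty channels
(nuclei, fibers) catch it and return an empty result with a warning
instead. Manual thresholds can be supplied everywhere Otsu is the default.

**Labeling and cleanup.** Connected components default to 8-connectivity
(4-connectivity is available); hole filling runs before labeling, and
components below a minimum area are dropped, with labels kept contiguous
from 1. The minimum nucleus area defaults to 30 px at the generator's
scale — small enough to keep every simulated nucleus (radii 5–8 px, areas
≥ ~78 px), large enough to reject threshold speckle.

**Background subtraction** (`subtract_background()`) subtracts a constant
or a raster percentile and clamps at zero. Whether the original analyses
subtracted background before the ratio or FRET computations is not
something the data formats record, so the default is no subtraction, with
the operation available as an explicit pipeline step.

## HRas localization: the R_mean statistic

Each field yields one ratio: mean HRas intensity over the Golgi mask
divided by mean HRas intensity over the plasma-membrane mask. The masks
come from the marker channels only (GalT-RFP, WGA), never from the HRas
channel itself, so the statistic is unbiased by HRas redistribution.
Pixels passing both marker thresholds are removed from *both* compartments
— the alternative (assigning them to one side) double-counts signal at
Golgi/membrane apposition and the choice of side would be arbitrary. The
membrane mask is purely the WGA threshold, with no geometric ring fitting;
the unit of analysis is the field, not the cell, because cell boundaries
are not segmented anywhere in this pipeline.

`r_mean` is gain-invariant (multiplying the HRas channel by any positive
scalar leaves it unchanged) and swapping the masks yields the reciprocal —
both are tested properties. A zero membrane mean flags the result
undefined rather than erroring, so batch runs survive pathological fields;
`batch_rmean()` excludes fields whose segmentation fails and reports them.

## Sensitized-emission FRET

The three-channel acquisition (donor excitation/donor emission, acceptor
excitation/acceptor emission, donor excitation/acceptor emission) mixes
true sensitized emission with two contaminations: donor emission bleeding
into the acceptor detection band (fraction *a*) and direct excitation of
the acceptor by the donor laser (fraction *b*). Both are estimated from
single-label control cells as regression-through-origin slopes of the
transfer channel on the labeled channel, pooled over all pixels above an
intensity floor (default: 10% of the pooled maximum; below it the
regression is dominated by background). Fits outside [0, 1) are flagged,
not silently accepted.

The corrected signal per pixel is nF = I_FRET − a·I_donor − b·I_acceptor,
clamped below at zero — negative sensitized emission is detector noise.
The index divides nF by the acceptor intensity *pixelwise* and averages,
matching the index-image output of plugin-style implementations; the
ratio-of-means alternative (`normalization = "ratio_of_means"`) is a
config switch and both are tested. Pixels are analyzed only inside a cell
mask (default: Otsu on the donor channel with a 50 px area floor) and only
where the acceptor reaches a floor (default: the 95th percentile of the
acceptor signal *outside* the cell mask, i.e. a cell-free background
estimate), which keeps the division stable.

Clamping has one consequence worth stating: at zero true FRET the clamped
index has a positive bias of roughly sd(nF)/(√(2π)·I_acceptor) per pixel.
Under read-noise-dominated acquisition that bias scales like 1/(2.5·SNR)
and a zero-FRET control cannot read below ~0.01 until SNR exceeds ~40. The
generator's default regime is therefore shot-noise-limited confocal
detection (donor ≈ 1500, acceptor ≈ 2000 expected counts, read noise
sd 10), where the bias is ~0.005 and zero-FRET controls test clean. The
fraction of clamped pixels is reported on every result so saturation of
this rule is visible.

## Myotube fusion and nuclear area

Nuclei: DAPI → Otsu → fill holes → area floor → optional
distance-transform watershed (`split_touching = TRUE`) for touching
nuclei, with the watershed `tolerance` controlling how deep a saddle must
be to split. Fibers: MHC → Otsu → area floor (default 200 px; a fiber is
much larger than a nucleus). A nucleus counts as fused when the pixel
under its centroid carries a positive fiber label. The centroid rule is
deterministic and insensitive to partial rim overlap; a nucleus whose body
touches a fiber but whose centroid is outside counts as *not* fused, a
documented and tested edge case. An area-overlap ≥ 50% alternative
(`rule = "overlap50"`) is selectable. The fusion index is undefined (not
zero) on a field with no nuclei; a field with no fibers gives 0%.

Nuclear areas convert to µm² through the field's pixel size; without one
they stay in pixels, labeled as such.

## Bench quantifications

**ΔΔCt.** Per sample ΔCt = Ct(gene) − Ct(reference); ΔCt values are
averaged within a condition *first*, then differenced against the control
condition and exponentiated (fold = 2^(−ΔΔCt)) — the standard
relative-quantification order of operations. The control's own fold is
exactly 1 by construction. Per-sample ΔCt mode covers designs with no
vehicle control (animal tissue). No amplification-efficiency correction
beyond the 2-fold-per-cycle assumption is applied.

**Doubling time** is 1/slope of the OLS fit of log2(count/count₀) on
time. The t = 0 point anchors the normalization but the intercept is free.
A non-positive slope is reported as a non-growing flag with `NA` hours —
never as a negative or infinite number.

**MRM quantitation.** The standard curve is an *unweighted* OLS line of
peak area on nominal concentration — weighted fits would improve
low-concentration accuracy but the plain line is what the upstream
procedure specifies, so accuracy at the curve bottom depends on replicate
standards (the generator supports them by repeating concentrations).
Back-calculated concentrations below zero clamp to 0 with a `below_curve`
flag; areas above the top standard warn (or fail, by option). Mass
conversion uses MW = 316.43 g/mol (C20H28O3, consistent with the [M−H]⁻
precursor at m/z 315.100), overridable. Because the extraction
concentrates 1.35 mL of conditioned medium into a 100 µL resuspension,
concentrations are reported at both volumes, clearly labeled, and per-cell
masses in femtograms. MRM transitions ride along as metadata; chromatogram
peak integration is upstream of this package.

**Statistics.** Student *t*-tests are the classical pooled-variance
(unpaired) or difference-score (paired) forms; zero-variance inputs are
flagged degenerate rather than producing spurious p-values. Dunnett's
many-to-one comparisons pool the variance across all groups and adjust
family-wise by Monte-Carlo sampling of the null max-|T| distribution with
a shared control variate and pooled chi-square scale — this captures the
comparisons' correlation exactly and is verified in the tests against
both a brute-force simulation with an independent seed and the
multivariate-integration implementation in `multcomp`. The Monte-Carlo
draw order (scale, control, then treatments) makes results for the first
k comparisons reproducible when comparisons are added, and adjusted
p-values are floored at the unadjusted p, which Dunnett's procedure
guarantees analytically.

## What the generators emulate — and what they do not

Images carry Poisson shot noise on expected counts plus additive Gaussian
read noise, clamped at zero; SNR is defined as (signal mean − background
mean)/background sd and recorded in each ground-truth sidecar. Counts use
mean-one lognormal multiplicative noise; peak areas and absorbances use
relative Gaussian noise. All randomness flows from one explicit seed per
call — identical seed and parameters give bit-identical outputs.

The localization generator draws 6 elliptical cells per 192×192 field,
membrane annuli 3–4 px thick, Golgi blobs of radius 6–8 px (roughly 900
Golgi pixels per field — enough that the ground-truth-mask ratio estimate
stays within ~1% at SNR 10), cytosol at 10% of membrane intensity. The
myotube generator lays horizontal fiber stripes and places exactly
round(fused_fraction · n) nucleus centers inside them, margins included,
so the noise-free fusion index is exact by construction. The FRET
generator produces single-label calibration fields and double-label
experimental fields obeying the linear mixing model exactly before noise.

None of this is photorealistic: there is no point-spread function, no
flat-field or chromatic aberration, no 3D structure, no cell-to-cell
expression variability beyond what the noise models give. Passing the
recovery tests therefore shows the *computations* are correct and robust
to instrument-like noise — it does not certify segmentation performance
on real micrographs, where touching cells, uneven illumination and
autofluorescence dominate.

One emulated dataset deserves a note: the released-lipid comparison. The
per-condition 15d-PGJ2 table is simulated with both conditions inside the
calibrated 100–500 nM range (quiescent 100 nM from 2.4×10⁶ cells,
senescent 450 nM from 2.7×10⁵ cells — arrested cultures are sparse), so
the 40-fold per-cell difference splits into a 4.5-fold concentration
ratio times an 8.9-fold cell-count ratio. An earlier design that put the
quiescent sample at 10 nM — a 10-fold extrapolation below the lowest
standard — made the fold estimate diverge under intercept noise, which is
exactly the failure mode an unweighted curve has at the bottom of its
range; keeping samples in range is the honest fix, not a smaller noise
setting.

## Problem sizes and numerical conventions

The test and reproduction runs use 192×192 localization fields (20 seeds
per ratio level), 96×96 FRET fields (10 calibration + 10 experimental per
set), 256×256 myotube fields (20 seeds), 100 growth-curve replicates, and
10⁵ Monte-Carlo draws for Dunnett adjustment — sizes at which every
recovery criterion is comfortably resolved by the available statistical
power. Ties in the Otsu scan take the first maximizer; label order is
raster order; centroids are means of 1-based pixel indices rounded to the
nearest pixel for the fusion rule. Degenerate inputs (constant rasters,
empty masks, zero variance, non-growing counts, unusable curves) each
have a defined, tested behavior — a typed error where the input is a
configuration mistake, a flagged result where nature could genuinely
produce it.

## Known limitations

Per-cell localization analysis is out of scope (no cell segmentation);
FRET supports only the two-coefficient sensitized-emission correction (no
spectral unmixing, no acceptor photobleaching or lifetime methods); the
fusion readout does not measure myotube morphology; qPCR assumes perfect
doubling efficiency; and the MRM stage starts from integrated peak areas,
not chromatograms.
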