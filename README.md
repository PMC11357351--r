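# myoquant

Quantification toolkit for senescence and myoblast-differentiation imaging
and bench assays, built for studies of how senescent cells — and the
electrophilic lipid 15d-PGJ2 they secrete — alter HRas signalling and
muscle-cell differentiation. It is aimed at cell biologists who have
multi-channel confocal micrographs (HRas localization, sensitized-emission
FRET, DAPI/MHC myotube stains) and the usual bench tables (qPCR Ct values,
cell counts, LC-MS/MS peak areas, MTT absorbances) and want every number in
the figures to come from tested, scriptable code.

## What it computes

**HRas localization (R_mean).** Golgi and plasma-membrane masks are
segmented from a GalT-RFP marker and a WGA membrane stain (Otsu threshold,
overlap pixels discarded from both compartments), and the statistic

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>mean</sub> = mean(*I*<sub>HRas</sub> | Golgi) / mean(*I*<sub>HRas</sub> | membrane)

is reported per field, with per-condition summaries, percent change versus
control, and a two-tailed Student *t*-test.

**Sensitized-emission FRET.** Bleed-through fractions *a* (donor into the
transfer channel) and *b* (acceptor direct excitation) are fitted as
regression-through-origin slopes on single-label control cells. Per pixel,

&nbsp;&nbsp;&nbsp;&nbsp;*nF* = *I*<sub>FRET</sub> − *a·I*<sub>donor</sub> − *b·I*<sub>acceptor</sub>,

clamped at zero, then divided by *I*<sub>acceptor</sub>; the mean over
analyzed pixels is the acceptor-normalized FRET index, compared pre/post
treatment by a paired *t*-test.

**Myotube fusion index.** Nuclei are segmented from DAPI (Otsu, hole fill,
area floor, optional distance-transform watershed for touching nuclei),
fibers from the MHC immunostain; the fusion index is the percentage of
nuclei whose centroid lies on an MHC-positive fiber, with nuclei-per-fiber
counts and nuclear-area statistics (a senescence readout) alongside.

**Bench quantifications.** ΔΔCt relative expression (fold = 2^(−ΔΔCt)
against a reference gene and control condition, or per-sample ΔCt),
doubling time as the reciprocal slope of log2(normalized count) vs time,
MRM standard-curve quantitation of 15d-PGJ2 (100–500 nM standards,
transition 315.100→271.100) with per-cell mass conversion, MTT viability,
pooled-variance Student *t*-tests, and Dunnett many-to-one comparisons with
Monte-Carlo family-wise adjustment.

**Synthetic data.** Every input has a seeded generator with a ground-truth
sidecar (`sim_localization_field()`, `sim_fret_set()`,
`sim_myotube_field()`, `sim_growth_curve()`, `sim_ct_table()`,
`sim_mrm_run()`, `sim_mtt_plate()`), so the whole pipeline can be exercised
and scored against known truth.

## Worked example

```r
library(myoquant)

# a synthetic field whose true Golgi:membrane HRas ratio is 0.8
sim   <- sim_localization_field(g = 0.8, snr = 10, seed = 1)
masks <- segment_compartments(sim$field)
compute_rmean(sim$field, masks, field_id = "demo")
#> # A tibble: 1 × 7
#>   field_id mean_golgi mean_membrane r_mean n_golgi_px n_membrane_px undefined
#>   <chr>         <dbl>         <dbl>  <dbl>      <int>         <int> <lgl>
#> 1 demo           160.          200.  0.799        861          1034 FALSE
```

The recovered `r_mean` of 0.799 is the marker-guided estimate of the true
ratio 0.8: HRas is ~20% depleted at the Golgi relative to the membrane.

```r
mt <- sim_myotube_field(n_nuclei = 40, fused_fraction = 0.6, seed = 2)
res <- fusion_index(segment_nuclei(mt$field), segment_fibers(mt$field))
glance(res)
#> # A tibble: 1 × 4
#>   n_total n_in_fiber fusion_index_pct undefined
#>     <int>      <int>            <dbl> <lgl>
#> 1      40         24               60 FALSE

gr <- sim_growth_curve(doubling_time_hr = 14, cv = 0.05, seed = 3)
doubling_time(gr$data)
#> # A tibble: 1 × 4
#>    slope doubling_time_hr r_squared non_growing
#>    <dbl>            <dbl>     <dbl> <lgl>
#> 1 0.0714             14.0     1.000 FALSE
```

24 of 40 nuclei sit on MHC-positive fibers (fusion index 60%, exactly the
constructed fraction), and the growth fit recovers the 14 h doubling time
from four noisy counts. Reproducible batch runs over directories of TIFFs
and CSVs go through `run_pipeline()` with a YAML config; each run writes
its outputs plus a `manifest.json` of parameters, seed and record counts.

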