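# contourIOV

Interobserver variation (IOV) analysis for multi-observer tumour
delineations on a shared planning-CT voxel grid.

When several experts contour the same gross tumour volume (GTV) — for
example in locally recurrent rectal cancer, where tumour blends into
post-surgical fibrosis — their contours disagree, and that disagreement
propagates straight into radiotherapy target volumes. contourIOV is for
researchers running delineation studies who need to quantify that
disagreement per case and per observer group, and to test whether an
intervention (such as exposing radiation oncologists to a radiology
consensus contour) changes it.

## What it computes

For observer groups `RAD` (radiologists), `GTV-` and `GTV+` (radiation
oncologists without / with radiology input), per case:

* **Consensus contours** — the *median* (strict-majority) contour, voxel
  included iff > 50 % of the group marked it (with 8 observers, 4/8 is out,
  5/8 is in), and the *union* contour.
* **Agreement metrics** of each observer against their own group's median:
  * DSC = 2|A∩B| / (|A|+|B|) (volumetric overlap),
  * SDSC = area fraction of both surfaces within a 3 mm tolerance of each
    other (surface Dice),
  * HD98 = 98th percentile of directed nearest-surface distances (robust
    Hausdorff), in mm,
  * MDA = mean distance to agreement ± SD, in mm.
* **Categories** — little / average / large variation (DSC/SDSC cut at
  0.6 and 0.8; HD98 at 10 and 20 mm) and per-metric relevance of the
  GTV+ − GTV− median difference (thresholds ±0.1 and ±3 mm).
* **Group comparisons** — two-sided Mann-Whitney U tests on per-contour
  pooled metrics: overall, per recurrence subtype (overlapping case groups
  supported), and excluding cases with large radiologist variation.

A synthetic study generator (phantom lesions + simulated observers with
controllable boundary noise, systematic volume bias, and secondary-lesion
misses) makes the whole pipeline testable without clinical data.

## Worked example

```r
library(contourIOV)

# simulate the default study: 14 cases, 8 RAD + 6 GTV- + 6 GTV+ observers,
# with the GTV+ arm modelled at half the GTV- boundary noise
cases  <- simulate_study(default_study_spec(master_seed = 1))
report <- run_pipeline(cases)
report
#> iov_report: 14 cases, 280 contours
#>
#> Pooled GTV- vs GTV+ comparison:
#>  metric n_1  median_1 n_2  median_2 difference  difference_category            p
#>    SDSC  84 0.7122066  84 0.9234716  0.2112650 relevant improvement 8.146267e-25
#>     DSC  84 0.6545695  84 0.8270640  0.1724946 relevant improvement 3.586851e-23
#>    HD98  84 8.6573192  84 4.1532029 -4.5041163 relevant improvement 3.897253e-21
```

Read: the radiology-aided arm's 84 pooled contours agree better with their
group median on every metric — median surface Dice 0.92 vs 0.71, median
HD98 4.2 mm vs 8.7 mm — and each difference exceeds its relevance threshold
and is significant under the rank-sum test. `report$case_table` holds the
per-case medians, categories and consistency labels;
`report$subtype_table` the per-morphology comparison; `write_report(report,
dir)` exports CSV tables plus a JSON summary.

Single pairs work too:

```r
g <- voxel_grid(c(64, 64, 32), spacing = c(1, 1, 3))
pair_metrics(observer_mask, reference_mask, tolerance_config())
#>     dsc  sdsc  hd98 mda_mean mda_sd observer_volume reference_volume
```

Masks travel as NIfTI (`read_mask_nifti()` / `write_mask_nifti()`), planar
contours as JSON polygon sets rasterized by the even-odd rule
(`read_structure_set()`). A thin command-line front end with `simulate`,
`consensus`, `metrics` and `analyze` subcommands lives at
`inst/cli/contouriov.R`.

See the vignette (`vignettes/interobserver-contour-agreement.Rmd`) for the
model, conventions (percentile interpolation, strict thresholds, surface
representation) and the generator's assumptions.

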