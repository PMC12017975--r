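---
title: "Quantifying interobserver variation in target volume delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interobserver variation in target volume delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When several experts delineate the same gross tumour volume (GTV) on a
planning CT, their contours disagree — interobserver variation (IOV). In
radiotherapy for locally recurrent rectal cancer this disagreement is large
enough to matter clinically: recurrences grow into fibrotic, post-surgical
anatomy where the tumour boundary is genuinely ambiguous, and different
specialties (radiologists versus radiation oncologists) read that anatomy
differently. contourIOV quantifies such disagreement and tests whether an
intervention — for example giving radiation oncologists access to a
radiology consensus contour — changes it.

The package analyses studies with the following shape: a set of cases, each
delineated by a radiologist group (`RAD`) and two radiation-oncologist arms
(`GTV-`, contouring unaided, and `GTV+`, contouring with the radiology
consensus available), all on one shared axis-aligned voxel grid.

## Consensus contours

Per group and case the package builds:

* the **median (majority) contour**: a voxel belongs iff *strictly more*
  than 50 % of the group's observers marked it. The strict inequality
  matters with even group sizes: with 8 observers, 4 votes are not enough,
  5 are. A majority contour can be legitimately empty for highly discordant
  observers; this raises a warning, and any metric evaluated against an
  empty reference raises an error rather than silently producing NaN.
* the **union (total) contour**: every voxel marked by at least one
  observer.

Each observer is evaluated against the majority contour of *their own*
group. The observer's own contour participates in the vote it is compared
against (leave-one-in). A leave-one-out variant
(`reference_rule = "majority_loo"`) is available; we make no claim that it
matches any published workflow, and it is not the default.

## Agreement metrics

For an observer mask $A$ and reference mask $B$ on a shared grid:

* **DSC** $= 2|A \cap B| / (|A| + |B|)$, on voxel counts. Volume-based;
  heavily influenced by absolute volume, which is why a group with
  systematically smaller volumes scores lower DSC even when its boundaries
  agree well.
* **SDSC** (surface Dice at tolerance $\tau$): the area fraction of the two
  boundary surfaces lying within $\tau$ of the other surface,
  $\big(a_{A\to B}(\tau) + a_{B\to A}(\tau)\big) / (a_A + a_B)$,
  area-weighted. Default $\tau = 3$ mm. Distances exactly at the tolerance
  count as agreeing ($\le$).
* **HD98**: the 98th percentile of all smallest distances from each surface
  element of the observer's contour to the reference surface — a
  outlier-robust variant of the directed Hausdorff maximum. Directed
  observer → reference by definition; a symmetric variant (max of both
  directions) sits behind a flag. At percentile 100 it equals the directed
  Hausdorff distance.
* **MDA**: mean of those same nearest-surface distances, reported with a
  population SD (divisor $n$; the convention is stated in the report
  metadata).

### Surface representation and numerical choices

Surfaces are sets of voxel *boundary faces* (face centres + areas), not
marching-cubes meshes: every face separating a foreground voxel from a
background voxel or the grid exterior contributes one element, with area
equal to the product of the two in-plane spacings (so anisotropic grids are
handled exactly). This choice keeps the surface definition consistent with
the voxel-defined majority contour and makes the brute-force test oracle
exact. Distances are Euclidean distances between face centres, found with an
exact kd-tree search — no distance-map discretization error, but
face-centre-to-face-centre measurement introduces up to half a voxel of
bias relative to true point-to-surface distance; implementation and test
oracles share the convention.

Percentiles (HD98, quartiles in summaries) use linear interpolation between
order statistics (R's default type 7). Oblique or rotated grids are rejected
at load time: the analysis assumes all contours of a case live on one
axis-aligned planning-CT lattice, and silently resampling would hide a data
problem.

Degenerate inputs are errors, not NaNs: Dice of two empty masks, any
surface metric involving an empty mask, an empty consensus reference, and
observer sets on mismatched grids all raise.

## Categories, relevance and group comparison

To make metric tables readable, each value is categorized:

| metric | little | average | large |
|---|---|---|---|
| DSC / SDSC | ≥ 0.8 | 0.6 ≤ v < 0.8 | < 0.6 |
| HD98 | < 10 mm | 10 ≤ v < 20 mm | ≥ 20 mm |

Between the two RO arms the package reports the signed median difference
(GTV+ − GTV−) per metric. A change is *relevant* only if its magnitude
strictly exceeds 0.1 (DSC/SDSC) or 3 mm (HD98); the threshold itself is not
relevant (exclusive comparison — the tie semantics are not otherwise
defined, so we fix and document them). Improvement direction is encoded once
per metric centrally (`higher is better` for DSC/SDSC, `lower is better`
for HD98) to prevent sign errors. A case shows *consistent* improvement
(or deterioration) only when all three metrics do.

Group comparisons use the two-sided Mann-Whitney U test with midranks for
ties: exact whenever the samples are tie-free and both smaller than 50,
otherwise the normal approximation with tie and continuity corrections.
Significance is flagged at α = 0.05; raw p-values are always reported and no
multiple-testing correction is applied (the analysis is descriptive, with
one pre-specified primary comparison per metric). Pooling is per contour:
every returned delineation contributes one value per metric.

Three comparison layers mirror the study design: a **pooled** GTV− versus
GTV+ comparison over all cases; a **sensitivity re-analysis** excluding
cases whose radiologist group shows large variation on all three metrics
(configurable to any-metric); and a **subtype** analysis restricted to
(possibly overlapping) recurrence-morphology case groups — a multifocal,
fibrotic case legitimately contributes to both subtypes.

## The synthetic study generator

No clinical delineations ship with the package, so the generator produces
studies with the same statistical structure, with every true parameter
known:

* **Phantoms**: spheres, ellipsoids, irregular blobs (a sphere whose
  boundary is deformed by a smoothed random field, largest connected
  component kept), and two-lesion phantoms (a primary plus a smaller
  disjoint secondary sphere). The default grid is 72 × 72 × 36 voxels at
  1 × 1 × 3 mm, mirroring a typical planning-CT slice thickness of 3 mm.
* **Observers**: a delineation is the truth's signed distance function
  thresholded after perturbation — voxel included iff
  $\mathrm{sdf} - m + s\,F \le 0$, where $m$ is a signed systematic margin
  in mm (negative erodes: a group that consistently contours smaller), $s$
  the boundary-noise SD in mm and $F$ a unit-variance Gaussian random field
  smoothed to a 5 mm correlation length. The smoothing produces spatially
  coherent over- and under-contouring like a human observer, not
  salt-and-pepper voxels; the field is winsorized at ±3 SD because real
  boundary misplacement is bounded. A systematic translation is applied as
  the nearest voxel-aligned shift. When the truth has a secondary lesion,
  the observer includes it with a group-specific probability — emulating
  lesions that some observers call tumour and others call benign.
* **Seeds**: every draw uses a child seed derived from the master seed via
  repeated Lehmer steps keyed by (case index, group code, observer index),
  so the whole study is a pure function of its spec and any single observer
  is regenerable in isolation. If a draw's perturbation would swallow the
  entire lesion (possible for strong erosion plus noise on a small
  phantom), the generator redraws with a deterministically derived retry
  seed: an observer never returns an empty contour.

### Default study conditions

`default_study_spec()` encodes the study structure the analysis is designed
for: 14 cases, 8 RAD + 6 GTV− + 6 GTV+ observers (280 contours). The five
overlapping subtype memberships (`lrrc_subtypes()`) drive the phantom
morphologies: multifocal cases are two-lesion phantoms, fibrotic cases
blobs, solitary-node cases small (r = 8 mm) spheres, the rest ellipsoids or
spheres of 11–16 mm. Group behaviour: RAD noise 3 mm with a −3 mm margin
(systematically smaller radiologist volumes) and secondary-lesion inclusion
0.5; GTV− noise 4 mm, inclusion 0.9; GTV+ noise 2 mm — half the unaided
arm, which is how the higher concordance of the radiology-aided arm is
injected — inclusion 0.7. These values were fixed once as plausible desk-
scale analogues of clinical behaviour. At these defaults the pooled RO mean
distance to agreement is ≈ 2.2 mm; clinical studies report larger MDAs on
larger, more complex lesions, and we deliberately did not inflate the noise
to chase such values because it would push SDSC far below any plausible
clinical range at phantom scale.

### What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes — groups with
different concordance, volume bias, secondary-lesion misses, overlapping
subtypes — not clinical realism: phantoms are smooth and convex-ish,
observer errors are radially unbiased apart from the margin, and the
radiology-exposure effect is injected directly as a concordance parameter
rather than modelled. Green tests therefore certify that the pipeline
measures, categorizes and compares correctly, and that it detects a known
injected difference in the expected direction; they are not a reproduction
of any clinical study's metric values.

## Problem sizes and runtime

Test and example sizes were chosen so a full run stays comfortably
interactive: oracle-equivalence tests run on ≤ 20³ grids (where the O(n²)
brute force is exact and fast), analytic sphere tests on ≈ 60³ 1 mm grids,
and the end-to-end discrimination check on the full 14-case default study
(≈ 45 s). The complete test suite runs in about a minute.

## Worked example

```{r, eval = FALSE}
library(contourIOV)

cases <- simulate_study(default_study_spec(master_seed = 1))
report <- run_pipeline(cases)
report
#> iov_report: 14 cases, 280 contours
#>
#> Pooled GTV- vs GTV+ comparison:
#>  metric n_1  median_1 n_2  median_2 difference  difference_category            p
#>    SDSC  84 0.7122066  84 0.9234716  0.2112650 relevant improvement 8.146267e-25
#>     DSC  84 0.6545695  84 0.8270640  0.1724946 relevant improvement 3.586851e-23
#>    HD98  84 8.6573192  84 4.1532029 -4.5041163 relevant improvement 3.897253e-21

# per-case Fig-1-style table, subtype analysis, CSV/JSON export
head(report$case_table)
report$subtype_table
write_report(report, "iov_report")
```

The GTV+ arm (half the boundary noise) scores higher SDSC and DSC and lower
HD98, and the pooled rank-sum comparison flags all three as significant —
the direction of effect the pipeline is built to detect.

## Known limitations

* Only axis-aligned shared grids; no registration, resampling or oblique
  orientations.
* Surface distances are face-centre based (≤ half-voxel bias); HD98 and
  SDSC conventions of commercial treatment-planning systems may differ in
  percentile convention and surface model, so absolute values are
  comparable within this package, not across tools.
* DICOM RT-STRUCT is not parsed; planar contours are accepted via a
  documented JSON format and rasterized with the even-odd rule (voxel
  centres on an edge count as inside).
* The leave-one-in consensus reference slightly favours each observer
  (their vote is in the reference); the leave-one-out option quantifies
  that choice but neither is claimed to match unpublished clinical
  workflows.
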