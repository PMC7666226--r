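---
title: "Quantifying immunofluorescence in midbrain organoid sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunofluorescence in midbrain organoid sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidIF)
```

## The measurement problem

Midbrain organoids (MOs) are 3D neural cultures differentiated from
induced pluripotent stem cells; they contain dopaminergic neurons
(marked by tyrosine hydroxylase, TH), astrocytes (GFAP, S100B) and a
general neuronal population (Tuj1). Comparing organoids from patients
carrying *PRKN* mutations against controls requires turning
multi-channel confocal stacks of 50 um vibratome sections into a small
number of per-section features that can be compared across groups:

| feature | meaning |
|---|---|
| `nuclear_pixels` | sum of Hoechst-positive voxels (tissue quantity, QC) |
| `n_cells` | nuclei surviving segmentation and the size filter |
| `gfap_percentage`, `s100b_percentage` | % of cells positive for the marker |
| `tuj1_pixels` | sum of Tuj1-positive voxels |
| `th_fragmentation` | surface-to-volume ratio of the TH mask |

This package implements that pipeline end to end, together with a
synthetic section renderer with full ground truth, so that every stage
is verifiable without access to raw microscope data.

## Pipeline stages and their parameters

**Axis convention.** Volumes are indexed `(z, y, x, channel)`, 1-based
as is natural in R. Physical voxel spacing in micrometres is carried as
metadata, but every pixel-count feature and threshold is expressed in
voxels of the analysed volume: the bounds the pipeline enforces
(10,000-voxel nuclei, 5,000-voxel Hoechst sums) are counts, not
calibrated areas.

**Nuclei.** The Hoechst channel is smoothed with a separable Gaussian
(default sigma 2 voxels in-plane, scaled by the voxel anisotropy along
z so the physical smoothing scale is isotropic), thresholded (Otsu by
default), and partitioned by a seeded watershed: seeds are local maxima
of the Euclidean distance transform of the foreground (plateaus merged,
seeds closer than `min_seed_distance_vox = 5` suppressed keeping the
deeper one), and regions grow by priority flooding on the distance
transform. Nuclei larger than 10,000 voxels are then removed — the
bound is strict (*greater than* 10,000 is removed; exactly 10,000 is
kept), because oversized "nuclei" in dense tissue are almost always
under-split clumps. The filter runs after the watershed, so a clump the
watershed did manage to split is kept as its pieces.

**Marker masks.** TH, GFAP, S100B, Tuj1 (and Hoechst, for the QC sum)
all pass through one operator: a 3D median filter (default 3x3x3, the
smallest denoising window) followed by thresholding
(`mask = filtered >= threshold`). Otsu is the parameter-free default;
each channel can override the window and threshold. One caveat is
documented and tested rather than hidden: per-section Otsu assumes both
an intensity background and a foreground class are present. On a
section in which a marker is genuinely absent, Otsu will split the
noise distribution and fabricate foreground. Cohort analyses in this
package therefore fix the marker threshold (the analysis scripts use
the mid-contrast value 550 for the simulated cohorts, the midpoint of
the renderer's background/foreground intensities; with real data the
value would be calibrated on control sections).

**Perinuclear positivity.** For each retained nucleus the perinuclear
zone is the set of background voxels within Euclidean distance
`ring_width_vox = 2` of that nucleus, excluding all nucleus voxels;
contested voxels go to the nearer nucleus, exact ties to the lower
label. A cell is positive for a marker when the marker mask covers at
least 1% of its zone — inclusively, so exactly 1% is positive. Cells
whose zone has zero area (fully enclosed by neighbours) cannot be
classified; they are excluded from numerator *and* denominator and
reported, never silently counted negative. The ring width of 2 voxels
is the minimal reading of "perinuclear": a thin shell adjacent to the
nuclear envelope; it is configurable.

**Fragmentation.** The TH fragmentation index is
`surface(mask) / volume(mask)`, where surface voxels are those removed
by one binary erosion. The default structuring element is the
6-connected cross, which yields the conventional voxel surface; the
26-connected cube is available. Voxels on the volume border count as
surface. For a solid a x b x c cuboid under 6-connectivity the index
has the closed form `1 - (a-2)(b-2)(c-2)/(abc)` (0.488 for a 10-cube),
which the tests exploit; a single voxel scores 1, and an empty mask is
flagged undefined rather than scored.

**QC and statistics.** Sections whose Hoechst pixel sum is strictly
below 5,000 are removed before analysis. The default unit of analysis
is the section (each passed section one data point); organoid means are
available as an alternative, since both readings of "a section is a
data point and was averaged" are defensible — the reported per-group
section counts favour the per-section reading, so that is the default,
and the analysis scripts emit both. Groups are compared per feature
with a two-sided Mann-Whitney test: exact (from the null permutation
distribution of U) for small tie-free samples (`n_a * n_b <= 400`),
otherwise a normal approximation with tie and continuity correction;
the method used is recorded in the result. No multiple-testing
correction is applied by default, matching the per-feature testing
convention; Bonferroni is available.

## What the synthetic renderer emulates

`scene_spec()` defaults describe one field of a 50 um section: 24
z-planes at 2 um spacing (48 um of depth), a 96 um field sampled at
0.6 um in-plane, and 20 non-overlapping ellipsoidal nuclei of ~8.4 um
diameter (in-plane semi-axis 7 voxels, z semi-axis scaled by the
anisotropy). Marker positivity is rendered as a perinuclear intensity
shell, not a whole-cell fill, because the classifier under test reads
the perinuclear area — ground truth must be expressible in the
classifier's own terms. Neurites are straight tubes of radius 4 voxels;
a fragmentation level of `b` splits each tube into `b + 1` pieces. The
capsule ends of each piece are inset by two-thirds of the radius, which
makes each piece's continuum volume exactly `pi r^2 x block length`:
the fragment series holds total volume fixed while adding surface, so
the fragmentation index has a controlled, monotone ground truth. The
tube radius is deliberately thick enough (the index sits near 0.4) that
fragmentation changes are resolvable; tubes thinner than the median
window saturate the index near 1, where voxelisation noise swamps the
signal. Noise is additive Gaussian (default sd 45, i.e. 5% of the
900-unit contrast) with optional Poisson shot noise; a single optional
Gaussian blur stands in for the PSF.

What it does **not** emulate: realistic PSF anisotropy, photobleaching,
spectral bleed-through, intensity gradients with depth, non-ellipsoidal
or touching nuclei (watershed splitting is exercised by purpose-built
touching-sphere fixtures instead), curved or branching neurites, and
autofluorescent debris. Passing the recovery tests therefore shows the
pipeline is *correct under its own model*, not that it is robust to
every artefact of real acquisitions.

## Numerical choices

* Median filter, Gaussian kernel, erosion and distance transform use
  whole-sample symmetric (reflect) boundaries; erosion treats space
  outside the volume as background so border voxels are surface.
* The Gaussian kernel is sampled and truncated at 3 sigma, then
  normalised, so constants are preserved exactly.
* The Euclidean distance transform is exact (per-axis lower-envelope
  algorithm), not a chamfer approximation.
* Watershed flooding is deterministic: priority ties are broken FIFO.
* Otsu uses 256 histogram bins and returns the upper edge of the
  selected bin; a constant channel yields an empty mask.
* Zone contests are resolved by exact squared-distance comparison;
  ties go to the lower label, so results are permutation-stable.
* Degenerate inputs are flagged, not guessed: `percent_positive` with
  zero cells and `th_fragmentation` of an empty mask return `NA`.

## Problem sizes

Desk-scale defaults keep every simulation fast while leaving the
geometry non-trivial: full-size scenes (24 x 160 x 160, all five
channels) render and analyse in about two seconds; the replicate-heavy
checks (noise sweeps, the 100-cohort power handshake) use reduced
fields (10 x 64 x 64, 12 nuclei, the marker of interest only) so the
whole suite runs in a few minutes. The two-line cohort analysed by the
`analysis/` scripts is 2 lines x 3 organoids x 3 sections.

## Known limitations

* Per-section Otsu on empty channels fabricates foreground (see
  above); fixed thresholds are the supported cohort configuration.
* The 10,000-voxel bound is applied to 3D voxel counts; if the
  original bound referred to 2D plane pixels the numeric value of the
  cut-off would need rescaling, though its strict semantics would not
  change.
* Whether foreground thresholding should precede or follow watershed
  seeding is not uniquely determined by the method description;
  thresholding-first is implemented and recorded in the provenance of
  every label map.
* Positivity is computed in 3D; a maximum-intensity-projection variant
  is not offered.
* The renderer's placement is rejection sampling with bounded retries:
  a spec that cannot be placed errors out rather than silently
  under-filling the field.

## A worked example

```{r example, eval = FALSE}
library(organoidIF)

# one clean section with known truth
sc <- render_scene(scene_spec(noise_sd = 0, seed = 11))
rec <- section_record("H_org1", "H", 1L, sc$stack)
extract_section_features(rec)
#> <section_features> H_org1/H s1: 20 cells, GFAP 45%, S100B 20%, Tuj1
#> 6023 px, TH frag 0.3414961, Hoechst 8082 px
length(sc$truth$positive_cells$GFAP)  # 9 of 20 -> 45%
#> [1] 9

# a two-line cohort, pipeline, QC and statistics
specs <- cohort_specs(
  scene_spec(), c(H = 9, P = 9),
  overrides_by_group = list(P = list(
    marker_positive_fraction = c(GFAP = 0.10, S100B = 0.15),
    fragmentation_level = 3L)),
  seed = 1)
run <- run_pipeline(render_cohort(specs),
                    pipeline_config(markers = list(
                      threshold_method = "fixed",
                      fixed_threshold = 550)))
compare_groups(run$points, "H", "P")
```

The `analysis/` directory holds the same workflow as three numbered
scripts (simulate, extract, compare) that exchange data through files,
and `scripts/acceptance.R` reruns it from scratch for a given seed.
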