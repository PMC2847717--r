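---
title: "Quantifying radial chromosome territory position by equal-area shell erosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial chromosome territory position by equal-area shell erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(radialfish)
library(dplyr)
```

## The measurement

Interphase chromosomes occupy preferred radial positions in the nucleus:
gene-poor chromosomes tend to sit at the nuclear periphery of fibroblast
nuclei and to relocate when cells exit the cell cycle. radialfish implements
the two standard ways this is quantified from FISH (fluorescence in situ
hybridization) images of DAPI-counterstained nuclei:

1. **2D erosion analysis.** The DAPI-defined nucleus is partitioned into
   five concentric shells of *equal area*, shell 1 at the periphery, shell 5
   in the interior. For each nucleus, the percentage of whole-chromosome
   paint signal falling in each shell is divided by the percentage of DAPI
   signal in the same shell; this DAPI normalization corrects for the DNA
   content actually available in each shell. Cohorts of nuclei are
   summarised as mean ± SEM per shell, compared between conditions with
   per-shell Welch tests, and reduced to a peripheral / intermediate /
   interior (P / IM / I) position call.

2. **3D center-to-periphery distance.** In structurally preserved nuclei
   imaged as confocal stacks, each territory's geometric center is measured
   to the nearest point of the DAPI-defined nuclear periphery, in
   micrometers, optionally normalized by nuclear axis length, and summarised
   as a frequency distribution.

Because public microscopy for this assay is not available, the package ships
a seeded synthetic-image generator with known ground truth, so every stage of
the pipeline can be validated end to end.

## Shell geometry: distance-transform quantiles

The historical erosion scripts peeled a fixed number of pixels per iteration
until roughly equal-area rings remained. On a discrete grid that procedure
does not guarantee equal areas, so this package *defines* the shells through
the Euclidean distance transform: every nucleus pixel is ranked by its
distance to the nearest background pixel, and the ranked list is cut into
`n_shells` equal blocks. Pixels that share one distance value across a cut
(a *tie group*) move as a block to the side holding the majority, which keeps
the construction deterministic. Each shell therefore deviates from
`area / n_shells` by at most one tie group — on solid disks the cut radii
converge to the analytic equal-area radii $R\sqrt{1 - k/5}$ within a pixel
at $R = 50$ px.

```{r shells}
mask <- matrix(FALSE, 121, 121)
mask[(row(mask) - 61)^2 + (col(mask) - 61)^2 <= 50^2] <- TRUE
part <- compute_shell_partition(mask)
tidy(part)
```

The normalized profile for one nucleus divides the probe percentage by the
DAPI percentage per shell, so a probe distributed exactly like DNA scores
1.0 everywhere, independent of channel gain:

$$\mathrm{norm}_k \;=\;
\frac{100 \cdot P_k / \sum_j P_j}{100 \cdot D_k / \sum_j D_j},$$

with $P_k$, $D_k$ the summed probe and DAPI intensities in shell $k$. No
background subtraction is applied before summing (an explicit design choice;
the measurement sums raw pixel intensity).

## Cohort statistics

Profiles are aggregated over nuclei (50–70 per chromosome is the usual
cohort size; the generator default is 60) into per-shell mean and SEM with
the $n-1$ sample standard deviation. Conditions are compared per shell with
the unpaired, unequal-variance (Welch), two-tailed *t* test on the
per-nucleus normalized values, using non-rounded Welch–Satterthwaite degrees
of freedom. Welch is used for *all* comparisons — a single, conservative
convention. **No multiple-testing correction** is applied across shells or
chromosomes: each shell is flagged at $p < 0.05$ on its own, matching how
per-shell significance squares are conventionally drawn; treat isolated
single-shell flags accordingly. The same machinery applied to the raw DAPI
percentages is the control that the DNA distribution itself did not change
between conditions (`dapi_control()`).

The position call reduces the mean profile $m$ to its center of mass over
shell indices, $\mathrm{com} = \sum_k k\, m_k / \sum_k m_k \in [1, 5]$,
which is invariant to uniform scaling of the profile. The default thresholds
call P below 2.75, I above 3.25, IM between. The literature assigns P/IM/I
codes without publishing a rule, so these cut points are this package's
operational definition (chosen symmetric around the uniform-profile value 3
and spanning half a shell); they are arguments of `classify_position()` and
the full profile always carries the complete information.

## 3D distances

The nuclear periphery is the set of nucleus voxels with at least one
background 6-neighbor (grid-border voxels included); territory centers are
unweighted means of foreground voxel centers ("geometric center" read
literally, not intensity-weighted). The reported distance is the minimum
anisotropic Euclidean distance from the center to a periphery voxel center,
which matches an exhaustive brute-force search exactly. Against the
continuum surface this discretization errs by about half a voxel on average
but can reach one full voxel dimension in the worst case, because taking a
minimum favors periphery voxels whose outward neighbor only just crosses
the boundary; a digitized 10 μm sphere sampled at ~0.5 μm reads ~9.6 μm.
Axis normalization divides by $(\text{major} + \text{minor})/2$ or by the
major axis alone, with the axes measured by second central moments on the
largest-area z-slice (the in-plane ellipse vocabulary appropriate to
flattened fibroblast nuclei); the package checks that cohort orderings are
unchanged by either normalization (`rank_invariance_check()`). Components
are merged across slices with 26-connectivity; frequency curves default to
0.5 μm bins.

## The synthetic generator

`sim_spec()` fixes the study conditions: flattened elliptical nuclei with
semi-axes 10 × 6.5 μm (plus a 2 μm axial semi-axis in 3D), 5% log-normal
per-nucleus axis jitter and uniformly random in-plane orientation; uniform
DAPI at 100 intensity units inside the nucleus (an optional radial gradient
exercises the normalization); territories as isotropic Gaussian blobs of
sd 1 μm and peak 150; additive Gaussian noise of sd 5 on both channels,
clipped at zero; 0.2 μm pixels in 2D and 0.15 × 0.15 × 0.2 μm voxels in 3D
(ordinary confocal in-plane sampling with 0.2 μm optical sectioning);
cohorts of 60 (2D) or 20 (3D) nuclei. Everything is deterministic given the
master seed: nucleus $i$ draws from substream `seed + i`, so cohorts are
independent of listing order and bit-reproducible.

**The radial coordinate.** The territory position parameter $r \in [0, 1]$
is expressed in the same equal-area metric the erosion analysis measures:
the center is placed on the homothetic contour enclosing a fraction $r$ of
the nuclear area (volume in 3D) along a random direction — ray fraction
$\sqrt{r}$ in 2D, $r^{1/3}$ in 3D. A plain ray-length fraction would put
$r = 0.5$ at area quantile 0.25, deep in the interior shells (center of
mass ≈ 3.8), making "middle" ground truth unrecoverable in principle; in the
equal-area coordinate the expected shell index of a point territory is
linear in $r$, so generated ground truth and measured position share a
scale. $r = 0$ is the nucleus center and $r = 1$ the boundary in either
convention.

```{r recovery}
cohort <- analyze_cohort_2d(
  generate_cohort(sim_spec("2d", radial_fraction = 0.85, n_nuclei = 20, seed = 1)),
  condition = "peripheral")
glance(cohort)
```

What the generator does *not* emulate: irregular nuclear outlines,
chromatin texture in the DAPI channel, optical PSF blur and z-attenuation,
Poisson photon statistics, touching nuclei, or any kinetics of chromosome
relocation. Passing tests therefore demonstrate that the *measurement
procedure* is correct and well calibrated on geometrically idealized
nuclei — not that segmentation would be robust on difficult real material.

## Numerical and degenerate-input choices

* Automatic thresholds use Otsu's inter-class-variance criterion on a
  256-level histogram; territory thresholds are computed only from pixels
  inside the nucleus.
* Components tie-broken deterministically: larger first, then smaller first
  linear index in scan order. Minimum nucleus size defaults to 20 μm² (2D)
  and 100 μm³ (3D).
* Constant images, empty masks, zero probe signal, zero-DAPI shells,
  mismatched shell counts and sub-minimal masks raise classed errors
  (`radialfish_error_*`) rather than propagating NaNs.
* Identical samples in a Welch test return $p = 1$ (degenerate
  zero-variance case) instead of erroring.
* Images round-trip losslessly through 8/16-bit TIFF; pixel size is always
  supplied explicitly, never parsed from vendor metadata.

## Known limitations

* The zero-clipped noise model rectifies to a small positive background;
  since no background subtraction is applied, a territory hard against the
  boundary (r ≳ 0.9) loses truncated blob mass while the rectified
  background is unchanged, slightly inflating interior-shell percentages.
  Shell-1 monotonicity in $r$ is unaffected; shell-5 values are not strictly
  monotone at the extreme peripheral end.
* Equal-*area* shells (not equal-thickness) are the only convention
  implemented.
* The P/IM/I thresholds are validated against synthetic ground truth only.
* One nucleus per image; no splitting of touching nuclei.

## Problem sizes used in the validation suite

The shipped tests run the full pipeline at the stated cohort sizes: 100
replicate cohorts of 60 nuclei per radial fraction for position recovery,
100 replicate pairs for repositioning power and 200 for the false-positive
calibration, 20 random 3D masks against the brute-force distance oracle,
and two 20-nucleus 3D cohorts for the normalization-invariance check.
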