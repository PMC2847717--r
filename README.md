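# radialfish

Radial nuclear positioning analysis of FISH-painted chromosome territories.

Interphase chromosomes occupy nonrandom radial positions in the nucleus —
gene-poor chromosomes such as 13, 18 and X sit at the periphery of
proliferating fibroblast nuclei, and several chromosomes relocate when cells
exit the cell cycle. The standard way to quantify this from 2D FISH images
is **erosion analysis**: the DAPI-stained nucleus is divided into five
concentric shells of equal area (shell 1 = periphery, shell 5 = interior),
and the percentage of chromosome-paint signal in each shell is divided by
the percentage of DAPI signal there,

```
norm_k = (100 · P_k / Σ P) / (100 · D_k / Σ D),    k = 1..5,
```

so a probe distributed like bulk DNA scores 1.0 in every shell. Cohorts of
nuclei are summarised as mean ± SEM per shell, compared between conditions
with per-shell unpaired unequal-variance (Welch) two-tailed *t* tests at
p < 0.05 (no multiple-testing correction), and reduced to a peripheral /
intermediate / interior (P / IM / I) call via the profile's center of mass
over shell indices. For 3D-preserved nuclei imaged as confocal stacks, the
package instead measures the distance in μm from each territory's geometric
center to the nearest DAPI-defined nuclear periphery, with optional
normalization by (major + minor)/2 or the major axis, and frequency
distribution summaries.

The package is aimed at nuclear-organization labs wanting a tested,
scriptable replacement for the one-off erosion macros used with such data:
TIFF in, tidy tibbles out, ggplot2 figures via `autoplot()`, plus a seeded
synthetic-image generator with known ground truth so the whole pipeline is
testable without microscope data.

## Worked example

Simulate a "proliferating" cohort with a peripheral territory (radial
fraction 0.85) and a "serum-starved" cohort with a more interior one, then
run the full analysis:

```r
library(radialfish)

prolif <- analyze_cohort_2d(
  generate_cohort(sim_spec("2d", radial_fraction = 0.85, n_nuclei = 60, seed = 1)),
  condition = "proliferating")
quiesc <- analyze_cohort_2d(
  generate_cohort(sim_spec("2d", radial_fraction = 0.35, n_nuclei = 60, seed = 2001)),
  condition = "serum-starved")

tidy(prolif)
#> # A tibble: 5 × 5
#>   condition     shell  mean     sem     n
#>   <chr>         <int> <dbl>   <dbl> <int>
#> 1 proliferating     1 1.77  0.00685    60
#> 2 proliferating     2 1.59  0.00581    60
#> 3 proliferating     3 0.815 0.00523    60
#> 4 proliferating     4 0.428 0.00283    60
#> 5 proliferating     5 0.392 0.00249    60

glance(prolif)
#> # A tibble: 1 × 5
#>   condition         n n_shells com_index position
#> 1 proliferating    60        5      2.22 P

glance(quiesc)$position
#> [1] "I"

compare_cohorts(prolif, quiesc)
#> # A tibble: 5 × 5
#>   shell t_stat    df   p_value significant
#> 1     1  168.  106.  3.95e-130 TRUE
#> 2     2   44.4  68.8 2.41e- 52 TRUE
#> 3     3  -21.7  62.6 8.81e- 31 TRUE
#> 4     4  -47.9  60.1 1.25e- 49 TRUE
#> 5     5  -11.3  60.1 1.91e- 16 TRUE

dapi_control(prolif, quiesc)$significant
#> [1] FALSE FALSE FALSE FALSE FALSE
```

Reading: the peripheral cohort is enriched ~1.8× over DNA in shell 1 and
depleted in the interior; its center-of-mass index 2.22 < 2.75 calls it
peripheral ("P"). Moving the territory inward flips every shell
significantly (probe channel), while the DAPI control confirms the DNA
distribution itself did not differ — the shift is in the probe, not in
nuclear shape or segmentation. `autoplot(prolif)` and
`plot_cohort_comparison(prolif, quiesc)` draw the standard histogram-with-SEM
figures; `analyze_cohort_3d()`, `frequency_distribution()` and
`rank_invariance_check()` cover the 3D distance workflow.

A command-line wrapper with the same verbs (`simulate-2d`, `shells`,
`cohort`, `compare`, `classify`, `radial3d`) is installed at
`inst/cli/radialfish`.

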