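# rafh

Quantification of **rim-area focal hyperautofluorescence (RAFH)** around
geographic atrophy (GA) lesions on fundus autofluorescence (FAF) images,
and the longitudinal statistical analysis built on it.

GA — the atrophic late form of age-related macular degeneration — shows on
blue-light FAF as a dark, sharply demarcated lesion. The junctional zone
bordering the lesion often carries focal patches of *increased*
autofluorescence that are of interest as a progression biomarker. RAFH
condenses this signal into one number:

    RAFH = (hyperautofluorescent area within a 450-µm rim around GA)
           / (total area of that rim)

a unitless ratio in [0, 1]. A rim pixel counts as hyperautofluorescent
when its raw 8-bit intensity is at least **+40 grey levels** above a local
background reference (the median of non-lesion pixels in a 500-µm window).
The rim is built from an exact Euclidean distance transform of the GA
mask: pixels with distance in (0, 450 µm].

On top of the measurement the package provides:

* lesion morphometry — area (mm²), sub-pixel perimeter (mm), focus count;
* three GA growth rates per eye from first/last visits — area rate
  (mm²/yr), square-root transformed rate (mm/yr), and perimeter-adjusted
  rate (mm/yr, area rate / mean perimeter);
* two-grader reliability — Bland–Altman limits of agreement, ICC(A,1)
  with McGraw–Wong CI, discordance flagging for consensus review;
* baseline-area tertile stratification and Spearman correlation panels of
  baseline RAFH against each growth rate;
* linear mixed-effects models (lme4, REML, Wald z): a univariate →
  multivariable baseline covariate screen with a participant random
  intercept, and longitudinal RAFH-drift models with participant/eye
  intercepts and an eye slope, including a time×arm treatment interaction
  and an adherence-restricted sensitivity refit;
* a synthetic generator for FAF-like images with *planted, known* RAFH and
  for hierarchical two-arm longitudinal cohorts — the ground-truth test
  substrate for everything above.

## Worked example

Simulate a trial-like cohort (44 participants, ~75 eyes, 5 scheduled
visits over 2 years, null treatment effect) and run the full analysis:

```r
library(rafh)

sim <- simulate_cohort(cohort_sim_config(seed = 42))
report <- run_pipeline(sim$records)
report
#> RAFH pipeline report: 352 images, 77 eyes, 44 participants
#>   agreement: ICC 0.846 (0.813-0.873), LoA [-0.128, 0.124], 17 flagged (4.8%)
#>   Spearman (all eyes): area 0.59, sqrt 0.26, perimeter-adjusted 0.19
#>   RAFH drift: 0.0187 units/year; arm slopes obs 0.0206 / met 0.0171 (interaction p = 0.647)
```

Reading this: the two simulated graders agree well (ICC 0.85; 4.8% of
images fall outside the 95% limits of agreement and would go to a joint
consensus review). Baseline RAFH correlates strongly with the raw area
growth rate (ρ = 0.59) but much less with the square-root (0.26) and
perimeter-adjusted (0.19) rates — the size-confounding signature the
square-root transform is meant to remove. RAFH drifts upward at ~0.019
units/yr (generator truth 0.020) and the arms do not differ (p = 0.65;
the generator's treatment effect is zero).

The image pathway, with known planted truth:

```r
img <- simulate_faf_image(image_sim_config(target_rafh = 0.15, seed = 42))
rim <- make_rim_band(img$ga_mask, img$image$scale)   # 450-µm band
detect_hyperaf(img$image, img$ga_mask, rim)
#> <hyperaf_result> RAFH = 0.1483 (3811 hyper px, offset +40, local background)
img$true_rafh
#> [1] 0.1499844

measure_image(img$image, img$ga_mask)
#>   ga_area_mm2 ga_perimeter_mm focus_count rim_area_mm2   rafh
#> 1      1.3472          4.3466           1       2.5696 0.1483
```

The planted RAFH of 0.150 is recovered as 0.148 by the default +40 /
500-µm detection.

A thin command-line wrapper (`inst/scripts/rafh`) exposes
`measure`, `growth`, `agree`, `simulate` and `run` subcommands over the
same functions.

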