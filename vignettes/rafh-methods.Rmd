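---
title: "Quantifying rim-area focal hyperautofluorescence around geographic atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rim-area focal hyperautofluorescence around geographic atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafh)
```

## The measurement problem

Geographic atrophy (GA), the atrophic late stage of age-related macular
degeneration, appears on blue-light fundus autofluorescence (FAF) imaging
as a sharply demarcated dark region. The retina immediately bordering the
lesion — the *junctional zone* — often shows focal patches of increased
autofluorescence, thought to reflect stressed or migrating retinal pigment
epithelium. **Rim-area focal hyperautofluorescence (RAFH)** summarizes this
signal as a single ratio: the fraction of a fixed-width rim band around the
lesion occupied by hyperautofluorescent pixels. It is unitless, lies in
[0, 1], and — because it is a pure pixel-count ratio — does not depend on
the physical pixel scale.

This package implements the full measurement and analysis chain: rim-band
construction, hyperautofluorescence detection, lesion morphometry, growth
rates, two-grader reliability, and the longitudinal mixed-effects models,
together with a synthetic-data generator that provides ground truth for
every stage.

## Rim-band geometry

The rim band is defined from an exact Euclidean distance transform of the
GA mask: a pixel belongs to the rim when its center-to-center distance to
the nearest lesion pixel lies in the half-open interval (0, 450 µm] — the
outer boundary is inclusive. Distances are computed with the two-pass
Felzenszwalb–Huttenlocher algorithm, which is exact; the test suite checks
it pixel-for-pixel against an exhaustive brute-force oracle on random
masks. Three geometric conventions are worth stating:

* **Multifocal lesions** produce the union of per-focus bands; overlapping
  bands are counted once.
* **Enclosed islands** of spared retina inside a lesion are rim pixels
  like any others if they fall within range: the geometric definition is
  applied uniformly since a biological distinction cannot be made from the
  mask alone.
* A band reaching the image edge is truncated there; this raises a warning
  (`touches_border`), not an error, because whole-macula frames routinely
  clip the band for large lesions.

Lesion **area** is the pixel count times the squared pixel pitch.
**Perimeter** is the summed polygon length of the 0.5 iso-contour
(marching squares with linear interpolation) of the mask indicator after a
3×3 box smoothing, including interior hole boundaries. The smoothing step
matters: contouring a raw binary grid overestimates the boundary of a
rasterized disk by about 5.5%, while the smoothed estimator reproduces a
square's and a circle's closed-form perimeters within about 1% at the
resolutions used here. **Focality** is the number of 8-connected
components (diagonal contact joins), the usual convention for counting
bright-blob lesions.

## Hyperautofluorescence detection

A rim pixel is called hyperautofluorescent when its raw 8-bit intensity is
at least 40 grey levels above a local background reference (inclusive
comparison, no normalization of the 0–255 scale). The reference surface is
the median intensity of non-lesion pixels inside a 500-µm square window
centered on the pixel. Two choices deserve justification:

* **Median, not mean** — the statistic must resist exactly the bright
  speckle being detected; a mean would drag the reference toward the
  signal and shrink sensitivity where speckle is dense.
* **Lesion pixels excluded** — the GA interior is systematically dark, so
  including it would depress the reference near the border and inflate
  detections there.

A `global` mode (constant median over rim pixels) is provided for
sensitivity analysis. Both the offset (default +40) and window (default
500 µm) are configurable. Manual corrections are modeled as separate
*add* and *remove* mask layers applied on top of the reproducible
automatic output and clipped to the rim, so the automatic result is never
destroyed by editing.

RAFH is then `sum(hyper) / sum(rim)` exactly.

## Growth-rate metrics

Three per-eye rates are computed from the **first and last** visits only —
the definitions are explicit subtractions, not regressions over visits:

* area rate: $(A_L - A_F)/\Delta t$ in mm²/yr;
* square-root rate: $(\sqrt{A_L} - \sqrt{A_F})/\Delta t$ in mm/yr, with
  the square root of the *total* area summed over foci;
* perimeter-adjusted rate: area rate divided by the mean of first and
  last perimeters, in mm/yr.

For a circular lesion expanding at constant radial speed $k$, the
perimeter-adjusted rate converges to $k$ and the square-root rate to
$\sqrt{\pi}\,k$; the suite verifies both within 3% on rasterized circles.
Baseline-area **tertiles** are assigned by ranking eyes on baseline area
(stable tie-break by participant then eye) and splitting as evenly as
possible with the remainder to the lower groups, so 71 eyes split
24/24/23.

## Grader agreement

Reliability of two independent graders is summarized by the Bland–Altman
mean difference and 95% limits of agreement (mean ± exactly 1.96 sample
SDs of the differences; the conventional normal multiplier, not a t
quantile) and by the intraclass correlation ICC(A,1): two-way random
effects, absolute agreement, single rater, computed from the two-way ANOVA
mean squares with the McGraw–Wong F-based confidence interval. Absolute
agreement is the right variant for interchangeable graders: a constant
offset between graders should, and does, lower it. Images whose grader
difference falls strictly outside the limits of agreement are flagged for
a single joint consensus round; downstream analyses use the grader mean.

## Mixed-effects models

Baseline associations are screened covariate-by-covariate with linear
mixed models of grader-mean baseline RAFH on one covariate plus a random
intercept for participant (two eyes of one person are correlated);
covariates reaching p < 0.05 enter a joint multivariable model with the
same structure, with no further selection. Estimation is REML; inference
is Wald z (CI = estimate ± 1.96 SE), chosen for portability over
degrees-of-freedom approximations.

The longitudinal model for RAFH change has fixed effects of time — plus
treatment arm and the time-by-arm interaction in the treatment model — and
random effects: a participant intercept, an eye intercept nested in
participant, and an uncorrelated random slope on time for eye (the
intercept–slope correlation is left out by default; with ~70 eyes it is
weakly identified and its omission is configurable). The treatment model
uses visits up to 1.5 years (the on-treatment window); the pooled-drift
model uses 2.0 years. A sensitivity refit excludes participants below 75%
treatment adherence. Non-convergence triggers an explicit, logged fallback
ladder — drop the eye slope, then the eye intercept, then all random
effects — while singular fits (zero variance at the boundary) are accepted
as legitimate estimates.

## The synthetic-data generator

Because the source trial's images are not public, validation rests on
synthetic data with known truth.

**Images.** A blobby perturbed-ellipse lesion (dark interior) on a
Gaussian-noise background (mean 100, SD 8 grey levels), with
hyperautofluorescent speckle blobs (+60 grey levels) planted inside the
analytic rim band until the planted fraction hits the target RAFH exactly
at pixel resolution. The generator returns the ground-truth masks, so
planted-truth recovery (|measured − true| ≤ 0.03 at targets 0.05–0.30) is
testable end to end. What the phantom does *not* model: vessels, the optic
disc, vignetting, media opacity, or inter-visit registration error — so a
passing recovery test validates the algorithmic chain, not robustness to
real-world imaging artifacts.

**Cohorts.** 44 participants (about 71 eyes; each contributes a second eye
with probability 0.61), randomized 1:1, visits at 0, 0.5, 1, 1.5 and
2 years with 12% independent visit dropout. Baseline GA area is log-normal
(median 5 mm², log-SD 0.9) truncated to [0.25, 35] mm² — the floor mirrors
trial minimum-lesion eligibility and the ceiling the imaged macula.
Square-root growth rates are Gaussian (mean 0.25, SD 0.12 mm/yr, floored
at 0.02). True RAFH is

$$\mathrm{RAFH}_{it} = 0.15 + 0.065\,\sqrt{A_{i0}} +
  (0.020 + b_i + \beta_{\mathrm{arm}})\,t + u_{p(i)} + u_i +
  \varepsilon_{it},$$

with participant and eye intercept SDs 0.05 and 0.04, eye-slope SD 0.010,
visit jitter SD 0.015, and a null treatment effect by default. Two points
about this construction:

* The cross-sectional size association uses √area at *baseline*, so the
  configured 0.020/yr is the true *marginal* drift that the longitudinal
  model should recover. Tying RAFH to the time-varying √A(t) instead
  would silently add ≈ 0.065 × 0.25 ≈ 0.016/yr of extra drift and make
  the generator's nominal slope a fiction.
* The eye's growth rate is coupled to its RAFH deviation with a
  stratum-specific coefficient (0.8, 0.8, 0 by tertile), so the
  size-dependent association pattern is a *reachable generator regime*,
  not an artifact. With the default settings, the confounding path
  through baseline area (larger lesions → larger RAFH *and* larger
  area-rate for the same radial speed) reproduces the qualitative
  ordering: Spearman correlation with the raw area rate exceeds that with
  the square-root rate.

Grader readings add independent Gaussian noise (SD 0.044 per grader — the
level implied by a between-grader difference SD near 0.062). All values
are clipped to [0, 1] with clip events counted; a run with more than 1% of
draws clipped is rejected as mis-configured. This rejection is rare at the
defaults (roughly one seed in several hundred, driven by extreme
random-effect draws); replicate studies simply redraw a rejected cohort
with a shifted seed, which leaves the generating conditions untouched.

## Numerical choices and problem sizes

Tests and the acceptance script run at desk scale by design: phantom
images are 256×256 px at 10 µm/px (512×512 at 5 µm/px for the resolution
invariance checks); rim-oracle property tests use 100 random masks up to
100×100; replicate studies use 200 trial-size cohorts (drift recovery and
interaction type-I error), 200 cohorts of ~300 eyes (cross-sectional
coefficient recovery), and 100 cohorts for the correlation-ordering check.
Exact-arithmetic claims (distance transform, RAFH ratio, Bland–Altman and
ICC formulas) are tested to 1e-10 or to identity; estimator claims carry
the tolerances stated above. Spearman p-values use the exact permutation
distribution for n ≤ 10 and the t approximation otherwise.

## Known limitations

* The original semiautomatic software's background-reference construction
  is not published; the windowed-median surface here is an explicit,
  configurable stand-in, and measured RAFH can differ from that software
  on the same image even though both implement "+40 over local
  background".
* Perimeter is estimator-dependent at the ~1% level; comparisons across
  software should fix the estimator.
* The generator's visit process is missing-completely-at-random; informative
  dropout is not modeled.
* Growth rates use endpoint subtraction by definition, so they inherit
  endpoint measurement noise; no shrinkage or regression smoothing is
  applied.
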