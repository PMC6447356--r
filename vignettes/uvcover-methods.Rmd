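---
title: "Quantifying sun-protection coverage from UV photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sun-protection coverage from UV photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvcover)
```

## The measurement

A camera modified to record only ultraviolet light sees sunscreen and
SPF moisturiser as dark: both products absorb UV, so covered skin
photographs darker than bare skin. `uvcover` turns that physical
contrast into per-region coverage metrics for a two-visit crossover
study in which each participant applies both formulations, once each,
in counterbalanced order:

1. A 68-point facial landmark set (consumed as a PTS or JSON file, or
   synthesised) defines the analysis regions.
2. A per-participant intensity threshold is calibrated on the bare-skin
   baseline image.
3. The post-application image is binarised into covered/uncovered
   pixels, and each region's *percent missed* is
   `100 * uncovered / total` pixels.
4. Each medial canthus additionally receives a binary
   fully-covered/missed call.
5. A repeated-measures statistical battery compares formulations and
   subgroups on the resulting table.

Because study photographs of faces are rarely shareable, the package
ships a synthetic generator with exact ground truth, so the entire
analysis runs, and is tested, without external data.

## Region geometry

Landmarks follow the standard 68-point scheme (jaw 1–17, brows 18–27,
nose 28–36, eyes 37–48, mouth 49–68; inner eye corners are points 40
and 43). Coordinates are 0-based pixels, origin top-left, y downward;
every box is half-open `[x0, x1) x [y0, y1)`, which keeps pixel
counting free of off-by-one ambiguity. "Left" and "right" are
image-frame, not anatomical.

* **Face** — the axis-aligned box spanning the jaw laterally, from an
  extrapolated forehead line (brow top minus `forehead_margin` times
  the eye-to-brow distance; default 1.0) down to the chin point,
  clipped to the image.
* **Eyelids** — each eye's bounding box, expanded up to its brow line
  and laterally by `lateral_margin` (default 10% of the eye width).
* **Medial canthi** — squares of side `canthus_frac` (default 0.6)
  times the inter-inner-corner distance, capped at `canthus_cap`
  (default 0.25) times the eye width, centred on the inner corners and
  shifted nasally by `nasal_offset` (default 0.25) of the side.
* **Non-eyelid** — face minus the eyelid union.

Eyelid and canthus boxes are clipped to the face, so the subset
invariants (`eyelid ⊆ face`, `non_eyelid = face \ eyelid`) hold by
construction. The box-delimiting landmarks were a genuinely open
choice — the study this design follows shows its regions only
graphically — so every margin is a `region_params()` argument and the
values used are recorded in the `region_set` provenance. The
dose-response measurement splits the face at the nose-bridge midline
(mean x of points 28–31); the two halves partition the face exactly.

## Calibration and segmentation

Skin tone varies across participants (Fitzpatrick types I–IV are
analysed), so a single global threshold cannot separate product from
skin: dark bare skin and product on light skin can photograph at the
same grey level. The threshold is therefore calibrated per participant
on their own baseline: with face-pixel mean `mu` and SD `sigma`,

```
threshold = max(mu - k * sigma, floor),   k = 3 by default.
```

At `k = 3` a Gaussian bare-skin image mislabels about 0.13% of pixels
as covered (the lower normal tail), which the component-size filter
then removes. A pixel of the post-application image is covered iff its
working-channel intensity is strictly below the threshold. RGB images
are reduced to the hue-saturation-value value channel (`max(R, G, B)`,
standard hexcone model) with an optional saturation band gate;
grayscale images pass through unchanged.

Optional morphological cleanup follows: a closing of the covered mask
(radius 1 by default — the radius-1 digital disc is the 4-neighbour
diamond; a 3×3 box would over-close) and removal of covered components
smaller than `min_blob = 5` pixels. Whether the original analysis used
such cleanup is unknowable from its description, so both steps are
disable-able (`close_radius = 0`, `min_blob = 1`).

Participants who arrive already wearing an SPF product would corrupt
their own calibration. A provisional global threshold (default 110
grey levels, below the darkest bare-skin baseline the generator
emulates) flags any baseline whose covered fraction exceeds 5%;
flagged baselines abort that participant unless an operator override
(`allow_flagged_baseline = TRUE`) is given.

Percent missed satisfies an exact pixel-weighted identity,
`missed(face) = [A_e missed(eyelid) + A_n missed(non_eyelid)] /
(A_e + A_n)`, which the tests assert to numerical precision. The
medial canthus is called covered iff its covered fraction is at least
`tau = 0.95`; "fully covered" is read with a small tolerance because a
literal 100% rule would flip on single noisy pixels, and `tau` is
exposed for stricter readings.

## The statistical battery

All tests run at significance level 0.05.

* **Normality gating.** Kolmogorov–Smirnov in its Lilliefors form
  (parameters estimated from the sample, via `nortest`): the naive KS
  test with estimated parameters is anti-conservative. If normality is
  rejected, the gate retries after log and then square-root
  transforms; non-positive samples are first shifted (log: `1 - min`,
  sqrt: `-min`), and the shift is recorded and applied jointly to both
  samples of a comparison. Samples that still fail route to the
  nonparametric path. Constant samples, and samples below the
  Lilliefors minimum of five observations, route nonparametric with a
  warning.
* **Paired comparison.** Two-sided paired t-test on the (possibly
  transformed) samples. The nonparametric fallback is the Mann–Whitney
  U test — kept as the default because it mirrors the analysis plan
  this package reproduces — with a Wilcoxon signed-rank option
  (`fallback = "signed-rank"`), arguably the better match for a paired
  design; the result records which path ran.
* **Repeated-measures ANOVA.** One within factor (formulation),
  participant as the blocking stratum. With two levels the F statistic
  equals the squared paired-t statistic; the tests assert this
  identity to 1e-9.
* **Subgroup contrasts.** One-way ANOVA across group-by-formulation
  cells, then independent t contrasts between groups within each
  formulation, Sidak-adjusted (`p_adj = 1 - (1 - p)^m`). Skin types
  are collapsed to I+II vs III+IV before analysis (the darker-skin
  group is small).
* **ANCOVA.** `percent_missed ~ sex * skin_group + age` per
  formulation, Type II sums of squares by default — appropriate for
  the near-balanced synthetic designs and invariant to factor order;
  Type III (with sum-to-zero contrasts) is available for comparison
  with software whose default it is. Rank-deficient designs error,
  naming the aliased term.
* **Order effect.** The sunscreen-first and moisturiser-first groups
  are compared per region and formulation (t or Mann–Whitney per the
  gate); the battery reports whether effects are consistent (no
  comparison significant), the precondition for pooling a crossover.
* **Dose-response.** `mean_intensity ~ mass * formulation` on
  half-face mass-series records; per-formulation slopes with 95% CIs
  from the shared-variance model, and a Type II F test for the
  formulation effect. An exact-line fit (zero residual, zero effect)
  reports F = 0 rather than 0/0.
* **Binary tabulation.** Counts of missed medial canthi with the exact
  percentage retained and a display percentage truncated to the whole
  percent, matching the study-report style (66 of 84 prints as 78%).

## The synthetic generator

### What it emulates

* **Skin tone.** Baseline images are uniform at a per-participant base
  intensity set by skin type (I: 200, II: 180, III: 150, IV: 120 grey
  levels) plus Gaussian pixel noise (`noise_sd = 2` by default). The
  study's imaging description does not characterise image noise, so
  this is a stated assumption, exposed as a parameter.
* **Dose-dependent darkening.** Applied product multiplies covered
  pixels by `a(mass) = exp(-kappa * mass)`; uncovered pixels are
  untouched baseline. The source data show only that more mass gives a
  darker image, so the exponential was chosen as the simplest
  saturating form with a strictly monotone invariant to test; the
  default `kappa` gives 40% attenuation at a 100 mg-equivalent
  application.
* **Structured application failures.** Uncovered areas are contiguous
  blobs, not salt-and-pepper pixels, matching the observation that
  people repeatedly miss the same anatomical areas. Blobs are unions
  of morphologically *open* atoms (digital discs of radius 2–3 and
  5-pixel plus shapes): an open set is invariant under the pipeline's
  default closing, so the recorded ground truth is exactly what the
  segmentation can see. Placement is budgeted per cell — the canthus
  union, the eyelid remainder, and the non-eyelid remainder — so each
  region's uncovered fraction hits its requested value to the pixel;
  residual counts that open atoms cannot express (1–4 or 6–7 pixels)
  are settled as one- or two-pixel boundary nubs. The weighting of
  misses toward the eyelids and canthi arises from the per-region
  budgets themselves.
* **Population structure.** Per region, the (sunscreen, moisturiser)
  pair is bivariate normal with correlation `rho = 0.5` and the
  region-wise means/SDs of the study population (face 11.1/5.0 vs
  16.6/6.4; eyelid 14.0/8.3 vs 20.9/8.2; non-eyelid 9.5/5.5 vs
  13.6/6.9 percent), clamped to [0, 100]. Demographics scale the
  study's 22/62 male/female and 60/24 order splits; sex (5 pp) and
  skin-group (8 pp) shifts are applied mean-centred, echoing the
  subgroup analyses. Each participant-formulation misses the medial
  canthus with probability 0.78.

### Emulation compromises

* The population draws each region independently at its published
  mean/SD, so the pixel-weighted face identity is *not* imposed on the
  population table; images are rendered from the eyelid and non-eyelid
  fractions and the measured face percent follows from the geometry.
  With the default boxes the eyelids are ~9% of the face area, so the
  measured face means sit nearer the non-eyelid values than the
  published face means, which imply a larger eyelid share under the
  identity. Both views are reported.
* The mean-centred subgroup shifts add variance, so the realised
  marginal SDs exceed the generating SDs by up to ~1.5 pp.
* A drawn canthus miss can exceed what a participant's (independently
  drawn) eyelid budget admits inside the canthus boxes — an
  inconsistency the study's real, spatially coherent data could not
  produce. `run_study()` steps such requests down a ladder that stays
  above the fully-covered cutoff, dropping to zero only when even a
  6% miss is infeasible; at the default geometry this changes the
  realised canthus rate by one or two participants per study.
* Canthus budgets are granularity-limited: at the default 192×192
  images one pixel is ~0.8% of the canthus union, so requested
  fractions are met to ±0.5 pp there but not at much smaller images.

### What it does not emulate

Illumination gradients, shadows, specular highlights, hair and
eyebrows, landmark-detector error beyond Gaussian jitter, partial
product thinning (coverage is binary at the pixel level), and
non-frontal pose. Passing tests therefore demonstrate that the
*measurement and analysis machinery* is correct under the stated image
model — they do not validate the thresholding rule against real
UV photographs, for which per-image inspection of the flagged-baseline
and calibration diagnostics remains necessary.

## Numerical choices and problem sizes

Box edges round half-up to pixel indices; bilateral symmetry of the
landmark template is exact before jitter, so mirror-equality tests
tolerate only discretisation. Determinism is absolute: every generator
output is a pure function of its spec and seed (`withr::with_seed`
leaves the caller's RNG untouched), and repeated `run_study()` calls
with one seed produce byte-identical CSVs (no timestamps are written;
the seed and full configuration are echoed into every output).

The shipped tests exercise: oracle equivalence of all pixel-counting
operations against naive per-pixel loops on 200 random instances up to
128×128; end-to-end recovery of missed fractions {0, 5, 15, 30}% at
the default 192×192 geometry to within ±1 pp per region; type-I error
of the paired comparison and RM-ANOVA within [0.04, 0.06] over 2000
null replicates at n = 84; detection of the default formulation
difference (p < 0.001) in ≥95% of 200 population replicates; slope
recovery of the dose-response generator at nominal CI coverage over
100 replicates; and hash-identical outputs for repeated runs. These
sizes keep the full suite under a minute on one core while leaving the
Monte-Carlo error well inside each asserted band.

## Limitations

The package quantifies *where* product landed, not how much protection
it affords: image darkness under UV-A reflects applied mass and the
formulation's absorption spectrum, so relative UV-B protection cannot
be inferred. Landmark detection itself is out of scope — landmarks are
consumed as input, and the synthetic template stands in for a detector
during testing. The statistical battery reproduces a specific analysis
plan, including its debatable unpaired Mann–Whitney fallback within a
paired design; the signed-rank option exists precisely because neither
choice is asserted as correct.
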