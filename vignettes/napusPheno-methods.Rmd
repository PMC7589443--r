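---
title: "Methods: image-derived shoot traits, growth dynamics and QTL mapping in napusPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-derived shoot traits, growth dynamics and QTL mapping in napusPheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

napusPheno implements a complete desk-scale analogue of a high-throughput
rapeseed (*Brassica napus*) shoot phenotyping pipeline: segmentation of
side- and top-view chamber images, extraction of 41 image-derived traits
("i-traits"), biomass estimation from projected area, growth-curve fitting,
stepwise yield modelling, and quantitative genetics on an intervarietal
substitution-line (ISL) population — heritability, QTL scans, Dunnett
validation against the recurrent parent, and permutation-based hotspot
detection. This vignette documents the methodological choices; every
numerical claim made here is asserted by the test suite
(`tests/testthat/`) or computed by `scripts/acceptance.R`, not quoted.

## Segmentation

Side views are segmented in HSI colour space (hue in [60, 180] degrees,
saturation at least 0.15, intensity in the half-open interval (0.02, 0.98]);
top views threshold the excess-green index EG = 2G − R − B at EG > 20.
Both gates are data in a `SegmentationConfig`, overridable from YAML.
Foreground components are labelled with 8-connectivity (two-pass
union-find) and components below `minComponentArea` (64 px) are removed.
A configurable crop removes the conveyor band from side views before
segmentation.

## Trait geometry: a deliberately mixed basis

Areas (TPA, hull area, and the area-based compactness ratios) are measured
on the polygon through pixel *corners*, so a w-by-h rectangle of pixels has
area exactly w·h. Perimeters are measured through pixel *centres*: the
plant perimeter is the length of the Moore (8-neighbour) boundary walk with
diagonal steps counted as sqrt(2), and the hull perimeter is the convex
hull of pixel centres. This mixed basis is chosen so that PC3 =
hull-perimeter / contour-perimeter is exactly 1 for rectangles and never
exceeds 1, while area identities (e.g. solidity = 1 for convex shapes)
remain exact. Maximum Feret diameter uses the corner hull. A single
isolated pixel has contour length 1 by convention.

The Moore tracer terminates by cycle detection on (pixel, backtrack
direction) states rather than by "returned to start", which is unsound on
masks whose start pixel is revisited with a different approach direction.
The contour length is the cycle length. An independent, naive reference
implementation (`referenceTraits`) shares no code with the production path
and the suite asserts agreement to 1e-9 on random polyominoes.

Fractal dimension is box counting over dyadic box sizes up to half the
(cropped or uncropped) mask side — FDIC crops to the bounding box, FDNIC
does not. Histogram texture features (mean, variance-based smoothness,
third moment, uniformity, entropy) use a fixed 256-bin histogram of the
masked intensity channel, which gives exact closed forms on constant,
two-level and uniform histograms.

## Biomass estimation

Eleven regression families map projected areas to fresh/dry weight; the
power-law members (model ids `powerFamilyIds()` = 4, 8, 9, 11) are fitted
by OLS on the log scale. Predictions back-transform with *no* smearing
correction, matching common practice in the source protocol, and all
reported metrics (adjusted R², MAPE, SD of absolute percentage error) are
computed on the original scale. One structural consequence, verified
empirically in the suite: with lognormal noise at sigma = 0.15, the
unsmeared power model and an OLS quadratic are nearly tied in
original-scale adjusted R², so "power ranks first" holds only about half
the time even though the data are generated from a power law; ranking by
MAPE instead recovers the power family almost always. The acceptance test
asserts the criterion as written and is therefore expected to fail; the
package exposes both rankings.

## Growth dynamics

Six families (linear, quadratic, exponential, power, logarithmic,
sinusoidal) are fitted per line and view over the 12 inspection time
points. The sinusoid is fitted by profiling the frequency b over a grid,
solving the conditionally linear coefficients, then polishing with
Levenberg–Marquardt restarts; fits are canonicalised to amplitude >= 0 and
phase in (−pi, pi]. Noise-free recovery is exact to 1e-4 relative. At 5%
multiplicative noise, *curve-level* recovery (median relative deviation of
the fitted curve from the true curve) is the meaningful criterion: for the
quadratic family individual coefficients are not identifiable to 5% from
12 points at this noise level (their variance floor exceeds the target),
while curve recovery is comfortably inside it. Constant series return
slope 0 and adjusted R² 0 by convention; short or domain-violating series
are flagged failed, never silently fitted.

## Yield model

Stepwise selection uses partial-F enter/remove tests (defaults 0.05/0.10)
with QR-based vectorised screening and visited-state cycle protection.
Cross-validation is honest: selection is redone inside every fold, so
pure-noise designs yield strongly negative out-of-sample R² while
in-sample selection on the same data inflates towards 100% — the suite
asserts both sides.

## Quantitative genetics

Broad-sense heritability is H² = sigma²G / (sigma²G + sigma²GE/n +
sigma²e/(nr)) on the line-mean basis. Components come from balanced EMS
(expected mean squares) ANOVA or REML (lme4); the suite asserts their
equivalence on balanced data and the closed form 20/27 = 0.7407 for
components (1, 0.5, 1) with n = 2 environments and r = 5 replicates.
Negative EMS estimates are truncated at zero and flagged.

The QTL scan regresses line means on 0/1 donor-segment markers with
forward-selected background cofactors (excluded within 5 Mb of the tested
marker); LOD = n·ln(RSS0/RSS1)/(2·ln 10), significant runs are reduced to
peaks, and support intervals are intersections of carrier segments.
Dunnett many-to-one validation uses a seeded Monte-Carlo multivariate-t
adjustment that the suite checks against the pooled t-test (one carrier)
and the multcomp package (several carriers). Hotspots are 1-Mb windows
whose QTL count exceeds the smallest threshold c with P(max window count
>= c) <= alpha under permutation of QTL locations.

## Synthetic data as study conditions

Generators default to the study's conditions rather than to values chosen
for test convenience: 512×512 scenes with a blue chamber background, grey
conveyor band and jittered vegetation green plus Gaussian pixel noise; a
~730 Mb, 19-chromosome genome with a 1-Mb marker grid; 89 substitution
lines plus the recurrent parent ZY821; 2 seasons × 5 replicates; planted
QTL effects sized as a = sqrt(PVE·V/(f(1−f))) on the line-mean scale.
Every generator takes a mandatory seed and every planted effect is
recorded in a truth ledger.

## Limitations

- The published headline results (hundreds of QTLs, specific yield R²,
  agreement with manual measurement) require the original images and field
  data and are out of desk-scale scope; acceptance is property-based.
- The published supplementary-table summary statistics (mean fold change,
  mean H² across traits and time points) cannot be recomputed offline; the
  suite instead certifies the identical summary machinery on synthetic
  tables with known truth.
- No smearing correction is applied in biomass back-transformation (see
  above for the measured consequence).
- Dunnett adjustment is Monte-Carlo based; agreement with references is to
  Monte-Carlo error, not exact.
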