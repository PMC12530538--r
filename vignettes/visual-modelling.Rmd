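---
title: "Receptor-noise visual modelling of colour morph spectra"
author: "morphvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-noise visual modelling of colour morph spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphvision)
```

## The question the package answers

Colour polymorphic animals carry discrete colour variants (morphs) within
one breeding population. Whether those variants function as signals depends
on whether observers — conspecifics and predators — can actually tell them
apart, and that is a property of the *observer's* visual system and of the
ambient light, not of human perception. morphvision implements the standard
workflow for answering this: reflectance spectrometry processing,
colorimetric description, receptor-noise-limited (RNL) modelling of
chromatic and achromatic contrast in just-noticeable-difference (JND)
units across several visual systems and illuminants, and group-level
inference (bootstrap centroid distances, distance-based PERMANOVA). The
default configuration mirrors a three-morph (orange / white / yellow)
lizard throat colour study viewed by the lizards themselves, a
violet-sensitive raptor, and a colubrid snake, under standard daylight
(D65) and forest shade.

## Spectral processing

Raw input is a wide CSV: a `wl` column plus one column per measurement,
named `<individual>_<replicate>` (six replicates per individual in the
default design). The default chain in `process_spectra()` is:

1. **Restrict/regrid** to the 300–700 nm integer grid by linear
   interpolation (`restrict_and_regrid()`). Linear interpolation is the
   conventional choice for smooth reflectance curves and keeps the
   quantum-catch integral a plain unit-step sum.
2. **Average replicates** per individual (`aggregate_replicates()`), a
   pointwise arithmetic mean. Averaging precedes smoothing by default
   (the order can be swapped via `order=`), matching the usual
   spectrometry workflow where replicate noise is pooled before curve
   fitting.
3. **Smooth** with tricube-weighted local quadratic regression
   (`smooth_spectra()`, `stats::loess` with an exact direct fit), with
   `span` the fraction of grid points in the local window; the default
   0.2 suppresses electrical noise while preserving cut-on shapes. A
   degree-2 local fit reproduces constants and straight lines exactly,
   which the tests exploit. Other software families implement "span"
   smoothers with slightly different kernels; numerical agreement with
   them is close but not bit-exact.
4. **Validate nonnegativity** (`validate_nonnegative()`): the default
   policy is to *error* on any negative reflectance, mirroring a
   confirm-then-proceed workflow; `clip_zero` is available for foreign
   data with small negative calibration artefacts.

## Colorimetrics

Three segment-free variables per processed spectrum: brightness (mean
percent reflectance over 300–700 nm), chroma ((Rmax − Rmin)/brightness)
and hue (wavelength at middle reflectance). Hue is implemented as the grid
wavelength whose reflectance is closest to (Rmax + Rmin)/2 with ties broken
toward the shorter wavelength — a deterministic rule; spectra that cross
the mid level more than once (UV-spiked spectra do) are flagged via the
`multiple_crossings` attribute since "the" mid-reflectance wavelength is
then ambiguous. Group tables (`summarize_groups()`) report arithmetic means
of per-individual brightness and chroma, and the hue of the group mean
spectrum (printed as an integer nm, the convention most published tables
appear to use); the mean of per-individual hues is also emitted because
both conventions are in circulation.

## Visual systems and illuminants

A visual system is 3 or 4 chromatic receptor classes plus an achromatic
channel. Sensitivity curves come from the Govardovskii A1 pigment nomogram
(alpha plus beta band) evaluated on the grid and area-normalized, or from a
user CSV. Receptor noise uses the neural (abundance-scaled) model
\(e_i = \omega_{ref}\sqrt{\eta_{ref}/\eta_i}\) anchored at the
long-wavelength cone, which is how a single published Weber fraction for
the LW cone is conventionally expanded to all channels.

Three editable YAML configs ship with the package:

* **lizard** — wall-lizard tetrachromat, λmax 367/456/497/562 nm, cone
  ratio 1:1:1:4, LW Weber fraction 0.05;
* **bird** — violet-sensitive raptor tetrachromat, λmax 405/449/504/567
  nm, ratio 1:2:2:4, Weber 0.10;
* **snake** — colubrid trichromat, λmax 360/482/554 nm with an
  LW-dominated retina (1:1:8), Weber 0.05. Garter-snake-type retinas have
  three cone classes, so the snake model deliberately has no fourth
  channel; chromatic distances then flow through the generic n-chromatic
  evaluator, and tetrahedral coordinates are (correctly) unavailable.

The achromatic channel defaults to the LW curve with the system's stated
Weber fraction, standing in for the double cones believed to drive
luminance vision in these taxa. No ocular-media transmission is applied by
default; custom sensitivity files can encode it.

Illuminants are relative-quanta irradiance spectra. `d65` is the standard
tabulated CIE daylight distribution (bundled at 5 nm, interpolated,
converted energy→quanta). `forestshade` is a two-component parametric
approximation — a broad Gaussian peaking at 550 nm plus a logistic far-red
rise near 680 nm — capturing the "yellow-green plus far-red" signature of
light under a canopy; measured spectra can be supplied as CSV instead.
Because all distances are computed on log catches, any overall rescaling
of an illuminant cancels exactly (tested), so the unit-mean normalization
of the built-ins is cosmetic.

## JND distances

Quantum catches are unit-step Riemann sums of R·I·S over the grid; log
catches implement the Weber–Fechner transform that makes JNDs
illumination-scale invariant. Chromatic distance uses the RNL
quadratic form (closed tetrachromat expression, generic evaluator for
other channel counts — both are kept and cross-checked to 1e-10);
achromatic distance is |Δ log Q_A| divided by the achromatic Weber
fraction. The package constants 1 JND (discrimination threshold) and
3 JND (easily discriminable even in poor light) are reporting flags only.
ΔS is a Mahalanobis-type norm on log-catch space, hence a true metric;
the tests assert identity, symmetry, the triangle inequality, and
invariance to illuminant scale and per-receptor gain (the reason a von
Kries normalization is immaterial to the distances; relative catches are
still used for the tetrahedral colourspace, where it would matter).

## Group inference

`boot_group_distance()` reports the JND distance between group centroids
(per-channel means of log catches — the log-domain centroid is the
default because distances are defined on log catches) with percentile
bootstrap CIs from within-group resampling of individuals.
`permanova()` implements the one-way distance-based decomposition
(SS_total = Σd²/N, within-group terms 1/n_g Σd², pseudo-F with the
+1-convention permutation p that can never be zero), with an exact
enumeration mode for small samples; `pairwise_permanova()` runs it per
group pair with Bonferroni adjustment across the pairs within one
system × illuminant × channel block. `dispersion_test()` wraps the
standard distance-to-centroid Levene analogue (vegan's betadisper +
permutest, centroid type) as the assumption check; the package reports it
alongside PERMANOVA and never transforms the data automatically. All
Monte-Carlo functions take a mandatory seed, carried into the output.

## The synthetic generator

`generate_dataset(default_study_config())` emulates the study's
structure: 102 individuals (orange 23M/22F, white 13M/12F, yellow
16M/16F), six replicates each on 300–700 nm. Each morph is a logistic
cut-on — baseline plus amplitude/(1+exp(−(λ−centre)/steepness)) — with
between-individual Gaussian variation of centre (sd 6 nm) and amplitude
(sd 5), iid replicate noise (sd 1.5 % reflectance, clipped at zero after
addition), and a Bernoulli 370-nm Gaussian UV spike (probability 0.40 in
white, 0.09 in orange, 0 in yellow, reflecting the observed carrier
fractions). Cut-on centres (543/411/502 nm) and amplitudes (75/55/70 over
a baseline of 10 %) were chosen once so that processed group hues land
near 543 (orange), 410 (white) and 502 (yellow) nm with white the
brightest, lowest-chroma morph — the qualitative geometry of the real
morphs. Per-individual seeds are derived arithmetically from the master
seed, so draws are order-independent and runs bit-reproducible.

What the generator does *not* emulate: measurement-geometry artefacts,
specular glare, wavelength-dependent sensor noise, and the true
covariance structure of real throat spectra. Passing tests on synthetic
data therefore demonstrate the correctness and stability of the
computations, not field-data effect sizes.

## Numerical choices and edge cases

* Smoothing uses loess's exact ("direct") surface so polynomial
  reproduction holds to 1e-8; the interpolated approximation would not.
* Zero or negative quantum catches (spectra not overlapping a sensitivity
  band) raise errors naming the individual and channel rather than
  propagating −Inf log catches.
* Hue is undefined for constant spectra (error), chroma for zero
  brightness (error).
* Tiny negative squared distances from floating-point cancellation are
  clipped to zero before the square root.
* The degenerate PERMANOVA case SS_within = 0 yields an infinite F with a
  permutation p still defined.
* The tetrachromat closed form and the generic quadratic evaluator are
  both retained deliberately, as mutual cross-checks.

## Problem sizes used in the test-suite

The shipped tests run the full 102-individual, six-model synthetic
analysis with 199 permutations and 200 bootstrap replicates, and the
acceptance script uses 999 permutations and 1000 replicates — enough for
stable two-decimal summaries of the reported quantities while keeping a
complete run in seconds on one CPU. The bootstrap-monotonicity property
(larger between-morph cut-on separation ⇒ larger chromatic ΔS) is asserted
for separations below the LW pigment peak; beyond it the JND response
flattens because catch contrast saturates, which is a feature of the
visual model, not a numerical artefact.

## Known limitations

* Snake retinal parameters (and all λmax values) are transcriptions from
  the primary sensory literature shipped as editable configs; replication
  of any particular published analysis should start by checking those
  configs against that study's sources.
* No background/substrate contrast ("conspicuousness against granite vs
  grass") — distances are between animal colour patches only.
* The forest-shade illuminant is parametric; for quantitative work under
  measured field irradiance, load the measured spectrum from file.
* PERMANOVA is one-way (morph); sex or population strata would need
  restricted permutations, which are out of scope.
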