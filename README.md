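# morphvision

Receptor-noise visual modelling of colour morph reflectance spectra.

## What it is for

Colour polymorphic animals — here the motivating case is a lizard with
co-occurring orange, white and yellow throat morphs — signal with colours
that matter only insofar as *other animals* can tell them apart. morphvision
answers "who can discriminate which morphs, under which light?" for
researchers in visual ecology. It takes replicated reflectance spectra,
processes them (regrid to 300–700 nm, replicate averaging, local-regression
smoothing, negativity checks), summarizes colorimetrics (brightness, chroma,
hue), and evaluates discriminability under configurable observer visual
systems and illuminants with the receptor-noise-limited (RNL) model.

The core statistic is the RNL chromatic contrast between stimuli *a* and
*b*, in just-noticeable-difference (JND) units. With quantum catches
Q<sub>i</sub> = Σ<sub>λ</sub> R(λ)I(λ)S<sub>i</sub>(λ), log catches
f<sub>i</sub> = ln Q<sub>i</sub>, and channel noise
e<sub>i</sub> = ω<sub>ref</sub>√(η<sub>ref</sub>/η<sub>i</sub>), the
tetrachromat distance is

ΔS = √(N / D), with
N = e₁²e₂²(Δf₄−Δf₃)² + e₁²e₃²(Δf₄−Δf₂)² + e₁²e₄²(Δf₃−Δf₂)² +
e₂²e₃²(Δf₄−Δf₁)² + e₂²e₄²(Δf₃−Δf₁)² + e₃²e₄²(Δf₂−Δf₁)²,
D = (e₁e₂e₃)² + (e₁e₂e₄)² + (e₁e₃e₄)² + (e₂e₃e₄)²

(a generic n-chromatic evaluator covers di-/trichromats), and the
achromatic contrast is ΔL = |Δf<sub>A</sub>|/ω<sub>A</sub>. Contrasts below
1 JND are indistinguishable; 3 JND or more is easily discriminable even in
poor light. Group-level inference uses bootstrap CIs on centroid distances,
distance-based PERMANOVA (pairwise, Bonferroni-adjusted, with an exact
enumeration mode for small n) and a multivariate dispersion check. Three
observer configs ship as editable YAML (a tetrachromat wall lizard, a
violet-sensitive raptor, a trichromat colubrid snake) together with CIE D65
and a parametric forest-shade illuminant, and a synthetic-spectra generator
reproduces the full study design (102 individuals, 6 replicates each) so
the whole pipeline runs without any external data.

## Worked example

```r
library(morphvision)

sim  <- generate_dataset(default_study_config(seed = 2017))
proc <- process_spectra(sim$spectra, sim$metadata)
summarize_groups(proc, sim$metadata)
#>    morph sex  n brightness chroma hue hue_indiv_mean
#> 1 orange   F 22     39.458  1.928 545          544.5
#> 2 orange   M 23     40.078  1.917 543          543.0
#> 3  white   F 12     48.092  1.066 410          409.9
#> 4  white   M 13     50.580  1.087 411          410.4
#> 5 yellow   F 16     44.586  1.591 504          504.0
#> 6 yellow   M 16     45.720  1.584 501          501.4
```

Per group: sample size, mean brightness (percent reflectance), mean
spectral contrast (chroma), and the mid-reflectance hue of the group mean
spectrum in nm — orange morphs cut on near 543 nm, white spectra are bright
and flat with a ~410 nm midpoint, yellow sits in between.

```r
vs   <- load_visual_system("lizard")
ill  <- load_illuminant("d65")
ct   <- quantum_catches(proc, vs, ill)
boot_group_distance(ct, sim$metadata, B = 1000, seed = 42)
#>            pair    channel point    lo    hi    B seed
#> 1  orange-white  chromatic 14.09 13.88 14.29 1000   42
#> 2  orange-white achromatic  3.35  2.66  4.10 1000   42
#> 3 orange-yellow  chromatic  5.87  5.51  6.24 1000   42
#> 4 orange-yellow achromatic  4.71  4.14  5.33 1000   42
#> 5  white-yellow  chromatic 11.70 11.33 12.03 1000   42
#> 6  white-yellow achromatic  1.36  0.64  2.05 1000   42
```

Every morph pair exceeds the 1-JND discrimination threshold for the lizard
visual system under daylight; all chromatic contrasts clear the 3-JND
"easily discriminable" mark, while the white–yellow achromatic contrast
(1.36 JND, CI 0.64–2.05) is marginal — brightness alone barely separates
those morphs. A pairwise PERMANOVA on the chromatic distance matrix
confirms the separation (`pairwise_permanova(...)`: R² 0.87–0.97,
adjusted p = 0.003 at 999 permutations).

`run_full_analysis(analysis_config(...))` runs the whole 3-system ×
2-illuminant grid and `write_result_bundle()` emits the result tables as
CSV; `inst/cli/morphvision.R` wraps the same calls for shell use
(`simulate` and `run-all` subcommands).

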