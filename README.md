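# spinemorph

Dendritic spines isolate synaptic biochemistry behind a thin neck. How
strongly a spine compartmentalizes is summarized by the
**compartmentalization factor**

    cf = V * L / A        (µm²)

with `V` the head volume, `L` the neck length and `A` the neck
cross-sectional area; for a molecule with cytosolic diffusion coefficient
`D`, `τ = V L / (A D)` is the time constant of diffusional recovery of the
head after a step change in the dendrite. Measuring the ingredients takes
super-resolution (STED) imaging: heads are ~0.4–0.5 µm, necks ~0.1–0.2 µm.

spinemorph is for researchers who quantify spine morphology on STED-like
images and want the entire measurement chain testable. It provides

* a **synthetic data generator**: ground-truth spine populations (built-in
  wild-type and APP/PS1-like presets), rendered as realistic image stacks
  (40 nm pixels, 10 z-sections at 192 nm, Gaussian PSF of 50 nm lateral /
  600 nm axial FWHM, Poisson noise) plus matching generators for EPSC
  time courses, exploration trials and radioligand binding points;
* **morphometry operators**: curvature-following spine length via
  intensity-weighted geodesic tracing, neck width as the average
  Gaussian-fit FWHM of profiles orthogonal to the neck, head width
  orthogonal to the neck axis, spine density;
* **compartmentalization**: per-spine `cf` and `τ`, validated against an
  explicit finite-difference diffusion simulation;
* the **group-comparison workflow**: D'Agostino–Pearson normality gate,
  Student t / Mann–Whitney selection, two-sample Kolmogorov–Smirnov
  against a reference group, empirical CDFs;
* **scalar indices**: LTP magnitude (% of an 8 min baseline, 30–40 min
  post-induction), paired-pulse ratio, NMDAR/AMPAR ratio, tonic current
  shift, displacement index, novel-arm fraction, specific binding per mg
  protein.

Everything takes and returns tidy data frames, is seeded, and chains with
the pipe.

## Worked example

A complete synthetic two-genotype experiment — generate both populations,
render every branch, re-measure each spine from the images, compute cf, and
compare the groups with the wild-type sample as KS reference:

```r
library(spinemorph)

exp1 <- run_full_synthetic_experiment(
  pipeline_config(seed = 1, n_spines_per_group = 60), quiet = TRUE)
exp1
#> <spinemorph_experiment>
#>   135 spines measured in 2 groups (8 branches)
#>   KS spine_length vs appps1: D = 0.204, p = 0.1264
#>   KS head_width   vs appps1: D = 0.253, p = 0.02928 *
#>   KS neck_length  vs appps1: D = 0.107, p = 0.8467
#>   KS neck_width   vs appps1: D = 0.150, p = 0.4426
#>   KS cf           vs appps1: D = 0.175, p = 0.2633
#>   KS density      vs appps1: D = 0.667, p = 0.2857
```

Already at 60 spines per group the head-width distributions separate
(p = 0.029) while spine length and — despite the larger heads and shorter,
wider necks — the compartmentalization factor do not: the morphological
changes cancel in `cf`. At the default 250 spines per group the contrast
sharpens (head width p ≈ 3e-7, cf still non-significant), and the
neck-width shift becomes detectable too. Group summaries and the tidy test
table come from `glance(exp1)` and `tidy(exp1)`; `autoplot(exp1)` draws
the per-variable cumulative distributions.

The scalar indices work the same way on their generators:

```r
ltp <- normalize_timecourse(generate_ltp_series(100, 2.18, noise_sd = 5, seed = 1))
ltp
#> <ltp_result> baseline 100.6 pA, LTP 217.2% of baseline (post window 1800-2400 s)
```

a robust potentiation to ~218% of baseline, read off 30–40 min after the
induction event exactly as the index defines it.

## Documentation

The methods vignette (`vignettes/spinemorph-methods.Rmd`) describes the
generative model and its presets, the rendering physics and its numerical
choices (z anti-aliasing, sub-pixel rasterization), the measurement
operators and their calibration (chord-projection width model, boundary
rules), the diffusion oracle and its regime of validity, the statistical
conventions, and known limitations.
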